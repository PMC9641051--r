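test_that("prepare_curve is idempotent, averages duplicates, selects branches", {
  bb <- healthy_fe_backbone()
  sw <- generate_sweep(bb, resolution = 0.01)
  expect_equal(prepare_curve(sw), sw)

  dup <- sw
  dup$rotation_deg[2] <- dup$rotation_deg[1]
  prep <- prepare_curve(dup)
  expect_equal(nrow(prep), nrow(sw) - 1)
  expect_equal(prep$moment_Nm[1], mean(dup$moment_Nm[1:2]))

  lp <- generate_loop(bb, resolution = 0.01, hysteresis_halfwidth = 0)
  asc <- dplyr::filter(lp, branch == "ascending")
  expect_equal(prepare_curve(lp)$moment_Nm, asc$moment_Nm)

  expect_error(prepare_curve(sw[1:20, ]), "50")
  short <- dplyr::filter(sw, abs(moment_Nm) < 5)
  expect_error(prepare_curve(short), "span")
})

test_that("local-quadratic smoothing reproduces quadratics and kills noise", {
  x <- seq(-2, 2, length.out = 401)
  quad <- tibble::tibble(rotation_deg = x,
                         moment_Nm = 1.5 - 0.3 * x + 2 * x^2)
  expect_equal(smooth_curve(quad, 21)$moment_Nm, quad$moment_Nm,
               tolerance = 1e-9)

  const <- tibble::tibble(rotation_deg = x, moment_Nm = rep(3, 401))
  expect_equal(smooth_curve(const, 21)$moment_Nm, const$moment_Nm)

  expect_error(smooth_curve(quad, 20), "odd")
  expect_error(smooth_curve(quad, 3), "odd|5")

  withr::with_seed(1, {
    noisy <- tibble::tibble(rotation_deg = x,
                            moment_Nm = 2 * x + rnorm(401, 0, 0.1))
  })
  sm <- smooth_curve(noisy, 21)
  res_raw <- sd(noisy$moment_Nm - 2 * x)
  res_sm <- sd(sm$moment_Nm - 2 * x)
  expect_lt(res_sm, res_raw / 2)
  # slope preserved: well within 3 SE of the unsmoothed fit
  slope_se <- res_raw / (sd(x) * sqrt(401))
  expect_lt(abs(fit_linear_band(sm, rotation_band = c(-2, 2)) - 2),
            3 * slope_se)
})

test_that("second derivative matches closed forms on linear and quadratic data", {
  x <- seq(0, 1, length.out = 101)
  lin <- tibble::tibble(rotation_deg = x, moment_Nm = 3 * x)
  expect_equal(second_derivative(lin)$d2M, rep(0, 101), tolerance = 1e-9)

  quad <- tibble::tibble(rotation_deg = x, moment_Nm = 2.5 * x^2)
  expect_equal(second_derivative(quad)$d2M, rep(5, 101), tolerance = 1e-7)

  # non-uniform grid, same closed form
  xn <- sort(c(0, runif(99), 1))
  quadn <- tibble::tibble(rotation_deg = xn, moment_Nm = 2.5 * xn^2)
  expect_equal(second_derivative(quadn)$d2M, rep(5, 101), tolerance = 1e-6)

  bad <- tibble::tibble(rotation_deg = c(0, 0.5, 0.5, 1),
                        moment_Nm = 1:4)
  expect_error(second_derivative(bad), "increasing")
})

test_that("second derivative of a noiseless backbone localises the corners", {
  bb <- healthy_fe_backbone()
  sw <- generate_sweep(bb, resolution = 0.005)
  d2 <- second_derivative(smooth_curve(sw))
  f <- bb$fillet_halfwidth
  w <- default_window(nrow(sw))
  half_support <- f + (w - 1) / 2 * 0.005  # fillet plus smoothing support
  near_corner <- vapply(d2$rotation_deg,
                        function(t) any(abs(t - bb$corners) < half_support),
                        logical(1))
  expect_lt(max(abs(d2$d2M[!near_corner])), 0.05 * max(abs(d2$d2M)))
})

test_that("neutral-zone bounds land on the construction's corners", {
  r <- ref_row("intact", "flexion_extension")
  bb <- solve_backbone(params_from_row(r))
  sw <- generate_sweep(bb, resolution = 0.005)
  nz <- detect_nz_bounds(sw)
  expect_equal(unname(nz[1]), -1.265, tolerance = 0.006)
  expect_equal(unname(nz[2]), 1.265, tolerance = 0.006)
  expect_equal(unname(nz[2] - nz[1]), 2.53, tolerance = 0.01)

  # translation equivariance
  bb1 <- solve_backbone(params_from_row(r, center_offset = 1))
  nz1 <- detect_nz_bounds(generate_sweep(bb1, resolution = 0.005))
  expect_equal(unname(nz1), unname(nz) + 1, tolerance = 0.006)
})

test_that("quasi-linear curves raise a neutral-zone-undetectable error", {
  x <- seq(-4, 4, length.out = 801)
  lin <- tibble::tibble(rotation_deg = x, moment_Nm = 1.5 * x)
  expect_error(detect_nz_bounds(lin), "neutral zone undetectable")
})

test_that("band fits recover exact and published slopes", {
  x <- seq(-4, 4, length.out = 801)
  line <- tibble::tibble(rotation_deg = x, moment_Nm = 2.5 * x)
  expect_equal(as.numeric(fit_linear_band(line, rotation_band = c(-1, 1))),
               2.5, tolerance = 1e-12)
  expect_equal(as.numeric(fit_linear_band(line, moment_band = c(4.5, 6))),
               2.5, tolerance = 1e-12)

  lb <- solve_backbone(params_from_row(ref_row("intact", "lateral_bending")))
  sw <- generate_sweep(lb, resolution = 0.005)
  expect_equal(as.numeric(fit_linear_band(sw, moment_band = c(4.5, 6))),
               2.60, tolerance = 0.01)

  expect_error(fit_linear_band(line, moment_band = c(10.5, 11)), "band")
  expect_error(fit_linear_band(line), "exactly one")
})

test_that("band-fit slopes are unbiased under moment noise", {
  x <- seq(0, 1, length.out = 200)
  slopes <- withr::with_seed(11, {
    vapply(1:500, function(i) {
      cv <- tibble::tibble(rotation_deg = x,
                           moment_Nm = 5 + 3 * x + rnorm(200, 0, 0.05))
      as.numeric(fit_linear_band(cv, rotation_band = c(0, 1)))
    }, numeric(1))
  })
  se_mean <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 3), 3 * se_mean)
})

test_that("ROM matches closed forms and the backbone span", {
  bb <- healthy_fe_backbone()
  sw <- generate_sweep(bb, resolution = 0.005)
  expect_equal(compute_rom(sw), 8.15, tolerance = 1e-6)

  k <- 1.7
  x <- seq(-7, 7, length.out = 701) / k
  anti <- tibble::tibble(rotation_deg = x, moment_Nm = k * x)
  expect_equal(compute_rom(anti), 12 / k, tolerance = 1e-9)

  expect_error(compute_rom(anti, limit = 8), "outside")
})

test_that("full extraction round-trips two noiseless published cells", {
  for (key in list(c("defect", "lateral_bending"),
                   c("treated", "axial_rotation"))) {
    r <- ref_row(key[1], key[2])
    bb <- solve_backbone(params_from_row(r))
    sw <- generate_sweep(bb, resolution = cell_resolution(r$modality))
    k <- process_curve(sw)
    expect_equal(k$rom, r$rom, tolerance = 1e-4)
    expect_equal(k$nz_size, r$nz_size, tolerance = 0.01)
    expect_equal(k$nz_stiffness, r$nz_stiffness, tolerance = 0.01)
    expect_equal(k$ezs_pos, r$ezs_pos, tolerance = 0.01)
    expect_equal(k$ezs_neg, r$ezs_neg, tolerance = 0.01)
  }
})

test_that("loop extraction averages branches and matches the sweep result", {
  r <- ref_row("intact", "flexion_extension")
  bb <- solve_backbone(params_from_row(r))
  lp <- generate_loop(bb, resolution = 0.005, hysteresis_halfwidth = 0.3)
  k <- process_curve(lp)
  expect_equal(k$rom, r$rom, tolerance = 1e-4)
  expect_equal(k$nz_stiffness, r$nz_stiffness, tolerance = 0.01)
  expect_equal(k$ezs_pos, r$ezs_pos, tolerance = 0.01)
  expect_equal(k$ezs_neg, r$ezs_neg, tolerance = 0.01)
  expect_setequal(k$branches, c("ascending", "descending"))
})

test_that("extraction is equivariant under translation and scaling", {
  r <- ref_row("intact", "flexion_extension")
  bb <- solve_backbone(params_from_row(r))
  sw <- generate_sweep(bb, resolution = 0.005)
  base <- process_curve(sw)

  shifted <- dplyr::mutate(sw, rotation_deg = rotation_deg + 2.5)
  ks <- process_curve(shifted)
  expect_equal(ks$nz_bounds, base$nz_bounds + 2.5, tolerance = 1e-9)
  for (nm in c("rom", "nz_size", "nz_stiffness", "ezs_pos", "ezs_neg")) {
    expect_equal(ks[[nm]], base[[nm]], tolerance = 1e-9)
  }

  c_scale <- 2
  scaled <- dplyr::mutate(sw, rotation_deg = rotation_deg * c_scale)
  kc <- process_curve(scaled)
  expect_equal(kc$rom, base$rom * c_scale, tolerance = 1e-9)
  expect_equal(kc$nz_size, base$nz_size * c_scale, tolerance = 1e-9)
  expect_equal(kc$nz_stiffness, base$nz_stiffness / c_scale,
               tolerance = 1e-9)
  expect_equal(kc$ezs_pos, base$ezs_pos / c_scale, tolerance = 1e-9)
  expect_equal(kc$ezs_neg, base$ezs_neg / c_scale, tolerance = 1e-9)
})

test_that("stage errors carry stage provenance", {
  x <- seq(-4, 4, length.out = 801)
  lin <- tibble::tibble(rotation_deg = x, moment_Nm = 1.5 * x)
  expect_error(process_curve(lin), "\\[detect_nz_bounds\\]")
})
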