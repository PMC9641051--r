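#' Published kinetic measures for ovine L4L5 functional spinal units
#'
#' Group means and between-specimen standard deviations of the five kinetic
#' measures for cadaveric ovine L4L5 FSUs (n = 8) under pure-moment loading to
#' +/-6 Nm, for three conditions (intact, with an annulus-fibrosus defect, and
#' defect treated with a repair implant) and three loading modalities. These
#' are the default calibration of the cohort simulator.
#'
#' @return A tibble with columns `condition` (`intact`, `defect`, `treated`),
#'   `modality`, `rom`, `nz_size`, `nz_stiffness`, `ezs_pos`, `ezs_neg` and
#'   the matching `*_sd` columns. Units: degrees for `rom`/`nz_size`,
#'   Nm/degree for the stiffnesses.
#' @export
#' @examples
#' reference_kinetics()
reference_kinetics <- function() {
  tb <- tibble::tribble(
    ~condition, ~modality,
    ~rom, ~rom_sd, ~nz_size, ~nz_size_sd, ~nz_stiffness, ~nz_stiffness_sd,
    ~ezs_pos, ~ezs_pos_sd, ~ezs_neg, ~ezs_neg_sd,
    "intact",  "flexion_extension", 8.15, 2.30, 2.53, 0.71, 0.59, 0.27, 4.18, 1.54, 5.76, 1.44,
    "intact",  "lateral_bending",   9.57, 1.40, 2.69, 0.82, 0.59, 0.14, 2.60, 0.41, 2.86, 0.51,
    "intact",  "axial_rotation",    0.95, 0.27, 0.28, 0.08, 9.04, 3.39, 16.28, 4.92, 20.32, 8.99,
    "defect",  "flexion_extension", 8.86, 2.29, 2.45, 0.87, 0.31, 0.14, 5.15, 1.90, 5.56, 1.54,
    "defect",  "lateral_bending",  12.32, 2.05, 3.13, 0.40, 0.25, 0.09, 2.46, 0.52, 3.29, 0.60,
    "defect",  "axial_rotation",    1.14, 0.29, 0.27, 0.12, 5.59, 2.08, 13.07, 2.87, 15.59, 5.73,
    "treated", "flexion_extension", 8.62, 2.34, 2.66, 0.86, 0.50, 0.26, 4.70, 2.71, 4.81, 1.11,
    "treated", "lateral_bending",  10.52, 1.93, 2.78, 0.77, 0.47, 0.18, 2.37, 0.29, 2.93, 0.50,
    "treated", "axial_rotation",    1.12, 0.34, 0.33, 0.13, 6.15, 2.13, 14.64, 8.09, 13.92, 4.17
  )
  tb
}

#' Default per-modality measurement noise
#'
#' Additive Gaussian noise applied independently to the sampled rotations and
#' moments. The axial-rotation plane gets three times the rotation noise of
#' the bending planes, reflecting the lower signal-to-noise ratio typical of
#' axial-rotation flexibility data.
#'
#' @return A tibble with columns `modality`, `sigma_rotation` (degrees) and
#'   `sigma_moment` (Nm).
#' @export
default_noise <- function() {
  tibble::tibble(
    modality = c("flexion_extension", "lateral_bending", "axial_rotation"),
    sigma_rotation = c(0.02, 0.02, 0.06),
    sigma_moment = c(0.02, 0.02, 0.02)
  )
}

#' Default per-modality sampling resolution
#'
#' Uniform-in-rotation sampling step, in degrees. Axial rotation is sampled
#' an order of magnitude finer because its neutral zone is roughly a tenth
#' the width of the bending-plane neutral zones.
#'
#' @return A tibble with columns `modality` and `resolution` (degrees).
#' @export
default_resolution <- function() {
  tibble::tibble(
    modality = c("flexion_extension", "lateral_bending", "axial_rotation"),
    resolution = c(0.005, 0.005, 0.001)
  )
}

.curve_tibble <- function(rotation, moment, branch, backbone,
                          specimen_id = NA_character_,
                          condition = NA_character_) {
  tibble::tibble(
    rotation_deg = rotation,
    moment_Nm = moment,
    branch = branch,
    specimen_id = specimen_id,
    condition = condition,
    modality = backbone$protocol$modality
  )
}

#' Generate one noiseless-or-noisy moment-rotation sweep
#'
#' Samples the ascending branch of a backbone uniformly in rotation from the
#' rotation at the negative moment limit to the rotation at the positive
#' limit. Both endpoints are included exactly (pre-noise) so the curve spans
#' the full moment range. Gaussian noise is then added independently to
#' rotation and moment.
#'
#' @param backbone An `fsu_backbone` from [solve_backbone()].
#' @param resolution Sampling step in degrees; must be finer than half the
#'   fillet half-width so the corner curvature bumps are resolved.
#' @param noise Length-2 numeric `c(sigma_rotation, sigma_moment)` (degrees,
#'   Nm); 0 disables noise.
#' @param seed Optional integer seed; the global RNG state is left untouched.
#' @param min_samples Minimum number of samples per sweep (default 200).
#' @return A curve tibble with columns `rotation_deg`, `moment_Nm`, `branch`,
#'   `specimen_id`, `condition`, `modality`.
#' @export
#' @examples
#' bb <- solve_backbone(backbone_params(8.15, 2.53, 0.59, 4.18, 5.76))
#' sw <- generate_sweep(bb, resolution = 0.01)
#' range(sw$moment_Nm)
generate_sweep <- function(backbone, resolution = 0.005, noise = c(0, 0),
                           seed = NULL, min_samples = 200L) {
  stopifnot(inherits(backbone, "fsu_backbone"))
  f <- backbone$fillet_halfwidth
  if (!is.numeric(resolution) || resolution <= 0) {
    stop("resolution must be > 0", call. = FALSE)
  }
  if (resolution >= f / 2) {
    stop(sprintf(paste0("resolution %.4g deg too coarse: must be finer than ",
                        "half the fillet half-width (%.4g deg)"),
                 resolution, f / 2), call. = FALSE)
  }
  noise <- rep_len(as.numeric(noise), 2L)
  t_lo <- backbone$knots[1]
  t_hi <- backbone$knots[6]
  n <- max(ceiling((t_hi - t_lo) / resolution) + 1L, as.integer(min_samples))
  theta <- seq(t_lo, t_hi, length.out = n)
  moment <- backbone_moment(backbone, theta)
  # endpoints carry the exact limit moments pre-noise
  moment[1] <- backbone$values[1]
  moment[n] <- backbone$values[6]
  if (any(noise > 0)) {
    if (!is.null(seed)) withr::local_seed(seed)
    theta <- theta + stats::rnorm(n, 0, noise[1])
    moment <- moment + stats::rnorm(n, 0, noise[2])
  }
  .curve_tibble(theta, moment, "ascending", backbone)
}

#' Generate a full hysteresis loop
#'
#' Builds a loading/unloading loop from one backbone: the ascending branch is
#' the backbone shifted down in moment by the hysteresis half-width `h`, the
#' descending branch shifted up by `h`; each branch is sampled over the
#' rotation range where its moments span the full +/-limit, so the loop is
#' closed at the moment limits. With `h = 0` the two branches coincide. The
#' per-branch neutral-zone and elastic-zone measures equal the backbone's,
#' and the branch-averaged range of motion equals the backbone's exactly.
#'
#' @inheritParams generate_sweep
#' @param hysteresis_halfwidth Half the moment separation between the two
#'   branches, in Nm; must satisfy `0 <= h < ez_band_lower / 2`.
#' @return A curve tibble with both branches (`ascending` first, then
#'   `descending` in decreasing rotation order).
#' @export
generate_loop <- function(backbone, resolution = 0.005,
                          hysteresis_halfwidth = 0.3, noise = c(0, 0),
                          seed = NULL, min_samples = 200L) {
  stopifnot(inherits(backbone, "fsu_backbone"))
  h <- hysteresis_halfwidth
  band_low <- backbone$protocol$ez_band[1]
  if (!is.numeric(h) || h < 0 || h >= band_low / 2) {
    stop(sprintf("hysteresis_halfwidth must satisfy 0 <= h < %.4g Nm",
                 band_low / 2), call. = FALSE)
  }
  noise <- rep_len(as.numeric(noise), 2L)
  limit <- backbone$protocol$moment_limit
  if (!is.null(seed)) withr::local_seed(seed)

  one_branch <- function(shift, branch) {
    # branch moment = backbone moment + shift; spans exactly +/-limit
    ends <- backbone_rotation_at(backbone, c(-limit - shift, limit - shift))
    n <- max(ceiling((ends[2] - ends[1]) / resolution) + 1L,
             as.integer(min_samples))
    theta <- seq(ends[1], ends[2], length.out = n)
    moment <- backbone_moment(backbone, theta) + shift
    moment[1] <- -limit
    moment[n] <- limit
    if (any(noise > 0)) {
      theta <- theta + stats::rnorm(n, 0, noise[1])
      moment <- moment + stats::rnorm(n, 0, noise[2])
    }
    cv <- .curve_tibble(theta, moment, branch, backbone)
    if (branch == "descending") cv <- cv[rev(seq_len(nrow(cv))), ]
    cv
  }

  res <- resolution
  if (res >= backbone$fillet_halfwidth / 2) {
    stop(sprintf(paste0("resolution %.4g deg too coarse: must be finer than ",
                        "half the fillet half-width (%.4g deg)"),
                 res, backbone$fillet_halfwidth / 2), call. = FALSE)
  }
  dplyr::bind_rows(one_branch(-h, "ascending"), one_branch(h, "descending"))
}

#' Specify a simulated cohort of flexibility tests
#'
#' Defines a paired-design cohort: `n_specimens` specimens, each tested in
#' every condition and modality listed in `cells`. Per-specimen parameters
#' are drawn from lognormal distributions whose mean and SD match the
#' configured cell means/SDs exactly; a specimen-level random effect shared
#' across conditions induces the within-specimen correlation of a
#' repeated-measures design.
#'
#' @param cells Tibble of cell means and SDs in the format of
#'   [reference_kinetics()] (the default).
#' @param n_specimens Number of specimens (default 8).
#' @param within_correlation Correlation, on the log scale, between a
#'   specimen's draws of the same parameter across conditions (default 0.8).
#' @param noise Per-modality noise tibble as [default_noise()]; set the
#'   sigmas to 0 for noiseless curves.
#' @param resolution Per-modality sampling-step tibble as
#'   [default_resolution()].
#' @param hysteresis_halfwidth Loop half-width in Nm (default 0.3); 0 plus
#'   `loops = FALSE` generates single ascending sweeps.
#' @param loops Generate full loops (default `TRUE`) or ascending sweeps.
#' @param seed Integer seed (required).
#' @param max_retries Resampling attempts per cell draw before failing when a
#'   draw violates the backbone feasibility constraints (default 20).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(cells = reference_kinetics(), n_specimens = 8,
                        within_correlation = 0.8, noise = default_noise(),
                        resolution = default_resolution(),
                        hysteresis_halfwidth = 0.3, loops = TRUE,
                        seed, max_retries = 20L) {
  if (missing(seed) || !is.numeric(seed)) {
    stop("cohort_spec requires an integer seed", call. = FALSE)
  }
  stopifnot(is.data.frame(cells), n_specimens >= 2,
            within_correlation >= 0, within_correlation <= 1)
  need <- c("condition", "modality", "rom", "nz_size", "nz_stiffness",
            "ezs_pos", "ezs_neg")
  miss <- setdiff(need, names(cells))
  if (length(miss)) {
    stop("cells is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sd_cols <- paste0(c("rom", "nz_size", "nz_stiffness", "ezs_pos", "ezs_neg"),
                    "_sd")
  for (sc in sd_cols) if (!sc %in% names(cells)) cells[[sc]] <- 0
  if (any(unlist(cells[sd_cols]) < 0)) {
    stop("cell SDs must be >= 0", call. = FALSE)
  }
  structure(
    list(cells = tibble::as_tibble(cells), n_specimens = as.integer(n_specimens),
         within_correlation = within_correlation, noise = noise,
         resolution = resolution,
         hysteresis_halfwidth = hysteresis_halfwidth, loops = loops,
         seed = as.integer(seed), max_retries = as.integer(max_retries)),
    class = "cohort_spec"
  )
}

# exact lognormal draw: mean m, sd s, with supplied standard-normal deviate z
.lognormal_from_z <- function(m, s, z) {
  if (s == 0) return(m)
  sigma2 <- log(1 + (s / m)^2)
  mu <- log(m) - sigma2 / 2
  exp(mu + sqrt(sigma2) * z)
}

.measure_names <- c("rom", "nz_size", "nz_stiffness", "ezs_pos", "ezs_neg")

#' Sample the ground-truth parameter table of a cohort
#'
#' Draws per-specimen, per-cell kinetic parameters without generating curves.
#' Each parameter is lognormal with exactly the configured cell mean and SD;
#' the underlying normal deviate is `rho * z_specimen + sqrt(1 - rho^2) *
#' z_cell`, where `z_specimen` is shared by a specimen across conditions,
#' giving within-specimen correlation `rho` on the log scale. Draws that
#' violate the backbone feasibility constraints are resampled (cell deviate
#' only) up to `max_retries` times.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per (specimen, condition, modality) and the
#'   five parameter columns.
#' @export
sample_cohort_params <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::local_seed(spec$seed)
  rho <- spec$within_correlation
  cells <- spec$cells
  draw_cell <- function(cell, z_spec) {
    # retries redraw only the cell-level residual, keeping the specimen
    # effect that ties conditions together
    for (try in seq_len(spec$max_retries)) {
      z_cell <- stats::rnorm(length(.measure_names))
      z <- rho * z_spec + sqrt(1 - rho^2) * z_cell
      vals <- vapply(.measure_names, function(nm) {
        .lognormal_from_z(cell[[nm]], cell[[paste0(nm, "_sd")]], z[[nm]])
      }, numeric(1))
      feasible <- tryCatch({
        solve_backbone(backbone_params(
          rom = vals[["rom"]], nz_size = vals[["nz_size"]],
          nz_stiffness = vals[["nz_stiffness"]],
          ezs_pos = vals[["ezs_pos"]], ezs_neg = vals[["ezs_neg"]],
          protocol = loading_protocol(cell$modality)
        ))
        TRUE
      }, error = function(e) FALSE)
      if (feasible) return(vals)
    }
    NULL
  }

  draw_specimen <- function(s) {
    # an unlucky specimen effect can make a cell unreachable by cell-level
    # retries alone; in that case the whole specimen is redrawn
    for (attempt in seq_len(spec$max_retries)) {
      z_spec <- stats::setNames(stats::rnorm(length(.measure_names)),
                                .measure_names)
      rows <- vector("list", nrow(cells))
      failed <- NULL
      for (ci in seq_len(nrow(cells))) {
        cell <- cells[ci, ]
        vals <- draw_cell(cell, z_spec)
        if (is.null(vals)) {
          failed <- cell
          break
        }
        rows[[ci]] <- tibble::tibble(
          specimen_id = sprintf("S%02d", s),
          condition = cell$condition, modality = cell$modality,
          rom = vals[["rom"]], nz_size = vals[["nz_size"]],
          nz_stiffness = vals[["nz_stiffness"]],
          ezs_pos = vals[["ezs_pos"]], ezs_neg = vals[["ezs_neg"]]
        )
      }
      if (is.null(failed)) return(dplyr::bind_rows(rows))
    }
    stop(sprintf(paste0("could not draw feasible backbone parameters for ",
                        "cell (%s, %s) after %d retries"),
                 failed$condition, failed$modality, spec$max_retries),
         call. = FALSE)
  }

  dplyr::bind_rows(lapply(seq_len(spec$n_specimens), draw_specimen))
}

#' Generate a full synthetic cohort of moment-rotation curves
#'
#' Samples ground-truth parameters with [sample_cohort_params()] and renders
#' one curve (loop or sweep, per the spec) for every (specimen, condition,
#' modality) cell, with the configured per-modality resolution and noise.
#' Fully reproducible from the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `fsu_cohort` with elements `curves` (one long
#'   tibble of all samples) and `truth` (the ground-truth parameter table).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  truth <- sample_cohort_params(spec)
  withr::local_seed(spec$seed + 1L)
  res_map <- stats::setNames(spec$resolution$resolution,
                             spec$resolution$modality)
  sig_r <- stats::setNames(spec$noise$sigma_rotation, spec$noise$modality)
  sig_m <- stats::setNames(spec$noise$sigma_moment, spec$noise$modality)
  curves <- purrr::pmap(truth, function(specimen_id, condition, modality,
                                        rom, nz_size, nz_stiffness,
                                        ezs_pos, ezs_neg) {
    bb <- solve_backbone(backbone_params(
      rom, nz_size, nz_stiffness, ezs_pos, ezs_neg,
      protocol = loading_protocol(modality)
    ))
    nz <- c(sig_r[[modality]], sig_m[[modality]])
    cv <- if (spec$loops) {
      generate_loop(bb, resolution = res_map[[modality]],
                    hysteresis_halfwidth = spec$hysteresis_halfwidth,
                    noise = nz)
    } else {
      generate_sweep(bb, resolution = res_map[[modality]], noise = nz)
    }
    cv$specimen_id <- specimen_id
    cv$condition <- condition
    cv
  })
  structure(list(curves = dplyr::bind_rows(curves), truth = truth,
                 spec = spec),
            class = "fsu_cohort")
}

#' @export
print.fsu_cohort <- function(x, ...) {
  cat(sprintf("<fsu_cohort> %d curves (%d samples), %d specimens\n",
              nrow(dplyr::distinct(x$curves, .data$specimen_id,
                                   .data$condition, .data$modality)),
              nrow(x$curves), x$spec$n_specimens))
  invisible(x)
}
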