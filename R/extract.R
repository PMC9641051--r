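#' Prepare a moment-rotation curve for analysis
#'
#' Selects one monotone branch of the curve, sorts it by rotation, collapses
#' duplicate rotations by averaging their moments, and checks that the curve
#' is long and wide enough to analyse.
#'
#' @param curve Tibble with at least `rotation_deg` and `moment_Nm`;
#'   optionally a `branch` column (`ascending`/`descending`/`full_loop`).
#' @param branch Which branch to keep when a `branch` column is present
#'   (default `"ascending"`).
#' @param moment_limit Required moment span: the curve must reach at least
#'   `+/-(moment_limit - span_tolerance)` Nm. Default 6.
#' @param span_tolerance Slack (Nm) allowed at the moment extremes before the
#'   span check fails; accommodates measurement noise at the limits.
#'   Default 0.1.
#' @param min_samples Minimum sample count (default 50).
#' @return The prepared curve tibble, ascending in rotation.
#' @export
prepare_curve <- function(curve, branch = "ascending", moment_limit = 6,
                          span_tolerance = 0.1, min_samples = 50L) {
  stopifnot(is.data.frame(curve),
            all(c("rotation_deg", "moment_Nm") %in% names(curve)))
  cv <- tibble::as_tibble(curve)
  if ("branch" %in% names(cv) && any(cv$branch == branch)) {
    cv <- dplyr::filter(cv, .data$branch == !!branch)
  }
  if (nrow(cv) < min_samples) {
    stop(sprintf("curve has %d samples; at least %d required",
                 nrow(cv), min_samples), call. = FALSE)
  }
  if (max(cv$moment_Nm) < moment_limit - span_tolerance ||
      min(cv$moment_Nm) > -moment_limit + span_tolerance) {
    stop(sprintf(paste0("moment span [%.3f, %.3f] Nm falls short of the ",
                        "+/-%.3g Nm limits"),
                 min(cv$moment_Nm), max(cv$moment_Nm), moment_limit),
         call. = FALSE)
  }
  cv <- dplyr::arrange(cv, .data$rotation_deg)
  # Collapse coincident rotations by bin-averaging on the curve's nominal
  # uniform grid (grid step = span / (n - 1)). For noiselessly sampled
  # curves every sample keeps its own bin and the curve passes through
  # unchanged; rotation noise that reorders or nearly duplicates samples is
  # averaged out instead of creating the tiny rotation gaps that would blow
  # up a finite-difference second derivative.
  x <- cv$rotation_deg
  n <- length(x)
  h <- (x[n] - x[1]) / (n - 1)
  cv$`.bin` <- round((x - x[1]) / h)
  cv <- cv |>
    dplyr::group_by(.data$.bin) |>
    dplyr::summarise(
      rotation_deg = mean(.data$rotation_deg),
      moment_Nm = mean(.data$moment_Nm),
      dplyr::across(!c("rotation_deg", "moment_Nm"), dplyr::first),
      .groups = "drop"
    ) |>
    dplyr::select(!".bin") |>
    dplyr::relocate("rotation_deg", "moment_Nm")
  cv
}

#' Smooth a curve with local quadratic least squares
#'
#' Savitzky-Golay-style smoothing of moment as a function of rotation: each
#' sample is replaced by the value, at that rotation, of an order-2
#' polynomial fitted by least squares to the `window` surrounding samples.
#' Works on non-uniform rotation grids. Endpoints use symmetric windows
#' shrunk to fit; the first and last points are left unchanged (a quadratic
#' through three points interpolates them). Rotations are not modified.
#' Exactly quadratic input is reproduced to round-off.
#'
#' @param curve Prepared curve tibble (ascending rotations).
#' @param window Odd number of samples per fit, `>= 5` and less than the
#'   sample count. Default: 5% of the sample count, rounded to odd.
#' @return The curve with smoothed `moment_Nm`.
#' @export
smooth_curve <- function(curve, window = NULL) {
  stopifnot(is.data.frame(curve))
  x <- curve$rotation_deg
  y <- curve$moment_Nm
  n <- length(x)
  if (is.null(window)) window <- default_window(n)
  if (window %% 2 == 0 || window < 5 || window >= n) {
    stop(sprintf(paste0("smoothing window must be an odd sample count in ",
                        "[5, %d); got %s"), n, format(window)), call. = FALSE)
  }
  curve$moment_Nm <- .local_quadratic(x, y, as.integer(window))
  curve
}

#' @rdname smooth_curve
#' @param n_samples Sample count from which to derive the default window.
#' @export
default_window <- function(n_samples) {
  w <- max(5L, as.integer(round(0.05 * n_samples)))
  if (w %% 2L == 0L) w <- w + 1L
  min(w, if (n_samples %% 2L == 0L) n_samples - 1L else n_samples - 2L)
}

#' @rdname smooth_curve
#' @details `curvature_window()` is the slightly wider default (7.5% of
#'   samples) used when the smoothed curve feeds the second-derivative
#'   neutral-zone detection, paired with a finite-difference stride of half
#'   the window so that the curvature is estimated at the smoothing scale.
#'   Both the window and the stencil are symmetric, so the curvature peaks'
#'   locations stay centred on the true zone corners.
#' @export
curvature_window <- function(n_samples) {
  w <- max(5L, as.integer(round(0.075 * n_samples)))
  if (w %% 2L == 0L) w <- w + 1L
  min(w, if (n_samples %% 2L == 0L) n_samples - 1L else n_samples - 2L)
}

# Vectorised running local-quadratic fit. Windows are contiguous index
# ranges; per-window normal equations are assembled from cumulative power
# sums re-centred (exactly, via binomial expansion) at the evaluation point,
# and solved with Cramer's rule. O(n). The global linear trend is removed
# first and restored afterwards: local quadratic fits reproduce it exactly,
# and working on the (much smaller) residuals keeps the accumulated
# round-off far below any curvature of interest.
.local_quadratic <- function(x, y, window) {
  xbar <- mean(x)
  ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  beta <- if (sxx > 0) sum((x - xbar) * (y - ybar)) / sxx else 0
  trend <- ybar + beta * (x - xbar)
  trend + .local_quadratic_raw(x, y - trend, window)
}

.local_quadratic_raw <- function(x, y, window) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  i <- seq_len(n)
  hw <- pmin(h, i - 1L, n - i)
  lo <- i - hw
  hi <- i + hw
  xc <- x - mean(x)  # global shift for conditioning; result is shift-invariant
  cs <- function(v) cumsum(c(0, v))
  S1 <- cs(xc); S2 <- cs(xc^2); S3 <- cs(xc^3); S4 <- cs(xc^4)
  Sy <- cs(y); Sxy <- cs(xc * y); Sx2y <- cs(xc^2 * y)
  w <- function(S) S[hi + 1L] - S[lo]
  m <- (hi - lo) + 1L
  c0 <- xc
  W1 <- w(S1); W2 <- w(S2); W3 <- w(S3); W4 <- w(S4)
  Wy <- w(Sy); Wxy <- w(Sxy); Wx2y <- w(Sx2y)
  T0 <- m
  T1 <- W1 - c0 * m
  T2 <- W2 - 2 * c0 * W1 + c0^2 * m
  T3 <- W3 - 3 * c0 * W2 + 3 * c0^2 * W1 - c0^3 * m
  T4 <- W4 - 4 * c0 * W3 + 6 * c0^2 * W2 - 4 * c0^3 * W1 + c0^4 * m
  U0 <- Wy
  U1 <- Wxy - c0 * Wy
  U2 <- Wx2y - 2 * c0 * Wxy + c0^2 * Wy
  det <- T0 * (T2 * T4 - T3^2) - T1 * (T1 * T4 - T2 * T3) +
    T2 * (T1 * T3 - T2^2)
  a <- (U0 * (T2 * T4 - T3^2) - U1 * (T1 * T4 - T2 * T3) +
          U2 * (T1 * T3 - T2^2)) / det
  bad <- !is.finite(a) | m < 3L
  a[bad] <- y[bad]
  a
}

#' Second derivative of moment with respect to rotation
#'
#' Central finite differences on the (possibly non-uniform) rotation grid,
#' using the three points `i - stride`, `i`, `i + stride`; the formula is
#' exact for quadratics at any stride. A stride greater than 1 estimates the
#' curvature at the scale of `stride` grid steps, which is what makes the
#' derivative of a smoothed noisy curve usable: differencing adjacent
#' samples of a smoothed sequence amplifies the sample-scale jitter that
#' smoothing leaves behind, while differencing at the smoothing scale does
#' not. The end points reuse the outermost interior estimate.
#'
#' @param curve Curve tibble with strictly increasing `rotation_deg`
#'   (normally the output of [smooth_curve()]).
#' @param stride Half-stencil width in samples (default 1, the classical
#'   three-point formula).
#' @return A tibble with `rotation_deg` and `d2M` (Nm/degree^2).
#' @export
second_derivative <- function(curve, stride = 1L) {
  x <- curve$rotation_deg
  y <- curve$moment_Nm
  n <- length(x)
  stride <- max(1L, as.integer(stride))
  if (n < 2L * stride + 1L) {
    stop("need at least 2 * stride + 1 samples", call. = FALSE)
  }
  if (any(diff(x) <= 0)) {
    stop("rotations must be strictly increasing; run prepare_curve() first",
         call. = FALSE)
  }
  i <- (stride + 1L):(n - stride)
  h0 <- x[i] - x[i - stride]
  h1 <- x[i + stride] - x[i]
  d2 <- 2 * ((y[i + stride] - y[i]) / h1 - (y[i] - y[i - stride]) / h0) /
    (h0 + h1)
  tibble::tibble(rotation_deg = x,
                 d2M = c(rep(d2[1L], stride), d2,
                         rep(d2[length(d2)], stride)))
}

#' Detect neutral-zone bounds from second-derivative extrema
#'
#' The neutral zone is bounded by the inflections of the moment-rotation
#' curve, located as local extrema of the second derivative of the smoothed
#' curve. Within the central search band (samples with
#' `|moment| < search_band`), extrema whose absolute curvature exceeds
#' `prominence_fraction` times the maximum in-band absolute curvature
#' qualify; the innermost qualifying extremum on each side of the
#' zero-moment crossing gives the bounds. Samples whose smoothing window was
#' truncated at the curve ends are excluded from the search: their curvature
#' is estimated at a different scale and would distort the gate.
#'
#' @param curve Prepared curve tibble (used for the moment values and the
#'   zero-moment crossing).
#' @param curvature Optional precomputed tibble from [second_derivative()];
#'   by default the curve is smoothed with `window` samples and
#'   differentiated.
#' @param window Smoothing window used for the curvature; default
#'   [curvature_window()].
#' @param search_band Moment half-width (Nm) of the central region searched;
#'   default 4.5, the inner edge of the elastic zones.
#' @param prominence_fraction Curvature threshold as a fraction of the
#'   in-band maximum (default 0.25).
#' @param min_curvature Absolute curvature floor below which the curve is
#'   declared quasi-linear (neutral zone undetectable). Defaults to
#'   `1e-6 * moment span / rotation span^2`, i.e. one millionth of the
#'   curve's global curvature scale, which rejects the round-off-level
#'   wiggles of an exactly linear curve.
#' @return Named numeric `c(lower, upper)` rotation bounds in degrees, with
#'   attributes `peaks` (the curvature magnitudes at the two bounds) and
#'   `window`.
#' @export
detect_nz_bounds <- function(curve, curvature = NULL, window = NULL,
                             search_band = 4.5, prominence_fraction = 0.25,
                             min_curvature = NULL) {
  margin <- 0L
  if (is.null(curvature)) {
    if (is.null(window)) window <- curvature_window(nrow(curve))
    stride <- max(1L, (as.integer(window) - 1L) %/% 2L)
    curvature <- second_derivative(smooth_curve(curve, window),
                                   stride = stride)
    # exclude samples whose stencil touches shrunken end windows
    margin <- (as.integer(window) - 1L) %/% 2L + stride
  }
  d2 <- curvature$d2M
  x <- curvature$rotation_deg
  m <- curve$moment_Nm
  stopifnot(length(m) == length(d2))
  n <- length(d2)
  core <- seq_len(n) > margin & seq_len(n) <= n - margin
  in_band <- abs(m) < search_band & core
  if (!any(in_band)) {
    stop("no full-window samples inside the search band", call. = FALSE)
  }
  if (is.null(min_curvature)) {
    min_curvature <- 1e-6 * diff(range(m)) / diff(range(x))^2
  }
  dd <- diff(d2)
  is_max <- c(FALSE, dd[-(n - 1L)] > 0 & dd[-1L] < 0, FALSE)
  is_min <- c(FALSE, dd[-(n - 1L)] < 0 & dd[-1L] > 0, FALSE)
  ext <- which((is_max | is_min) & in_band)
  # the gate is normalised by the largest in-band curvature *peak*: the
  # monotone flanks of out-of-band features have no extrema and therefore
  # cannot mask the neutral-zone bumps
  max_abs <- if (length(ext)) max(abs(d2[ext])) else 0
  if (max_abs < min_curvature) {
    stop(paste0("neutral zone undetectable: in-band curvature is below the ",
                "quasi-linear floor (curve may be quasi-linear)"),
         call. = FALSE)
  }
  thr <- prominence_fraction * max_abs
  cand <- ext[abs(d2[ext]) >= thr]
  theta0 <- x[which.min(abs(m))]
  # on an ascending-rotation curve the slope falls entering the neutral
  # zone and rises leaving it: the lower bound is a curvature minimum, the
  # upper bound a curvature maximum
  left <- cand[x[cand] < theta0 & is_min[cand]]
  right <- cand[x[cand] > theta0 & is_max[cand]]
  if (!length(left) || !length(right)) {
    stop(paste0("neutral zone undetectable: no qualifying curvature ",
                "extremum on both sides of the zero-moment crossing ",
                "(curve may be quasi-linear)"), call. = FALSE)
  }
  # noise can split one broad curvature peak into several sample-level
  # extrema; the contiguous above-threshold run containing the innermost
  # candidate is treated as a single peak and its extremum is the bound
  peak_of_run <- function(i0, sign) {
    keep <- sign * d2 >= thr
    j0 <- i0
    while (j0 > 1L && keep[j0 - 1L]) j0 <- j0 - 1L
    j1 <- i0
    while (j1 < n && keep[j1 + 1L]) j1 <- j1 + 1L
    run <- j0:j1
    run[which.max(sign * d2[run])]
  }
  i_lo <- peak_of_run(left[which.max(x[left])], -1)
  i_hi <- peak_of_run(right[which.min(x[right])], 1)
  structure(c(lower = x[i_lo], upper = x[i_hi]),
            peaks = c(abs(d2[i_lo]), abs(d2[i_hi])),
            window = window)
}

#' Least-squares slope of moment on rotation over a selected band
#'
#' Ordinary least squares of moment regressed on rotation over the samples
#' selected either by a rotation interval (neutral-zone fit) or by a signed
#' moment interval (elastic-zone fit).
#'
#' @param curve Prepared curve tibble.
#' @param rotation_band Length-2 rotation interval in degrees, or `NULL`.
#' @param moment_band Length-2 signed moment interval in Nm (e.g.
#'   `c(4.5, 6)` or `c(-6, -4.5)`), or `NULL`. Exactly one selector must be
#'   given.
#' @param min_points Minimum samples in the band (default 5).
#' @return The slope in Nm/degree, with attribute `n` (samples used).
#' @export
fit_linear_band <- function(curve, rotation_band = NULL, moment_band = NULL,
                            min_points = 5L) {
  if (is.null(rotation_band) == is.null(moment_band)) {
    stop("supply exactly one of rotation_band or moment_band", call. = FALSE)
  }
  sel <- if (!is.null(rotation_band)) {
    b <- sort(rotation_band)
    curve$rotation_deg >= b[1] & curve$rotation_deg <= b[2]
  } else {
    b <- sort(moment_band)
    curve$moment_Nm >= b[1] & curve$moment_Nm <= b[2]
  }
  n <- sum(sel)
  if (n < min_points) {
    stop(sprintf(paste0("only %d samples in the requested band [%.4g, %.4g] ",
                        "(%s); at least %d required"),
                 n, b[1], b[2],
                 if (!is.null(rotation_band)) "deg" else "Nm", min_points),
         call. = FALSE)
  }
  x <- curve$rotation_deg[sel]
  y <- curve$moment_Nm[sel]
  slope <- stats::cov(x, y) / stats::var(x)
  structure(slope, n = n)
}

#' Range of motion between the moment limits
#'
#' Rotation at the positive moment limit minus rotation at the negative
#' limit. Each endpoint rotation is obtained from the outermost monotone run
#' of the curve: an exact sample at the limit is used when present, otherwise
#' rotation is linearly interpolated against moment within that run (or
#' extrapolated from its last segment if noise leaves the recorded extreme
#' just short of the limit).
#'
#' @param curve Prepared curve tibble.
#' @param limit Moment limit in Nm (default 6).
#' @param span_tolerance How far (Nm) the recorded extreme may fall short of
#'   `limit` before an error is raised. Default 0.1.
#' @return ROM in degrees.
#' @export
compute_rom <- function(curve, limit = 6, span_tolerance = 0.1) {
  x <- curve$rotation_deg
  y <- curve$moment_Nm
  n <- length(x)
  if (max(y) < limit - span_tolerance || min(y) > -limit + span_tolerance) {
    stop(sprintf("moment limit +/-%.3g Nm outside the sampled range [%.3f, %.3f]",
                 limit, min(y), max(y)), call. = FALSE)
  }
  endpoint <- function(target, tail_end) {
    idx <- if (tail_end) rev(seq_len(n)) else seq_len(n)
    ym <- y[idx]
    # outermost monotone run: walk inwards while the moment keeps moving
    # away from the interior
    run <- 1L
    while (run < n - 1L &&
           ((tail_end && ym[run + 1L] < ym[run]) ||
            (!tail_end && ym[run + 1L] > ym[run]))) {
      run <- run + 1L
    }
    ii <- idx[seq_len(max(run, 2L))]
    xr <- x[ii]
    yr <- y[ii]
    hit <- which(yr == target)
    if (length(hit)) return(xr[hit[1L]])
    o <- order(yr)
    yr <- yr[o]
    xr <- xr[o]
    if (target >= yr[1] && target <= yr[length(yr)]) {
      stats::approx(yr, xr, xout = target, ties = "ordered")$y
    } else {
      # extrapolate from the outermost segment of the run
      k <- length(yr)
      if (tail_end) {
        xr[k] + (target - yr[k]) * (xr[k] - xr[k - 1]) / (yr[k] - yr[k - 1])
      } else {
        xr[1] + (target - yr[1]) * (xr[2] - xr[1]) / (yr[2] - yr[1])
      }
    }
  }
  endpoint(limit, tail_end = TRUE) - endpoint(-limit, tail_end = FALSE)
}

#' Extract all five kinetic measures from one moment-rotation curve
#'
#' Full processing chain: branch preparation, local-quadratic smoothing,
#' second derivative, neutral-zone bound detection, least-squares
#' neutral-zone and elastic-zone fits, and range of motion. Smoothing feeds
#' only the curvature used for bound detection; the slope fits and the ROM
#' are computed on the prepared (unsmoothed) curve, since smoothing a kinked
#' curve would bias the slopes near the zone corners. For a full loop, each
#' branch is processed separately and the five measures averaged.
#'
#' @param curve Curve tibble; may contain one sweep or a full loop (branch
#'   column `ascending`/`descending`).
#' @param protocol A [loading_protocol()]; defaults to one matching the
#'   curve's `modality` column (or flexion-extension).
#' @param window Smoothing window feeding the curvature-based neutral-zone
#'   detection; `NULL` for the [curvature_window()] default.
#' @param search_band,prominence_fraction Passed to [detect_nz_bounds()];
#'   `search_band = NULL` uses the protocol's elastic-zone lower bound.
#' @param branch_policy `"average"` (default) processes both branches of a
#'   loop and averages the measures; `"ascending"`/`"descending"` use one
#'   branch only.
#' @param span_tolerance Passed to [prepare_curve()] and [compute_rom()].
#' @return An object of class `kinetics_result`; see [tidy.kinetics_result()].
#' @export
#' @examples
#' bb <- solve_backbone(backbone_params(8.15, 2.53, 0.59, 4.18, 5.76))
#' res <- process_curve(generate_sweep(bb, resolution = 0.01))
#' tidy(res)
process_curve <- function(curve, protocol = NULL, window = NULL,
                          search_band = NULL, prominence_fraction = 0.25,
                          branch_policy = c("average", "ascending",
                                            "descending"),
                          span_tolerance = 0.1) {
  branch_policy <- match.arg(branch_policy)
  if (is.null(protocol)) {
    modality <- if ("modality" %in% names(curve)) curve$modality[1]
      else "flexion_extension"
    protocol <- loading_protocol(modality)
  }
  if (is.null(search_band)) search_band <- protocol$ez_band[1]
  branches <- if ("branch" %in% names(curve)) {
    intersect(c("ascending", "descending"), unique(curve$branch))
  } else "ascending"
  if (branch_policy != "average") branches <- intersect(branches, branch_policy)
  if (!length(branches)) branches <- "ascending"

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  per_branch <- lapply(branches, function(br) {
    prep <- stage("prepare", prepare_curve(
      curve, branch = br, moment_limit = protocol$moment_limit,
      span_tolerance = span_tolerance))
    win <- if (is.null(window)) curvature_window(nrow(prep)) else window
    nz <- stage("detect_nz_bounds", detect_nz_bounds(
      prep, window = win, search_band = search_band,
      prominence_fraction = prominence_fraction))
    k_nz <- stage("nz_fit", fit_linear_band(prep, rotation_band = nz))
    ez1 <- stage("ez_fit_pos", fit_linear_band(
      prep, moment_band = protocol$ez_band))
    ez2 <- stage("ez_fit_neg", fit_linear_band(
      prep, moment_band = -rev(protocol$ez_band)))
    rom <- stage("rom", compute_rom(prep, limit = protocol$moment_limit,
                                    span_tolerance = span_tolerance))
    list(rom = rom, nz_size = unname(nz[2] - nz[1]),
         nz_stiffness = as.numeric(k_nz),
         ezs_pos = as.numeric(ez1), ezs_neg = as.numeric(ez2),
         nz_lower = unname(nz[1]), nz_upper = unname(nz[2]),
         window = win, n_nz = attr(k_nz, "n"),
         n_ez_pos = attr(ez1, "n"), n_ez_neg = attr(ez2, "n"),
         peaks = attr(nz, "peaks"), curve = prep)
  })

  avg <- function(field) mean(vapply(per_branch, `[[`, numeric(1), field))
  structure(
    list(rom = avg("rom"), nz_size = avg("nz_size"),
         nz_stiffness = avg("nz_stiffness"),
         ezs_pos = avg("ezs_pos"), ezs_neg = avg("ezs_neg"),
         nz_bounds = c(lower = avg("nz_lower"), upper = avg("nz_upper")),
         protocol = protocol,
         branches = branches,
         diagnostics = list(
           window = per_branch[[1]]$window,
           n_nz = vapply(per_branch, `[[`, integer(1), "n_nz"),
           n_ez_pos = vapply(per_branch, `[[`, integer(1), "n_ez_pos"),
           n_ez_neg = vapply(per_branch, `[[`, integer(1), "n_ez_neg"),
           curvature_peaks = lapply(per_branch, `[[`, "peaks")
         ),
         curve = per_branch[[1]]$curve),
    class = "kinetics_result"
  )
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat("<kinetics_result>\n")
  cat(sprintf("  ROM          %8.4f deg\n", x$rom))
  cat(sprintf("  NZ size      %8.4f deg  [%.4f, %.4f]\n",
              x$nz_size, x$nz_bounds[1], x$nz_bounds[2]))
  cat(sprintf("  NZ stiffness %8.4f Nm/deg\n", x$nz_stiffness))
  cat(sprintf("  EZS1 / EZS2  %8.4f / %.4f Nm/deg\n", x$ezs_pos, x$ezs_neg))
  invisible(x)
}

#' Tidy a kinetics result into a one-row tibble
#'
#' @param x A `kinetics_result` from [process_curve()].
#' @param ... Unused.
#' @return A one-row tibble with the five measures, the neutral-zone bounds
#'   and the smoothing window used.
#' @export
tidy.kinetics_result <- function(x, ...) {
  tibble::tibble(
    rom = x$rom, nz_size = x$nz_size, nz_stiffness = x$nz_stiffness,
    ezs_pos = x$ezs_pos, ezs_neg = x$ezs_neg,
    nz_lower = unname(x$nz_bounds[1]), nz_upper = unname(x$nz_bounds[2]),
    window = x$diagnostics$window
  )
}

#' Extract kinetics for every curve in a long table
#'
#' Splits a long curve table by (specimen, condition, modality), runs
#' [process_curve()] on each, and binds the tidied results.
#'
#' @param curves Long tibble of samples with `specimen_id`, `condition`,
#'   `modality`, `branch`, `rotation_deg`, `moment_Nm`.
#' @param on_error `"propagate"` (default) re-raises the first per-curve
#'   failure; `"na"` records `NA` measures for failed curves and keeps the
#'   staged error message in the `note` column, so one undetectable neutral
#'   zone does not abort a whole cohort.
#' @param ... Passed to [process_curve()].
#' @return A tibble with one row per curve: the identifiers plus the columns
#'   of [tidy.kinetics_result()] and a `note` column (`NA` on success).
#' @export
extract_kinetics <- function(curves, ..., on_error = c("propagate", "na")) {
  on_error <- match.arg(on_error)
  stopifnot(all(c("specimen_id", "condition", "modality") %in% names(curves)))
  na_row <- tibble::tibble(
    rom = NA_real_, nz_size = NA_real_, nz_stiffness = NA_real_,
    ezs_pos = NA_real_, ezs_neg = NA_real_,
    nz_lower = NA_real_, nz_upper = NA_real_, window = NA_integer_
  )
  curves |>
    dplyr::group_by(.data$specimen_id, .data$condition, .data$modality) |>
    dplyr::group_modify(function(df, key) {
      out <- tryCatch(
        dplyr::mutate(
          tidy(process_curve(dplyr::mutate(df, modality = key$modality),
                             ...)),
          note = NA_character_),
        error = function(e) {
          if (on_error == "propagate") stop(e)
          dplyr::mutate(na_row, note = conditionMessage(e))
        }
      )
      out
    }) |>
    dplyr::ungroup()
}
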