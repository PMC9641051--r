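#' Loading protocol for a pure-moment flexibility test
#'
#' Describes how a functional spinal unit (FSU) is loaded: the peak applied
#' moment, the moment band over which the elastic zones are fitted, and the
#' anatomical plane. The sign convention is positive = extension / left
#' lateral bending / left axial rotation.
#'
#' @param modality One of `"flexion_extension"`, `"lateral_bending"`,
#'   `"axial_rotation"`.
#' @param moment_limit Peak applied moment in Nm. Default 6.
#' @param ez_band Closed moment interval (Nm) of the elastic-zone fit band;
#'   its upper bound must equal `moment_limit`. Default `c(4.5, 6)`.
#' @return An object of class `loading_protocol`.
#' @export
#' @examples
#' loading_protocol("flexion_extension")
loading_protocol <- function(modality = c("flexion_extension",
                                          "lateral_bending",
                                          "axial_rotation"),
                             moment_limit = 6,
                             ez_band = c(4.5, moment_limit)) {
  modality <- match.arg(modality)
  stopifnot(is.numeric(moment_limit), length(moment_limit) == 1L,
            is.numeric(ez_band), length(ez_band) == 2L)
  if (!(0 < ez_band[1] && ez_band[1] < ez_band[2])) {
    stop("ez_band must satisfy 0 < lower < upper", call. = FALSE)
  }
  if (abs(ez_band[2] - moment_limit) > 1e-12) {
    stop("upper bound of ez_band must equal moment_limit", call. = FALSE)
  }
  structure(
    list(modality = modality, moment_limit = moment_limit, ez_band = ez_band),
    class = "loading_protocol"
  )
}

#' @export
print.loading_protocol <- function(x, ...) {
  cat(sprintf("<loading_protocol> %s, +/-%.3g Nm, EZ band [%.3g, %.3g] Nm\n",
              x$modality, x$moment_limit, x$ez_band[1], x$ez_band[2]))
  invisible(x)
}

#' Ground-truth kinetic parameters for one synthetic FSU curve
#'
#' The five kinetic measures of a flexibility test, used as the ground truth
#' from which a synthetic moment-rotation backbone is constructed: range of
#' motion (`rom`), neutral-zone size (`nz_size`) and stiffness
#' (`nz_stiffness`), and the elastic-zone stiffnesses in the positive
#' (`ezs_pos`, EZS1) and negative (`ezs_neg`, EZS2) loading directions.
#'
#' @param rom Range of motion in degrees (rotation span between the negative
#'   and positive moment limits).
#' @param nz_size Neutral-zone width in degrees.
#' @param nz_stiffness Neutral-zone slope in Nm/degree.
#' @param ezs_pos,ezs_neg Elastic-zone slopes (Nm/degree) in the positive and
#'   negative directions.
#' @param center_offset Rotation (degrees) of the neutral-zone centre, where
#'   the applied moment is zero. Default 0.
#' @param fillet_halfwidth Half-width (degrees) of the smoothstep blends at
#'   the four slope corners. Default `0.05 * nz_size`.
#' @param protocol A [loading_protocol()].
#' @return An object of class `backbone_params`.
#' @seealso [solve_backbone()]
#' @export
backbone_params <- function(rom, nz_size, nz_stiffness, ezs_pos, ezs_neg,
                            center_offset = 0,
                            fillet_halfwidth = 0.05 * nz_size,
                            protocol = loading_protocol()) {
  vals <- c(rom = rom, nz_size = nz_size, nz_stiffness = nz_stiffness,
            ezs_pos = ezs_pos, ezs_neg = ezs_neg)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("rom, nz_size and all stiffnesses must be finite and > 0",
         call. = FALSE)
  }
  if (rom <= nz_size) {
    stop("infeasible parameters: rom must exceed nz_size", call. = FALSE)
  }
  if (!inherits(protocol, "loading_protocol")) {
    stop("protocol must be a loading_protocol", call. = FALSE)
  }
  if (!is.finite(fillet_halfwidth) || fillet_halfwidth <= 0) {
    stop("fillet_halfwidth must be > 0", call. = FALSE)
  }
  structure(
    list(rom = rom, nz_size = nz_size, nz_stiffness = nz_stiffness,
         ezs_pos = ezs_pos, ezs_neg = ezs_neg,
         center_offset = center_offset,
         fillet_halfwidth = fillet_halfwidth,
         protocol = protocol),
    class = "backbone_params"
  )
}

#' @export
print.backbone_params <- function(x, ...) {
  cat(sprintf(paste0("<backbone_params> ROM %.3g deg, NZ %.3g deg @ %.3g Nm/deg, ",
                     "EZS %.3g/%.3g Nm/deg (%s)\n"),
              x$rom, x$nz_size, x$nz_stiffness, x$ezs_pos, x$ezs_neg,
              x$protocol$modality))
  invisible(x)
}

#' Construct the piecewise moment-rotation backbone for a parameter set
#'
#' Realises a set of target kinetic measures as an explicit rotation-to-moment
#' function with five zones: a central neutral zone of width `nz_size` and
#' slope `nz_stiffness` centred at `center_offset`, one constant-slope
#' transition zone per side, and outer elastic zones with slopes
#' `ezs_pos`/`ezs_neg` covering the moments between the elastic-zone band and
#' the moment limit. The transition slopes and widths are solved from the
#' moment budget (neutral-zone edge moment up to the elastic-zone band lower
#' bound) and the rotation budget (total span must equal `rom`), with the two
#' transition widths split in proportion to the elastic-zone compliances.
#' Each of the four slope corners is blended over `+/- fillet_halfwidth` with
#' a smoothstep slope profile, so the second derivative of the curve is a
#' single-peaked bump centred exactly at each corner and zero elsewhere. The
#' neutral-zone corners sit exactly at `center_offset +/- nz_size / 2`; the
#' transition/elastic-zone corners are pulled inward by the fillet allowance
#' (corner moment `band_low - ezs * f`) so that the blend finishes exactly at
#' the elastic-zone band's lower bound — the curve is then exactly linear
#' with slope `ezs_pos`/`ezs_neg` for every moment inside the band, while
#' the rotations at the moment limits keep their budget values, making all
#' five target measures exact by construction.
#'
#' @param params A [backbone_params()] object.
#' @return An object of class `fsu_backbone` with elements `knots` (the six
#'   zone-boundary rotations, degrees), `values` (moments at the knots, Nm),
#'   `slopes` (the five zone slopes, Nm/degree), `corners` (the four filleted
#'   corner rotations), `fillet_halfwidth`, `params` and `protocol`. The
#'   rotation at the positive and negative moment limits are `knots[6]` and
#'   `knots[1]`; their difference equals `rom` exactly.
#' @export
#' @examples
#' p <- backbone_params(rom = 8.15, nz_size = 2.53, nz_stiffness = 0.59,
#'                      ezs_pos = 4.18, ezs_neg = 5.76)
#' bb <- solve_backbone(p)
#' bb$knots[6] - bb$knots[1]  # = 8.15
solve_backbone <- function(params) {
  stopifnot(inherits(params, "backbone_params"))
  p <- params
  pr <- p$protocol
  limit <- pr$moment_limit
  band_low <- pr$ez_band[1]

  m0 <- p$nz_stiffness * p$nz_size / 2
  if (m0 >= band_low) {
    stop(sprintf(paste0("infeasible backbone: NZ-edge moment ",
                        "nz_stiffness * nz_size / 2 = %.4g Nm must be < the ",
                        "elastic-zone band lower bound %.4g Nm"),
                 m0, band_low), call. = FALSE)
  }
  ez_w_pos <- (limit - band_low) / p$ezs_pos
  ez_w_neg <- (limit - band_low) / p$ezs_neg
  w_total <- p$rom - p$nz_size - ez_w_pos - ez_w_neg
  if (w_total <= 0) {
    stop(sprintf(paste0("infeasible backbone: transition-width budget ",
                        "rom - nz_size - (limit - band_low)/ezs_pos - ",
                        "(limit - band_low)/ezs_neg = %.4g deg must be > 0"),
                 w_total), call. = FALSE)
  }
  comp_pos <- 1 / p$ezs_pos
  comp_neg <- 1 / p$ezs_neg
  w_pos <- w_total * comp_pos / (comp_pos + comp_neg)
  w_neg <- w_total - w_pos

  # The transition/EZ corner is pulled in by the fillet half-width f (in
  # rotation) and by ezs * f (in moment) so that the smoothstep blend
  # finishes exactly at the EZ band's lower bound: the curve is then exactly
  # linear with slope ezs for all moments in the band, and theta(+/-limit)
  # keeps the plain budget values nz/2 + w + (limit - band_low)/ezs.
  f <- p$fillet_halfwidth
  tw_pos <- w_pos - f
  tw_neg <- w_neg - f
  if (tw_pos <= f || tw_neg <= f) {
    stop(sprintf(paste0("infeasible backbone: transition width net of the ",
                        "fillet allowance (w_pos - f = %.4g, w_neg - f = ",
                        "%.4g deg) must exceed the fillet half-width %.4g"),
                 tw_pos, tw_neg, f), call. = FALSE)
  }
  mc_pos <- band_low - p$ezs_pos * f
  mc_neg <- band_low - p$ezs_neg * f
  if (mc_pos <= m0 || mc_neg <= m0) {
    stop(sprintf(paste0("infeasible backbone: corner moment band_low - ",
                        "ezs * f (%.4g / %.4g Nm) must exceed the NZ-edge ",
                        "moment %.4g Nm"), mc_pos, mc_neg, m0),
         call. = FALSE)
  }
  k_pos <- (mc_pos - m0) / tw_pos
  k_neg <- (mc_neg - m0) / tw_neg
  for (side in c("positive", "negative")) {
    k <- if (side == "positive") k_pos else k_neg
    ez <- if (side == "positive") p$ezs_pos else p$ezs_neg
    if (!(k > p$nz_stiffness && k < ez)) {
      stop(sprintf(paste0("infeasible backbone: %s transition slope %.4g ",
                          "Nm/deg must lie strictly between nz_stiffness ",
                          "%.4g and the elastic-zone slope %.4g"),
                   side, k, p$nz_stiffness, ez), call. = FALSE)
    }
  }

  c0 <- p$center_offset
  nz2 <- p$nz_size / 2
  knots <- c(c0 - nz2 - w_neg - ez_w_neg,
             c0 - nz2 - tw_neg,
             c0 - nz2,
             c0 + nz2,
             c0 + nz2 + tw_pos,
             c0 + nz2 + w_pos + ez_w_pos)
  values <- c(-limit, -mc_neg, -m0, m0, mc_pos, limit)
  slopes <- c(p$ezs_neg, k_neg, p$nz_stiffness, k_pos, p$ezs_pos)
  gaps <- diff(knots)  # widths of the five zones
  if (2 * f >= min(gaps[2:4]) || f >= gaps[1] || f >= gaps[5]) {
    stop(sprintf(paste0("infeasible backbone: fillet_halfwidth %.4g deg too ",
                        "large; fillets at the four zone corners would ",
                        "overlap (zone widths %s deg)"),
                 f, paste(signif(gaps, 4), collapse = ", ")), call. = FALSE)
  }

  structure(
    list(knots = knots, values = values, slopes = slopes,
         corners = knots[2:5], fillet_halfwidth = f,
         params = p, protocol = pr),
    class = "fsu_backbone"
  )
}

#' @export
print.fsu_backbone <- function(x, ...) {
  cat("<fsu_backbone>\n")
  cat(sprintf("  rotation at -/+%g Nm: %.4f / %.4f deg (ROM %.4f)\n",
              x$protocol$moment_limit, x$knots[1], x$knots[6],
              x$knots[6] - x$knots[1]))
  cat(sprintf("  zone slopes [Nm/deg]: %s\n",
              paste(signif(x$slopes, 5), collapse = ", ")))
  cat(sprintf("  fillet half-width: %.4g deg\n", x$fillet_halfwidth))
  invisible(x)
}

# Smoothstep helpers for corner fillets. u in [0, 1]:
# slope blend S(u) = 3u^2 - 2u^3, its integral Si(u) = u^3 - u^4/2,
# its derivative S'(u) = 6u(1-u).
.smoothstep <- function(u) 3 * u^2 - 2 * u^3
.smoothstep_int <- function(u) u^3 - u^4 / 2
.smoothstep_deriv <- function(u) 6 * u * (1 - u)

# Evaluate the un-filleted piecewise-linear backbone, extending the outer
# elastic-zone slopes beyond the knots.
.pl_moment <- function(bb, theta) {
  idx <- findInterval(theta, bb$knots, all.inside = TRUE)
  bb$values[idx] + bb$slopes[idx] * (theta - bb$knots[idx])
}

.pl_slope <- function(bb, theta) {
  idx <- findInterval(theta, bb$knots, all.inside = TRUE)
  bb$slopes[idx]
}

#' Evaluate a backbone's moment, slope or curvature at given rotations
#'
#' `backbone_moment()` returns the applied moment M(theta) in Nm,
#' `backbone_slope()` the first derivative dM/dtheta in Nm/degree and
#' `backbone_curvature()` the second derivative in Nm/degree^2. Outside the
#' knot range the outer elastic-zone slopes are extended linearly.
#'
#' @param backbone An `fsu_backbone` from [solve_backbone()].
#' @param theta Numeric vector of rotations in degrees.
#' @return Numeric vector, same length as `theta`.
#' @export
backbone_moment <- function(backbone, theta) {
  bb <- backbone
  f <- bb$fillet_halfwidth
  m <- .pl_moment(bb, theta)
  for (j in seq_along(bb$corners)) {
    x0 <- bb$corners[j]
    s_l <- bb$slopes[j]
    s_r <- bb$slopes[j + 1]
    in_f <- theta > (x0 - f) & theta < (x0 + f)
    if (any(in_f)) {
      th <- theta[in_f]
      u <- (th - (x0 - f)) / (2 * f)
      base <- .pl_moment(bb, x0 - f) + s_l * (th - (x0 - f))
      m[in_f] <- base + (s_r - s_l) * 2 * f * .smoothstep_int(u)
    }
  }
  m
}

#' @rdname backbone_moment
#' @export
backbone_slope <- function(backbone, theta) {
  bb <- backbone
  f <- bb$fillet_halfwidth
  s <- .pl_slope(bb, theta)
  for (j in seq_along(bb$corners)) {
    x0 <- bb$corners[j]
    s_l <- bb$slopes[j]
    s_r <- bb$slopes[j + 1]
    in_f <- theta > (x0 - f) & theta < (x0 + f)
    if (any(in_f)) {
      u <- (theta[in_f] - (x0 - f)) / (2 * f)
      s[in_f] <- s_l + (s_r - s_l) * .smoothstep(u)
    }
  }
  s
}

#' @rdname backbone_moment
#' @export
backbone_curvature <- function(backbone, theta) {
  bb <- backbone
  f <- bb$fillet_halfwidth
  cv <- numeric(length(theta))
  for (j in seq_along(bb$corners)) {
    x0 <- bb$corners[j]
    s_l <- bb$slopes[j]
    s_r <- bb$slopes[j + 1]
    in_f <- theta > (x0 - f) & theta < (x0 + f)
    if (any(in_f)) {
      u <- (theta[in_f] - (x0 - f)) / (2 * f)
      cv[in_f] <- (s_r - s_l) * .smoothstep_deriv(u) / (2 * f)
    }
  }
  cv
}

#' Rotation at which a backbone reaches a given moment
#'
#' Inverts the (strictly increasing) backbone moment function by bisection.
#'
#' @param backbone An `fsu_backbone`.
#' @param moment Numeric vector of moments in Nm.
#' @return Rotations in degrees.
#' @export
backbone_rotation_at <- function(backbone, moment) {
  bb <- backbone
  vapply(moment, function(m) {
    # the curve is exactly linear beyond the knots, so these brackets hold
    lo <- bb$knots[1] - 1 + min(0, (m - bb$values[1]) / bb$slopes[1])
    hi <- bb$knots[6] + 1 + max(0, (m - bb$values[6]) / bb$slopes[5])
    stats::uniroot(function(th) backbone_moment(bb, th) - m,
                   lower = lo, upper = hi, tol = 1e-12)$root
  }, numeric(1))
}
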