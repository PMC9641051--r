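# Shared fixtures: published-cell parameter sets and small builders.

ref_row <- function(cond, mod) {
  r <- dplyr::filter(reference_kinetics(), condition == cond, modality == mod)
  stopifnot(nrow(r) == 1)
  r
}

params_from_row <- function(r, ...) {
  backbone_params(r$rom, r$nz_size, r$nz_stiffness, r$ezs_pos, r$ezs_neg,
                  protocol = loading_protocol(r$modality), ...)
}

healthy_fe_backbone <- function(...) {
  solve_backbone(params_from_row(ref_row("intact", "flexion_extension"), ...))
}

cell_resolution <- function(mod) {
  if (mod == "axial_rotation") 0.001 else 0.005
}

# trapezoidal quadrature, used as an independent numerical oracle
trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

# small balanced repeated-measures table
toy_rm_table <- function(values) {
  k <- ncol(values)
  n <- nrow(values)
  tibble::tibble(
    specimen = rep(sprintf("S%d", seq_len(n)), each = k),
    condition = rep(c("intact", "defect", "treated")[seq_len(k)], times = n),
    value = as.vector(t(values))
  )
}
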