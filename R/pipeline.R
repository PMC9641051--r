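#' Configure a full simulate-extract-compare study
#'
#' @param cohort A [cohort_spec()]; carries the mandatory seed.
#' @param window,search_band,prominence_fraction Extraction options passed to
#'   [process_curve()].
#' @param alpha Significance level for the comparisons.
#' @param percent_method Percent-change convention (see [compare_groups()]).
#' @param output_dir Optional directory; when set, [run_study()] writes the
#'   CSV report there via [render_report()].
#' @return An object of class `study_config`.
#' @export
study_config <- function(cohort, window = NULL, search_band = NULL,
                         prominence_fraction = 0.25, alpha = 0.05,
                         percent_method = "group_means", output_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_spec"))
  structure(
    list(cohort = cohort, window = window, search_band = search_band,
         prominence_fraction = prominence_fraction, alpha = alpha,
         percent_method = percent_method, output_dir = output_dir),
    class = "study_config"
  )
}

#' Read a study configuration from a YAML file
#'
#' Supported keys: `seed` (required), `n_specimens`, `within_correlation`,
#' `hysteresis_halfwidth`, `loops`, `sd_scale` (multiplies every cell SD; 0
#' gives a degenerate cohort at the cell means), `noise` (list of
#' `modality: [sigma_rotation, sigma_moment]` overrides), `window`,
#' `search_band`, `prominence_fraction`, `alpha`, `percent_method`,
#' `output_dir`.
#'
#' @param path Path to the YAML file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must contain a seed", call. = FALSE)
  cells <- reference_kinetics()
  if (!is.null(cfg$sd_scale)) {
    sd_cols <- grep("_sd$", names(cells), value = TRUE)
    cells[sd_cols] <- lapply(cells[sd_cols], function(v) v * cfg$sd_scale)
  }
  noise <- default_noise()
  for (mod in names(cfg$noise %||% list())) {
    i <- match(mod, noise$modality)
    if (is.na(i)) stop("unknown modality in noise config: ", mod,
                       call. = FALSE)
    noise$sigma_rotation[i] <- cfg$noise[[mod]][[1]]
    noise$sigma_moment[i] <- cfg$noise[[mod]][[2]]
  }
  spec <- cohort_spec(
    cells = cells,
    n_specimens = cfg$n_specimens %||% 8,
    within_correlation = cfg$within_correlation %||% 0.8,
    noise = noise,
    hysteresis_halfwidth = cfg$hysteresis_halfwidth %||% 0.3,
    loops = cfg$loops %||% TRUE,
    seed = cfg$seed
  )
  study_config(
    cohort = spec, window = cfg$window, search_band = cfg$search_band,
    prominence_fraction = cfg$prominence_fraction %||% 0.25,
    alpha = cfg$alpha %||% 0.05,
    percent_method = cfg$percent_method %||% "group_means",
    output_dir = cfg$output_dir
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a complete study: simulate, extract, summarise, compare
#'
#' Generates the cohort, extracts the five kinetic measures from every
#' curve, produces a mean +/- SD summary per (condition, modality, measure),
#' runs the full comparison battery, and keeps the ground truth alongside
#' the estimates for recovery auditing. Fully reproducible from the config's
#' seed.
#'
#' @param config A [study_config()].
#' @return An object of class `study_outputs` with elements `truth`,
#'   `curves`, `estimates`, `summary`, `comparisons`, `config`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cohort <- generate_cohort(config$cohort)
  estimates <- extract_kinetics(
    cohort$curves, window = config$window,
    search_band = config$search_band,
    prominence_fraction = config$prominence_fraction,
    on_error = "na"
  )
  summary <- summarize_kinetics(estimates)
  comparisons <- compare_groups(
    pivot_measures(estimates), alpha = config$alpha,
    percent_method = config$percent_method
  )
  out <- structure(
    list(truth = cohort$truth, curves = cohort$curves,
         estimates = estimates, summary = summary,
         comparisons = comparisons, config = config),
    class = "study_outputs"
  )
  if (!is.null(config$output_dir)) {
    render_report(out, config$output_dir)
  }
  out
}

#' @export
print.study_outputs <- function(x, ...) {
  cat(sprintf("<study_outputs> %d curves, %d summary cells\n",
              nrow(x$estimates), nrow(x$summary)))
  invisible(x)
}

#' Summarise extracted kinetics per study cell
#'
#' @param estimates Output of [extract_kinetics()].
#' @return Tibble with one row per (condition, modality, measure): `mean`,
#'   `sd`, `n`.
#' @export
summarize_kinetics <- function(estimates) {
  pivot_measures(estimates) |>
    dplyr::group_by(.data$condition, .data$modality, .data$measure) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = stats::sd(.data$value, na.rm = TRUE),
                     n = sum(!is.na(.data$value)), .groups = "drop")
}

#' Audit parameter recovery against the simulator ground truth
#'
#' Joins the estimates to the ground-truth table by (specimen, condition,
#' modality) and reports per-curve and per-cell relative errors, with
#' pass/fail flags against the noiseless recovery criteria (1% relative for
#' the five measures, 1e-4 relative for ROM).
#'
#' @param outputs A `study_outputs`, or a list with `truth` and `estimates`.
#' @param rel_tol Relative tolerance for the five measures (default 0.01).
#' @param rom_tol Relative tolerance for ROM (default 1e-4).
#' @return A list with `per_curve` (long tibble of relative errors),
#'   `per_cell` (max/mean error per condition x modality x measure) and
#'   `pass` (logical).
#' @export
recovery_audit <- function(outputs, rel_tol = 0.01, rom_tol = 1e-4) {
  truth <- outputs$truth
  est <- outputs$estimates
  if (is.null(truth) || is.null(est)) {
    stop("outputs must contain both truth and estimates", call. = FALSE)
  }
  keys <- c("specimen_id", "condition", "modality")
  tl <- truth |>
    tidyr::pivot_longer(dplyr::all_of(.measure_names),
                        names_to = "measure", values_to = "truth")
  el <- pivot_measures(est) |>
    dplyr::rename(estimate = "value")
  if (nrow(dplyr::anti_join(tl, el, by = keys)) > 0 ||
      nrow(dplyr::anti_join(el, tl, by = keys)) > 0) {
    stop("mismatched identifiers between truth and estimates tables",
         call. = FALSE)
  }
  joined <- dplyr::full_join(tl, el, by = c(keys, "measure"))
  per_curve <- joined |>
    dplyr::mutate(
      rel_error = abs(.data$estimate - .data$truth) / abs(.data$truth),
      tol = ifelse(.data$measure == "rom", rom_tol, rel_tol),
      pass = !is.na(.data$rel_error) & .data$rel_error <= .data$tol
    )
  per_cell <- per_curve |>
    dplyr::group_by(.data$condition, .data$modality, .data$measure) |>
    dplyr::summarise(max_rel_error = max(.data$rel_error),
                     mean_rel_error = mean(.data$rel_error),
                     pass = all(.data$pass), .groups = "drop")
  list(per_curve = per_curve, per_cell = per_cell,
       pass = all(per_cell$pass))
}

#' Write study outputs to disk
#'
#' Writes the estimates, ground truth, cell summary and comparison report as
#' CSV files, and optionally one annotated moment-rotation plot per curve.
#' Nothing is written if the outputs are empty.
#'
#' @param outputs A `study_outputs`.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("csv", "plots")`.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(outputs, dir, formats = "csv") {
  stopifnot(inherits(outputs, "study_outputs") ||
              is.list(outputs))
  bad <- setdiff(formats, c("csv", "plots"))
  if (length(bad)) {
    stop("unknown report format(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(outputs$estimates) || !nrow(outputs$estimates)) {
    stop("empty outputs: nothing to render", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if ("csv" %in% formats) {
    files <- list(estimates = outputs$estimates, truth = outputs$truth,
                  summary = outputs$summary,
                  comparisons = outputs$comparisons)
    for (nm in names(files)) {
      if (is.null(files[[nm]])) next
      p <- file.path(dir, paste0(nm, ".csv"))
      readr::write_csv(tibble::as_tibble(files[[nm]]), p)
      paths <- c(paths, p)
    }
  }
  if ("plots" %in% formats) {
    pdir <- file.path(dir, "plots")
    dir.create(pdir, showWarnings = FALSE)
    curves <- outputs$curves
    ids <- dplyr::distinct(curves, .data$specimen_id, .data$condition,
                           .data$modality)
    for (i in seq_len(nrow(ids))) {
      cv <- dplyr::semi_join(curves, ids[i, ],
                             by = c("specimen_id", "condition", "modality"))
      res <- process_curve(cv)
      p <- file.path(pdir, sprintf("%s_%s_%s.png", ids$specimen_id[i],
                                   ids$condition[i], ids$modality[i]))
      ggplot2::ggsave(p, plot_moment_rotation(cv, res),
                      width = 6, height = 4, dpi = 120)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Write / read a long curve table as CSV
#'
#' @param curves Curve tibble (`moment_Nm`, `rotation_deg`, `branch`,
#'   `specimen_id`, `condition`, `modality`).
#' @param path File path.
#' @return `read_curves` returns the curve tibble; `write_curves` its path,
#'   invisibly.
#' @export
write_curves <- function(curves, path) {
  readr::write_csv(curves, path)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    rotation_deg = "d", moment_Nm = "d", branch = "c",
                    specimen_id = "c", condition = "c", modality = "c"
                  ))
}
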