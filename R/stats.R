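#' Anderson-Darling normality test
#'
#' Anderson-Darling A-squared statistic for the normal family with estimated
#' mean and SD (composite null), with the usual small-sample correction and
#' p-value for that case.
#'
#' @param values Numeric vector, `n >= 5`, non-constant.
#' @return A one-row tibble: `a2` (the uncorrected statistic), `a2_corrected`
#'   (small-sample corrected), `p_value`, `n`.
#' @export
#' @examples
#' anderson_darling(rnorm(20))
anderson_darling <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 5) stop("anderson_darling requires n >= 5", call. = FALSE)
  if (stats::sd(values) == 0) {
    stop("anderson_darling undefined for constant input (zero SD)",
         call. = FALSE)
  }
  # direct order-statistic formula for the composite-normal case, with the
  # standard small-sample correction and p-value map (valid from n = 5;
  # cross-checked against nortest::ad.test in the test suite)
  z <- sort((values - mean(values)) / stats::sd(values))
  logp <- stats::pnorm(z, log.p = TRUE)
  logq <- stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)
  i <- seq_len(n)
  a2 <- -n - mean((2 * i - 1) * (logp + rev(logq)))
  aa <- a2 * (1 + 0.75 / n + 2.25 / n^2)
  p <- if (aa < 0.2) {
    1 - exp(-13.436 + 101.14 * aa - 223.73 * aa^2)
  } else if (aa < 0.34) {
    1 - exp(-8.318 + 42.796 * aa - 59.938 * aa^2)
  } else if (aa < 0.6) {
    exp(0.9177 - 4.279 * aa - 1.38 * aa^2)
  } else if (aa < 10) {
    exp(1.2937 - 5.709 * aa + 0.0186 * aa^2)
  } else {
    3.7e-24
  }
  tibble::tibble(a2 = a2, a2_corrected = aa, p_value = p, n = n)
}

#' Levene's test for equality of variances
#'
#' Levene's W: a one-way ANOVA on the absolute deviations of each value from
#' its group centre (mean by default; the Brown-Forsythe median variant is
#' selectable).
#'
#' @param values Numeric vector.
#' @param group Grouping vector, coerced to factor; at least 2 groups of at
#'   least 3 non-degenerate values each.
#' @param center `"mean"` (classic Levene, default) or `"median"`.
#' @return A one-row tibble: `statistic` (W), `df1`, `df2`, `p_value`.
#' @export
levene_test <- function(values, group, center = c("mean", "median")) {
  center <- match.arg(center)
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(group)
  if (any(sizes < 3)) {
    stop("every group needs at least 3 values", call. = FALSE)
  }
  sds <- tapply(values, group, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate group (zero variance): Levene's test undefined",
         call. = FALSE)
  }
  lt <- car::leveneTest(values, group,
                        center = if (center == "mean") mean else stats::median)
  tibble::tibble(
    statistic = lt[["F value"]][1],
    df1 = lt[["Df"]][1],
    df2 = lt[["Df"]][2],
    p_value = lt[["Pr(>F)"]][1],
    center = center
  )
}

#' One-way repeated-measures analysis of variance
#'
#' Within-subjects ANOVA with a single condition factor: the total sum of
#' squares is partitioned into subjects, condition and error (subject x
#' condition) strata via `stats::aov` with an `Error(specimen)` term, and
#' `F = MS_condition / MS_error` is referred to an F distribution on
#' `(k - 1, (k - 1)(n - 1))` degrees of freedom. Degenerate decompositions
#' are guarded: zero condition sum of squares gives `F = 0, p = 1`; zero
#' error sum of squares (with a non-zero effect) gives `F = Inf, p = 0`.
#'
#' @param data Long data frame with one value per (specimen, condition).
#' @param value,condition,specimen Bare column names (tidy evaluation).
#' @return An object of class `rm_anova`; see [tidy.rm_anova()] and
#'   [glance.rm_anova()]. Contains the condition means and the error-term
#'   mean square reused by [tukey_posthoc()].
#' @export
#' @examples
#' df <- tidyr::expand_grid(specimen = sprintf("S%d", 1:4),
#'                          condition = c("intact", "defect", "treated"))
#' df$value <- rnorm(nrow(df))
#' fit <- rm_anova(df, value, condition, specimen)
#' glance(fit)
rm_anova <- function(data, value, condition, specimen) {
  cond_raw <- dplyr::pull(data, {{ condition }})
  canonical <- c("intact", "defect", "treated")
  lev <- if (all(cond_raw %in% canonical)) {
    intersect(canonical, unique(cond_raw))
  } else {
    sort(unique(cond_raw))
  }
  df <- tibble::tibble(
    y = dplyr::pull(data, {{ value }}),
    cond = factor(cond_raw, levels = lev),
    subj = factor(dplyr::pull(data, {{ specimen }}))
  )
  if (any(!is.finite(df$y))) stop("non-finite values", call. = FALSE)
  counts <- table(df$subj, df$cond)
  if (any(counts != 1)) {
    bad <- which(counts == 0, arr.ind = TRUE)
    if (nrow(bad)) {
      cells <- apply(bad, 1, function(r) {
        sprintf("%s:%s", rownames(counts)[r[1]], colnames(counts)[r[2]])
      })
      stop("unbalanced design; missing cells: ",
           paste(cells, collapse = ", "), call. = FALSE)
    }
    stop("unbalanced design: duplicated (specimen, condition) cells",
         call. = FALSE)
  }
  k <- nlevels(df$cond)
  n <- nlevels(df$subj)

  fit <- stats::aov(y ~ cond + Error(subj), data = df)
  within <- summary(fit)[["Error: Within"]][[1]]
  ss_cond <- within["cond", "Sum Sq"]
  ss_err <- within["Residuals", "Sum Sq"]
  subj_tab <- summary(fit)[["Error: subj"]][[1]]
  ss_subj <- subj_tab["Residuals", "Sum Sq"]

  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)
  scale <- ss_cond + ss_err + ss_subj
  eps <- 1e-12 * max(scale, .Machine$double.xmin)
  if (ss_cond <= eps) {
    f <- 0
    p <- 1
  } else if (ss_err <= eps) {
    f <- Inf
    p <- 0
  } else {
    f <- (ss_cond / df1) / (ss_err / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  means <- tapply(df$y, df$cond, mean)
  structure(
    list(f = f, df1 = df1, df2 = df2, p_value = p,
         ss = c(subjects = ss_subj, condition = ss_cond, error = ss_err),
         ms_error = ss_err / df2, n_subjects = n, k = k,
         means = means, data = df),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova> F(%d, %d) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$f, x$p_value))
  invisible(x)
}

#' @rdname rm_anova
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @export
tidy.rm_anova <- function(x, ...) {
  tibble::tibble(
    term = c("subjects", "condition", "error"),
    df = c(x$n_subjects - 1L, x$df1, x$df2),
    sumsq = unname(x$ss),
    meansq = unname(x$ss) / c(x$n_subjects - 1L, x$df1, x$df2),
    statistic = c(NA, x$f, NA),
    p.value = c(NA, x$p_value, NA)
  )
}

#' @rdname rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(statistic = x$f, df1 = x$df1, df2 = x$df2,
                 p.value = x$p_value, n_subjects = x$n_subjects)
}

#' Tukey HSD post hoc comparisons on the within-subjects error term
#'
#' All pairwise condition comparisons using the studentized-range
#' distribution, with the repeated-measures error mean square and degrees of
#' freedom: `q = |mean_i - mean_j| / sqrt(MS_error / n)`.
#'
#' @param fit An [rm_anova()] object.
#' @return A tibble with one row per pair: `contrast`, `estimate` (mean
#'   difference), `q`, `adj_p_value`.
#' @export
tukey_posthoc <- function(fit) {
  stopifnot(inherits(fit, "rm_anova"))
  means <- fit$means
  lev <- names(means)
  n <- fit$n_subjects
  se <- sqrt(fit$ms_error / n)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    diff <- means[[pr[2]]] - means[[pr[1]]]
    if (se == 0) {
      q <- if (diff == 0) 0 else Inf
      p <- if (diff == 0) 1 else 0
    } else {
      q <- abs(diff) / se
      p <- stats::ptukey(q, nmeans = fit$k, df = fit$df2, lower.tail = FALSE)
    }
    tibble::tibble(contrast = paste(pr[2], "-", pr[1]),
                   estimate = diff, q = q, adj_p_value = p)
  })
}

#' One-sample Student's t-test of a group against a single value
#'
#' Two-sided t-test of a sample (e.g. a cadaveric study group) against a
#' single hypothesised mean (e.g. one in-vivo measurement).
#'
#' @param values Numeric sample, `n >= 3`, non-constant.
#' @param hypothesized_mean The single value tested against.
#' @return A one-row tibble: `estimate`, `statistic` (t), `df`, `p_value`,
#'   `hypothesized_mean`.
#' @export
one_sample_t <- function(values, hypothesized_mean) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("one_sample_t requires n >= 3", call. = FALSE)
  if (stats::sd(values) == 0) {
    stop("one_sample_t undefined for a constant sample", call. = FALSE)
  }
  tt <- stats::t.test(values, mu = hypothesized_mean)
  tibble::tibble(
    estimate = unname(tt$estimate),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    hypothesized_mean = hypothesized_mean
  )
}

#' Percent change relative to a reference
#'
#' `100 * (value - reference) / reference`, the convention used for
#' reporting defect/treated changes relative to the intact condition.
#'
#' @param value,reference Numeric (vectorised); `reference` must be nonzero.
#' @return Percent change.
#' @export
percent_change <- function(value, reference) {
  if (any(reference == 0)) {
    stop("percent change undefined for a zero reference", call. = FALSE)
  }
  100 * (value - reference) / reference
}

#' Run the full group-comparison battery over extracted kinetics
#'
#' For every (measure, modality) cell of a long measure table:
#' Anderson-Darling normality per condition group, Levene's variance test,
#' one-way repeated-measures ANOVA across conditions, Tukey post hoc
#' pairwise comparisons, group means/SDs, and percent changes of the defect
#' and treated groups relative to intact. Normality/variance check failures
#' are reported, not acted upon. Degenerate checks (e.g. a zero-variance
#' group) yield `NA` for that check rather than aborting the battery.
#'
#' @param measures Long tibble with columns `specimen_id`, `condition`
#'   (subset of intact/defect/treated), `modality`, `measure`, `value` — as
#'   produced by [pivot_measures()] from [extract_kinetics()] output.
#' @param alpha Significance level (default 0.05).
#' @param reference Reference condition for percent change (default
#'   `"intact"`).
#' @param percent_method `"group_means"` (ratio of group means, default) or
#'   `"paired"` (mean of per-specimen percent changes).
#' @return A tibble of class `comparison_report`, one row per (measure,
#'   modality), with test statistics, Tukey adjusted p-values per pair,
#'   means, percent changes and significance flags; `alpha` is stored as an
#'   attribute.
#' @export
compare_groups <- function(measures, alpha = 0.05, reference = "intact",
                           percent_method = c("group_means", "paired")) {
  percent_method <- match.arg(percent_method)
  need <- c("specimen_id", "condition", "modality", "measure", "value")
  stopifnot(all(need %in% names(measures)))
  allowed <- c("intact", "defect", "treated")
  if (!all(measures$condition %in% allowed)) {
    stop("conditions must be a subset of {intact, defect, treated}",
         call. = FALSE)
  }
  dup <- measures |>
    dplyr::count(.data$specimen_id, .data$condition, .data$modality,
                 .data$measure) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop("more than one value per (specimen, condition, modality, measure)",
         call. = FALSE)
  }

  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  measures <- dplyr::filter(measures, !is.na(.data$value))

  rows <- measures |>
    dplyr::group_by(.data$measure, .data$modality) |>
    dplyr::group_modify(function(df, key) {
      conds <- intersect(allowed, unique(df$condition))
      ad <- purrr::map_dbl(stats::setNames(conds, conds), function(cn) {
        safe(anderson_darling(df$value[df$condition == cn])$p_value)
      })
      lev <- tryCatch(levene_test(df$value, df$condition),
                      error = function(e) {
                        tibble::tibble(statistic = NA_real_, df1 = NA,
                                       df2 = NA, p_value = NA_real_)
                      })
      fit <- tryCatch(rm_anova(df, value, condition, specimen_id),
                      error = function(e) NULL)
      tk <- if (is.null(fit)) NULL else tukey_posthoc(fit)
      pick <- function(a, b) {
        if (is.null(tk)) return(NA_real_)
        hit <- tk$adj_p_value[tk$contrast %in%
                                c(paste(a, "-", b), paste(b, "-", a))]
        if (length(hit)) hit[1] else NA_real_
      }
      fget <- function(field) if (is.null(fit)) NA_real_ else fit[[field]]
      means <- tapply(df$value, df$condition, mean)
      sds <- tapply(df$value, df$condition, stats::sd)
      gm <- function(cn) if (cn %in% names(means)) means[[cn]] else NA_real_
      gs <- function(cn) if (cn %in% names(sds)) sds[[cn]] else NA_real_
      pct <- function(cn) {
        if (!cn %in% conds || !reference %in% conds) return(NA_real_)
        if (percent_method == "group_means") {
          percent_change(gm(cn), gm(reference))
        } else {
          wide <- df |>
            dplyr::filter(.data$condition %in% c(cn, reference)) |>
            tidyr::pivot_wider(id_cols = "specimen_id",
                               names_from = "condition",
                               values_from = "value")
          mean(percent_change(wide[[cn]], wide[[reference]]))
        }
      }
      tibble::tibble(
        ad_p_intact = ad[["intact"]],
        ad_p_defect = if ("defect" %in% conds) ad[["defect"]] else NA_real_,
        ad_p_treated = if ("treated" %in% conds) ad[["treated"]] else NA_real_,
        levene_stat = lev$statistic, levene_p = lev$p_value,
        f = fget("f"), df1 = fget("df1"), df2 = fget("df2"),
        p_anova = fget("p_value"),
        p_defect_intact = pick("defect", "intact"),
        p_treated_intact = pick("treated", "intact"),
        p_treated_defect = pick("treated", "defect"),
        mean_intact = gm("intact"), sd_intact = gs("intact"),
        mean_defect = gm("defect"), sd_defect = gs("defect"),
        mean_treated = gm("treated"), sd_treated = gs("treated"),
        pct_defect = pct("defect"), pct_treated = pct("treated")
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      sig_defect_intact = .data$p_defect_intact < alpha,
      sig_treated_intact = .data$p_treated_intact < alpha,
      sig_treated_defect = .data$p_treated_defect < alpha
    )
  attr(rows, "alpha") <- alpha
  attr(rows, "percent_method") <- percent_method
  class(rows) <- c("comparison_report", class(rows))
  rows
}

#' Count significantly altered measures per comparison pair
#'
#' Given a full comparison report (normally 5 measures x 3 modalities = 15
#' cells), counts, per condition pair, the cells whose Tukey-adjusted
#' p-value falls below `alpha`.
#'
#' @param report A `comparison_report` from [compare_groups()].
#' @param alpha Significance level; defaults to the report's own alpha.
#' @return A tibble with `comparison` and `n_significant`.
#' @export
significance_summary <- function(report, alpha = NULL) {
  stopifnot(inherits(report, "comparison_report"))
  if (is.null(alpha)) alpha <- attr(report, "alpha")
  tibble::tibble(
    comparison = c("defect_vs_intact", "treated_vs_intact",
                   "treated_vs_defect"),
    n_significant = c(
      sum(report$p_defect_intact < alpha, na.rm = TRUE),
      sum(report$p_treated_intact < alpha, na.rm = TRUE),
      sum(report$p_treated_defect < alpha, na.rm = TRUE)
    ),
    n_cells = nrow(report)
  )
}

#' Pivot extracted kinetics to the long measure-table format
#'
#' @param estimates Output of [extract_kinetics()] (one row per curve).
#' @return Long tibble with `specimen_id`, `condition`, `modality`,
#'   `measure`, `value` for the five kinetic measures.
#' @export
pivot_measures <- function(estimates) {
  estimates |>
    dplyr::select("specimen_id", "condition", "modality",
                  dplyr::all_of(c("rom", "nz_size", "nz_stiffness",
                                  "ezs_pos", "ezs_neg"))) |>
    tidyr::pivot_longer(cols = c("rom", "nz_size", "nz_stiffness",
                                 "ezs_pos", "ezs_neg"),
                        names_to = "measure", values_to = "value")
}
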