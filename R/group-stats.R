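#' Mann-Whitney U test for one edge
#'
#' Two-sided Mann-Whitney U comparing case and control coherence values
#' for one channel pair. `U` is the statistic for the case sample
#' (rank-sum with midranks for ties, minus `n_case (n_case + 1) / 2`).
#' The p-value uses exact enumeration when `n_case * n_control <= 100`
#' and there are no ties, and otherwise the normal approximation with
#' tie and continuity corrections.
#'
#' @param values_case,values_control Numeric vectors (>= 2 values each).
#' @return Named list with `U` and `p`.
#' @examples
#' mann_whitney_edge(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney_edge <- function(values_case, values_control) {
  nx <- length(values_case); ny <- length(values_control)
  if (nx < 2 || ny < 2) abort("Both groups need at least 2 values.")
  ties <- anyDuplicated(c(values_case, values_control)) > 0
  exact <- !ties && nx * ny <= 100
  wt <- suppressWarnings(
    wilcox.test(values_case, values_control, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment
#' `q_(i) = min_{j >= i} (m p_(j) / j)`, clipped at 1, returned in
#' input order.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Numeric vector of adjusted q-values, same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Edge-wise two-group comparison of coherence profiles
#'
#' For every unordered channel pair in every requested (band,
#' condition) cell: the Mann-Whitney U test between case and control
#' subjects' band coherence, BH-corrected within that cell's family of
#' all pairs (the paper-standard family scope; set `family = "global"`
#' to correct across all cells jointly for sensitivity analysis).
#' Group medians and the effect direction are attached.
#'
#' @param profiles Long profile tibble from [cohort_coherence()] /
#'   [coherence_profile()], containing both groups.
#' @param bands,conditions Optional character filters; default all
#'   present.
#' @param family `"cell"` (BH per band x condition) or `"global"`.
#' @return Tibble with columns `band`, `condition`, `chan_i`, `chan_j`,
#'   `U`, `p`, `q`, `median_case`, `median_control`, `direction`
#'   (`"case_deficit"`, `"case_excess"` or `"none"`).
#' @export
edgewise_comparison <- function(profiles, bands = NULL, conditions = NULL,
                                family = c("cell", "global")) {
  family <- match.arg(family)
  if (!is.null(bands)) profiles <- dplyr::filter(profiles, .data$band %in% bands)
  if (!is.null(conditions)) {
    profiles <- dplyr::filter(profiles, .data$condition %in% conditions)
  }
  groups <- unique(profiles$group)
  if (!all(c("case", "control") %in% groups)) {
    abort("Profiles must contain both a case and a control group.")
  }
  n_subj <- profiles |>
    dplyr::distinct(.data$subject_id, .data$group) |>
    dplyr::count(.data$group)
  if (any(n_subj$n < 2)) abort("Need at least 2 subjects per group.")

  # consistent channel lists across subjects
  pair_counts <- profiles |>
    dplyr::distinct(.data$subject_id, .data$chan_i, .data$chan_j) |>
    dplyr::count(.data$subject_id)
  if (length(unique(pair_counts$n)) != 1) {
    abort("Subjects have mismatched channel pair sets; align montages first.")
  }

  res <- profiles |>
    dplyr::summarise(
      test = list(mann_whitney_edge(.data$coherence[.data$group == "case"],
                                    .data$coherence[.data$group == "control"])),
      median_case = median(.data$coherence[.data$group == "case"]),
      median_control = median(.data$coherence[.data$group == "control"]),
      .by = c("band", "condition", "chan_i", "chan_j")) |>
    dplyr::mutate(U = vapply(.data$test, `[[`, 0, "U"),
                  p = vapply(.data$test, `[[`, 0, "p")) |>
    dplyr::select(-"test")
  if (family == "cell") {
    res <- res |>
      dplyr::mutate(q = bh_fdr(.data$p), .by = c("band", "condition"))
  } else {
    res <- dplyr::mutate(res, q = bh_fdr(.data$p))
  }
  res |>
    dplyr::mutate(direction = dplyr::case_when(
      median_case < median_control ~ "case_deficit",
      median_case > median_control ~ "case_excess",
      TRUE ~ "none")) |>
    dplyr::relocate("q", .after = "p")
}

#' Pooled two-sample t from summary statistics
#'
#' Independent-sample pooled-variance t-statistic recomputed from group
#' means, standard deviations and sizes, with
#' `df = n_case + n_control - 2`. The sign convention is
#' control-minus-case: negative when the case (burnout) mean exceeds
#' the control mean.
#'
#' @param m_case,sd_case,n_case Case-group mean, SD, size.
#' @param m_control,sd_control,n_control Control-group mean, SD, size.
#' @return Named list with `t` and `df`.
#' @examples
#' t_from_summary(4.13, 1.00, 49, 1.93, 0.75, 49)  # t approx -12.32
#' @export
t_from_summary <- function(m_case, sd_case, n_case,
                           m_control, sd_control, n_control) {
  stopifnot(sd_case >= 0, sd_control >= 0, n_case >= 2, n_control >= 2)
  if (sd_case == 0 && sd_control == 0) {
    abort("Degenerate summary: both SDs are zero.")
  }
  df <- n_case + n_control - 2
  sp <- sqrt(((n_case - 1) * sd_case^2 + (n_control - 1) * sd_control^2) / df)
  se <- sp * sqrt(1 / n_case + 1 / n_control)
  list(t = (m_control - m_case) / se, df = df)
}

#' Questionnaire summary-statistics table
#'
#' Group summary statistics (mean, SD, n = 49 per group) for age, the
#' MBI-GS burnout subscales (exhaustion, cynicism, professional
#' efficacy) and BDI depression, for a matched burnout / control
#' employee cohort. Shipped as reference input for recomputing the
#' group t-tests (see [t_from_summary()]) in examples and the
#' acceptance script.
#'
#' @return Tibble with columns `scale`, `m_case`, `sd_case`, `n_case`,
#'   `m_control`, `sd_control`, `n_control`.
#' @export
questionnaire_summaries <- function() {
  tibble::tribble(
    ~scale,       ~m_case, ~sd_case, ~n_case, ~m_control, ~sd_control, ~n_control,
    "age",          34.94,     8.45,      49,      37.37,        7.63,         49,
    "exhaustion",    4.13,     1.00,      49,       1.93,        0.75,         49,
    "cynicism",      4.02,     0.87,      49,       1.44,        0.65,         49,
    "efficacy",      3.37,     1.13,      49,       4.60,        0.63,         49,
    "depression",   14.04,     7.61,      49,       4.76,        4.72,         49)
}

#' Recompute group t-tests from a summary table
#'
#' Applies [t_from_summary()] row-wise to a summary-statistics tibble.
#'
#' @param stats Tibble as from [questionnaire_summaries()].
#' @return The input with `t` and `df` columns appended.
#' @export
summary_t_table <- function(stats = questionnaire_summaries()) {
  out <- purrr::pmap(
    stats[c("m_case", "sd_case", "n_case",
            "m_control", "sd_control", "n_control")],
    t_from_summary)
  stats |>
    dplyr::mutate(t = vapply(out, `[[`, 0, "t"),
                  df = vapply(out, `[[`, 0, "df"))
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`
#' for a subjects x items score matrix.
#'
#' @param item_scores Numeric matrix, subjects in rows, items in
#'   columns (>= 2 of each).
#' @return Scalar alpha.
#' @export
cronbach_alpha <- function(item_scores) {
  item_scores <- as.matrix(item_scores)
  k <- ncol(item_scores)
  if (k < 2 || nrow(item_scores) < 2) abort("Need >= 2 items and >= 2 subjects.")
  total_var <- var(rowSums(item_scores))
  if (total_var == 0) abort("Degenerate: total score has zero variance.")
  k / (k - 1) * (1 - sum(apply(item_scores, 2, var)) / total_var)
}
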