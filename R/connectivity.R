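#' Group-level median coherence matrix
#'
#' Element-wise median of one band x condition coherence matrix across
#' the subjects of one group. Even subject counts use the midpoint of
#' the two central order statistics (the standard median convention),
#' so the result is bit-reproducible.
#'
#' @param profiles Long profile tibble (see [cohort_coherence()]).
#' @param group,condition,band Cell selectors.
#' @return Symmetric channels x channels matrix with unit diagonal.
#' @export
group_median <- function(profiles, group, condition, band) {
  sub <- profiles[profiles$group == group &
                    profiles$condition == condition &
                    profiles$band == band, ]
  if (!nrow(sub)) abort("No profiles match this (group, condition, band).")
  per_subj <- sub |>
    dplyr::count(.data$subject_id)
  if (length(unique(per_subj$n)) != 1) {
    abort("Subjects have mismatched channel lists; cannot take an edge-wise median.")
  }
  med <- sub |>
    dplyr::summarise(coherence = median(.data$coherence),
                     .by = c("chan_i", "chan_j"))
  profile_matrix(med)
}

#' Thresholded group connectivity graph
#'
#' Edge set of channel pairs whose group-median coherence is at or
#' above the threshold. Thresholding is monotone: the 0.7-graph's edges
#' are always a subset of the 0.5-graph's.
#'
#' @param median_matrix Symmetric median coherence matrix
#'   (see [group_median()]).
#' @param threshold Coherence cutoff in \[0, 1\]; ties at the boundary
#'   are kept (`>=`).
#' @param group,condition,band Optional metadata carried on the object.
#' @return An object of class `"group_graph"`: list with `edges`
#'   (tibble `chan_i`, `chan_j`, `median`), `median_matrix`,
#'   `threshold` and the metadata.
#' @export
threshold_graph <- function(median_matrix, threshold,
                            group = NA, condition = NA, band = NA) {
  if (threshold < 0 || threshold > 1) abort("`threshold` must be in [0, 1].")
  labels <- rownames(median_matrix)
  pairs <- channel_pairs(labels)
  med <- median_matrix[cbind(match(pairs$chan_i, labels),
                             match(pairs$chan_j, labels))]
  edges <- pairs |>
    dplyr::mutate(median = med) |>
    dplyr::filter(.data$median >= threshold)
  structure(list(edges = edges, median_matrix = median_matrix,
                 threshold = threshold, group = group,
                 condition = condition, band = band),
            class = "group_graph")
}

#' @export
print.group_graph <- function(x, ...) {
  cat(sprintf("<group_graph> %s/%s/%s: %d edge(s) with median coherence >= %g (of %d pairs)\n",
              x$group, x$condition, x$band, nrow(x$edges), x$threshold,
              nrow(channel_pairs(rownames(x$median_matrix)))))
  invisible(x)
}

#' Significant-difference graph
#'
#' Edges where the FDR-adjusted q-value is at or below the cutoff and
#' the case-group median is below the control median (case-deficit
#' direction, the convention for "weaker connectivity in the case
#' group"). Pairs significant in the opposite direction are kept
#' separately in `$excess_edges` and reported with a message.
#'
#' @param test_results [edgewise_comparison()] tibble restricted to one
#'   band x condition cell.
#' @param q_cutoff FDR significance cutoff in (0, 1), default 0.05.
#' @return An object of class `"difference_graph"`: list with `edges`
#'   (deficit direction, carrying `q`), `excess_edges`, `q_cutoff`,
#'   `condition`, `band`.
#' @export
difference_graph <- function(test_results, q_cutoff = 0.05) {
  if (q_cutoff <= 0 || q_cutoff >= 1) abort("`q_cutoff` must be in (0, 1).")
  cell <- dplyr::distinct(test_results, .data$band, .data$condition)
  if (nrow(cell) != 1) {
    abort("`test_results` must cover exactly one (band, condition) cell.")
  }
  sig <- dplyr::filter(test_results, .data$q <= q_cutoff)
  deficit <- dplyr::filter(sig, .data$median_case < .data$median_control)
  excess <- dplyr::filter(sig, .data$median_case > .data$median_control)
  if (nrow(excess)) {
    inform(sprintf("%s/%s: %d significant edge(s) in the case-excess direction (kept separately).",
                   cell$band, cell$condition, nrow(excess)))
  }
  structure(list(edges = deficit, excess_edges = excess,
                 q_cutoff = q_cutoff, condition = cell$condition,
                 band = cell$band),
            class = "difference_graph")
}

#' @export
print.difference_graph <- function(x, ...) {
  cat(sprintf("<difference_graph> %s/%s: %d case-deficit edge(s) at q <= %g (%d case-excess)\n",
              x$band, x$condition, nrow(x$edges), x$q_cutoff,
              nrow(x$excess_edges)))
  invisible(x)
}

#' Region-pair summary of a difference graph
#'
#' Counts significant difference edges per scalp region pair (including
#' within-region) and normalises by the number of available channel
#' pairs, giving a topographic density in \[0, 1\].
#'
#' @param dg A [difference_graph()].
#' @param montage The [montage()] the tests were run on.
#' @return Tibble with columns `region_i`, `region_j`, `n_edges`,
#'   `n_pairs`, `density` (region pairs ordered with
#'   `region_i <= region_j`).
#' @export
region_summary <- function(dg, montage) {
  reg <- stats::setNames(montage$region, montage$label)
  all_pairs <- channel_pairs(montage)
  used <- unique(c(dg$edges$chan_i, dg$edges$chan_j))
  untagged <- used[is.na(reg[used])]
  if (length(untagged)) {
    abort(paste0("Channels without region tags: ",
                 paste(untagged, collapse = ", ")))
  }
  canon <- function(a, b) {
    tibble::tibble(region_i = pmin(a, b), region_j = pmax(a, b))
  }
  avail <- dplyr::bind_cols(canon(unname(reg[all_pairs$chan_i]),
                                  unname(reg[all_pairs$chan_j]))) |>
    dplyr::count(.data$region_i, .data$region_j, name = "n_pairs")
  hits <- if (nrow(dg$edges)) {
    dplyr::bind_cols(canon(unname(reg[dg$edges$chan_i]),
                           unname(reg[dg$edges$chan_j]))) |>
      dplyr::count(.data$region_i, .data$region_j, name = "n_edges")
  } else {
    tibble::tibble(region_i = character(), region_j = character(),
                   n_edges = integer())
  }
  avail |>
    dplyr::left_join(hits, by = c("region_i", "region_j")) |>
    dplyr::mutate(n_edges = dplyr::coalesce(.data$n_edges, 0L),
                  density = .data$n_edges / .data$n_pairs) |>
    dplyr::relocate("n_edges", .before = "n_pairs")
}
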