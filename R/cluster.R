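#' Cluster a cell-line panel into radiosensitivity cohorts from SF3.5
#'
#' Agglomerative hierarchical clustering (Euclidean distance, average/UPGMA
#' linkage, via [stats::hclust()]) on the one-dimensional SF3.5 values, with
#' the tree cut to exactly `k` clusters. Cohort labels are assigned by
#' ascending cluster-mean SF3.5 — the lowest-survival cluster is S
#' (sensitive), the highest is R (resistant) — so the ordering is
#' well-defined regardless of dendrogram leaf order. SF3.5 is clustered raw
#' (unscaled): the feature is univariate, so standardisation would only
#' rescale every pairwise distance.
#'
#' @param panel Data frame with columns `cell_line` and `sf35` (e.g.
#'   [hnscc_panel()]).
#' @param k Number of cohorts; default 4 (S/MS/MR/R). With other `k`, labels
#'   are `G1 < G2 < ...` in ascending mean SF3.5.
#'
#' @return A `sensitivity_grouping` object: list with `assignments` (tibble
#'   `cell_line, sf35, group`), `group_means` (tibble `group, mean_sf35, n`)
#'   and `hclust` (the merge history). `tidy()` returns the assignments.
#' @examples
#' grouping <- cluster_sf35(hnscc_panel())
#' tidy(grouping)
#' @export
cluster_sf35 <- function(panel, k = 4) {
  stopifnot(all(c("cell_line", "sf35") %in% names(panel)))
  if (anyDuplicated(panel$cell_line)) {
    rlang::abort("Duplicate cell-line names in `panel`.")
  }
  if (!all(is.finite(panel$sf35))) rlang::abort("`sf35` values must be finite.")
  n <- nrow(panel)
  if (k > n) rlang::abort("`k` must not exceed the number of cell lines.")
  if (k < 1) rlang::abort("`k` must be >= 1.")

  x <- panel$sf35
  names(x) <- panel$cell_line
  if (n == 1 || k == n) {
    membership <- seq_len(n)
    hc <- NULL
    if (n > 1) hc <- stats::hclust(stats::dist(x), method = "average")
  } else {
    hc <- stats::hclust(stats::dist(x), method = "average")
    membership <- stats::cutree(hc, k = k)
  }

  means <- tapply(x, membership, mean)
  ord <- order(means) # cluster ids in ascending mean SF3.5
  labels <- if (k == 4) sensitivity_levels() else sprintf("G%d", seq_len(k))
  group <- factor(labels[match(membership, as.integer(names(means))[ord])],
                  levels = labels)

  assignments <- tibble::tibble(cell_line = panel$cell_line, sf35 = x,
                                group = group) |>
    dplyr::arrange(.data$group, .data$sf35)
  group_means <- assignments |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_sf35 = mean(.data$sf35), n = dplyr::n(),
                     .groups = "drop")
  structure(list(assignments = assignments, group_means = group_means,
                 k = k, hclust = hc),
            class = "sensitivity_grouping")
}

#' @exportS3Method generics::tidy
tidy.sensitivity_grouping <- function(x, ...) x$assignments

#' @exportS3Method generics::glance
glance.sensitivity_grouping <- function(x, ...) {
  tibble::tibble(k = x$k, n = nrow(x$assignments),
                 smallest_group = min(x$group_means$n),
                 largest_group = max(x$group_means$n))
}

#' @export
print.sensitivity_grouping <- function(x, ...) {
  cat(sprintf("<sensitivity_grouping> %d cell lines in %d cohorts\n",
              nrow(x$assignments), x$k))
  print(x$group_means)
  invisible(x)
}

#' Collapse a four-cohort grouping to resistant vs. the rest
#'
#' Relabels members of the most-resistant cohort (R, the highest-mean-SF3.5
#' cluster) as `"resistant"` and everything else as `"other"`, for binary
#' classification of the radioresistant lines against all others.
#'
#' @param grouping A [cluster_sf35()] result.
#'
#' @return Tibble `cell_line, sf35, label` with `label` a factor
#'   `other < resistant`.
#' @export
resistant_vs_rest <- function(grouping) {
  stopifnot(inherits(grouping, "sensitivity_grouping"))
  top <- dplyr::slice_max(grouping$group_means, .data$mean_sf35, n = 1)$group
  grouping$assignments |>
    dplyr::mutate(label = factor(
      ifelse(.data$group == top, "resistant", "other"),
      levels = c("other", "resistant"))) |>
    dplyr::select("cell_line", "sf35", "label")
}
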