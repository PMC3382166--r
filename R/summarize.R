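#' Log2 consensus-ratio matrix for clustering
#'
#' Builds the feature x oncogene matrix of log2 averaged consensus ratios
#' that the oncogene dendrogram is computed from. Missing entries are left
#' `NA` (imputed to 0, "no change", at clustering time).
#'
#' @param consensus Consensus records from [call_study()].
#' @param called_only Restrict to features called in at least one oncogene.
#' @return Numeric matrix, rows = features, columns = oncogenes.
#' @export
consensus_log2_matrix <- function(consensus, called_only = FALSE) {
  if (called_only) {
    keep <- unique(consensus$feature[consensus$call != "none"])
    consensus <- consensus[consensus$feature %in% keep, ]
  }
  wide <- tidyr::pivot_wider(
    consensus[, c("feature", "condition", "avg_ratio")],
    names_from = "condition", values_from = "avg_ratio")
  m <- log2(as.matrix(wide[, -1, drop = FALSE]))
  rownames(m) <- wide$feature
  m
}

#' Cluster oncogenes by their protein expression profiles
#'
#' Agglomerative hierarchical clustering of the oncogene columns of a log2
#' ratio matrix, the dendrogram idiom of R's standard heat map (Euclidean
#' distance, complete linkage, by default). A shorter merge height means a
#' greater similarity of the proteome responses. Missing log2 values are
#' imputed to 0 (no change) before the distance computation.
#'
#' @param log2_matrix Numeric matrix, features x oncogenes (>= 2 columns).
#' @param distance Distance measure between oncogene profiles.
#' @param linkage Agglomeration method.
#' @return An [stats::hclust] tree with oncogene leaf labels.
#' @export
#' @examples
#' m <- matrix(rnorm(60), ncol = 3,
#'             dimnames = list(NULL, c("A", "B", "C")))
#' plot(cluster_oncogenes(m))
cluster_oncogenes <- function(log2_matrix, distance = "euclidean",
                              linkage = "complete") {
  if (!is.matrix(log2_matrix) || ncol(log2_matrix) < 2L) {
    stop("need a matrix with at least 2 oncogene columns", call. = FALSE)
  }
  log2_matrix[is.na(log2_matrix)] <- 0
  stats::hclust(stats::dist(t(log2_matrix), method = distance),
                method = linkage)
}

#' Exact region counts for a multi-set (Edwards) Venn diagram
#'
#' For up to six sets of features, counts how many features fall in exactly
#' each nonempty membership subset — the `2^k - 1` regions of a k-set Venn
#' diagram. Region counts sum to the size of the union, and the marginal sum
#' of all regions containing a set equals that set's size.
#'
#' @param sets Named list (1-6 elements) of feature identifier vectors.
#' @return Tibble with `region` (set labels joined by `&`, in input order)
#'   and `count`, covering every nonempty subset.
#' @export
#' @examples
#' venn_counts(list(A = c(1, 2), B = c(2, 3)))
venn_counts <- function(sets) {
  if (!is.list(sets) || length(sets) < 1L || length(sets) > 6L) {
    stop("`sets` must be a named list of 1 to 6 feature sets", call. = FALSE)
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets))) ||
      anyDuplicated(names(sets))) {
    stop("`sets` must have distinct nonempty names", call. = FALSE)
  }
  sets <- lapply(sets, unique)
  labels <- names(sets)
  k <- length(sets)
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, ncol = k)
  signature <- apply(membership, 1, function(row) {
    paste(labels[row], collapse = "&")
  })
  all_regions <- unlist(lapply(seq_len(k), function(size) {
    combn(labels, size, paste, collapse = "&")
  }))
  counts <- table(factor(signature, levels = all_regions))
  tibble::tibble(region = all_regions, count = as.integer(counts))
}

#' Common targets: features changed by several oncogenes
#'
#' Selects features with a consensus change call in at least `min_oncogenes`
#' oncogene conditions, reporting the per-oncogene averaged ratio and
#' averaged signed confidence with uncalled cells flagged, sorted by
#' descending call count.
#'
#' @param records Consensus records (columns `feature`, `condition`, `call`,
#'   `avg_ratio`, `avg_confidence`).
#' @param min_oncogenes Minimum number of calling oncogene conditions.
#' @return Long tibble: `feature`, `n_changed`, `condition`, `avg_ratio`,
#'   `avg_confidence`, `called`; use [format_common_targets()] for the
#'   wide bracketed display.
#' @export
common_targets <- function(records, min_oncogenes = 4) {
  counts <- records |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(n_changed = sum(.data$call != "none"), .groups = "drop")
  keep <- counts$feature[counts$n_changed >= min_oncogenes]
  out <- records[records$feature %in% keep,
                 c("feature", "condition", "avg_ratio", "avg_confidence",
                   "call")]
  out$called <- out$call != "none"
  out$call <- NULL
  out <- dplyr::left_join(out, counts, by = "feature")
  out <- out[order(-out$n_changed, out$feature), ]
  dplyr::relocate(tibble::as_tibble(out), "n_changed", .after = "feature")
}

#' Format common targets in the published table style
#'
#' Widens a [common_targets()] result to one row per feature with
#' `"ratio (conf)"` cells, the confidence bracketed when the oncogene's
#' change was not called.
#'
#' @param targets Output of [common_targets()].
#' @return Wide tibble of display strings.
#' @export
format_common_targets <- function(targets) {
  targets$cell <- paste(sprintf("%.2f", targets$avg_ratio),
                        format_confidence(targets$avg_confidence,
                                          targets$called))
  tidyr::pivot_wider(targets[, c("feature", "n_changed", "condition", "cell")],
                     names_from = "condition", values_from = "cell")
}

#' Percent reduction implied by a fold-change
#'
#' A fold-change of 0.72 is a 28% reduction. Rounded to the nearest integer
#' percent for reporting; negative values mean an increase.
#'
#' @param fold Positive fold-change(s).
#' @return Integer percent reduction.
#' @export
#' @examples
#' percent_reduction(0.72)  # 28
percent_reduction <- function(fold) {
  if (any(fold <= 0, na.rm = TRUE)) {
    stop("fold-changes must be > 0", call. = FALSE)
  }
  round((1 - fold) * 100)
}
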