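#' Build the bin-by-track matrix for clustering
#'
#' Rows are the genomic bins of the requested partition (autosomes or X) in
#' genome order; columns are the three signals in fixed order
#' `(wt_k27me3, oncohistone, mut_k27me3)`.
#'
#' @param wt,onco,mut `BinnedTrack`s on a shared (typically 10 kb) grid.
#' @param partition `"autosomes"` or `"X"`.
#' @return A `ClusterMatrix`: list with `matrix` and `bins` (chrom, start).
#'   An empty partition is flagged with a warning and attribute `empty`.
#' @export
build_matrix <- function(wt, onco, mut, partition = c("autosomes", "X")) {
  partition <- match.arg(partition)
  check_same_grid(wt, onco)
  check_same_grid(wt, mut)
  chroms <- if (partition == "autosomes") autosomes(wt$assembly)
            else x_chrom(wt$assembly)
  nb <- assembly_bins(wt$assembly, wt$bin_size)
  bins <- do.call(rbind, lapply(chroms, function(ch)
    data.frame(chrom = ch,
               start = (seq_len(nb[[ch]]) - 1L) * wt$bin_size,
               stringsAsFactors = FALSE)))
  if (is.null(bins)) bins <- data.frame(chrom = character(0), start = numeric(0))
  m <- cbind(wt_k27me3 = unlist(wt$values[chroms], use.names = FALSE),
             oncohistone = unlist(onco$values[chroms], use.names = FALSE),
             mut_k27me3 = unlist(mut$values[chroms], use.names = FALSE))
  if (nrow(bins) == 0L) {
    warning("empty partition: no bins to cluster")
    m <- matrix(numeric(0), 0, 3,
                dimnames = list(NULL, c("wt_k27me3", "oncohistone",
                                        "mut_k27me3")))
  }
  out <- structure(list(matrix = m, bins = bins, partition = partition),
                   class = "ClusterMatrix")
  attr(out, "empty") <- nrow(bins) == 0L
  out
}

#' Agglomerative clustering of genomic bins
#'
#' Hierarchical clustering of the bin-by-track matrix with distance
#' `1 - Pearson correlation` across the columns (or Euclidean distance) and
#' average (or complete) linkage; the tree is cut into `k` clusters.
#' Deterministic for a fixed matrix: no randomized initialization, ties
#' resolved by row order. Rows with zero variance have undefined
#' correlation; their pairwise distance is set to 1.
#'
#' @param cm a `ClusterMatrix` from [build_matrix()].
#' @param k number of clusters (default 6).
#' @param metric `"pearson"` (default) or `"euclidean"`.
#' @param linkage `"average"` (default) or `"complete"`.
#' @param scale_columns z-score the columns first (default `FALSE`; the
#'   columns are already comparable log-ratio signals).
#' @return A `BinClustering`: list with integer `labels` (in row order),
#'   the `hclust` tree, `k`, and cluster `sizes`.
#' @export
cluster_bins <- function(cm, k = 6L, metric = c("pearson", "euclidean"),
                         linkage = c("average", "complete"),
                         scale_columns = FALSE) {
  stopifnot(inherits(cm, "ClusterMatrix"))
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  m <- cm$matrix
  n <- nrow(m)
  if (!is_count(k) || k < 1 || k > n)
    validation_error("k must be an integer in [1, number of rows]")
  if (scale_columns) m <- scale(m)
  d <- if (metric == "pearson") {
    cc <- suppressWarnings(stats::cor(t(m)))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 1
    stats::as.dist(1 - cc)
  } else {
    stats::dist(m)
  }
  hc <- stats::hclust(d, method = linkage)
  labels <- stats::cutree(hc, k = k)
  structure(list(labels = unname(labels), hclust = hc, k = as.integer(k),
                 sizes = as.integer(table(labels))),
            class = "BinClustering")
}

#' Per-cluster summary of the clustered signals
#'
#' @param cm a `ClusterMatrix`.
#' @param labels integer cluster labels aligned with the matrix rows (e.g.
#'   from [cluster_bins()], or a `BinClustering` object).
#' @return Data frame with one row per cluster, sorted by size descending:
#'   cluster id, size, and the mean of each signal column.
#' @export
cluster_summary <- function(cm, labels) {
  stopifnot(inherits(cm, "ClusterMatrix"))
  if (inherits(labels, "BinClustering")) labels <- labels$labels
  if (length(labels) != nrow(cm$matrix))
    dimension_error("labels do not align with the matrix rows")
  ids <- sort(unique(labels))
  rows <- lapply(ids, function(cl) {
    m <- cm$matrix[labels == cl, , drop = FALSE]
    data.frame(cluster = cl, size = nrow(m),
               wt_k27me3 = mean(m[, "wt_k27me3"]),
               oncohistone = mean(m[, "oncohistone"]),
               mut_k27me3 = mean(m[, "mut_k27me3"]))
  })
  out <- do.call(rbind, rows)
  out[order(-out$size, out$cluster), , drop = FALSE]
}
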