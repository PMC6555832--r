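#' Label differential expression from fold change and FDR
#'
#' A gene is `up` when its fold change exceeds `fc_threshold` and its FDR is
#' below `fdr_threshold` (both strict), `down` when the fold change is below
#' `1 / fc_threshold` with the same FDR cut, otherwise `ns`. Boundary values
#' are `ns`.
#'
#' @param table data frame with numeric columns `fc` (linear mutant/wild-type
#'   fold change) and `fdr`.
#' @param fc_threshold fold-change cutoff (default 2).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return The table with a `de_status` factor column (`up`, `down`, `ns`).
#' @export
de_filter <- function(table, fc_threshold = 2, fdr_threshold = 0.05) {
  if (!all(c("fc", "fdr") %in% names(table)))
    validation_error("table must have 'fc' and 'fdr' columns")
  sig <- table$fdr < fdr_threshold
  status <- ifelse(sig & table$fc > fc_threshold, "up",
                   ifelse(sig & table$fc < 1 / fc_threshold, "down", "ns"))
  table$de_status <- factor(status, levels = c("up", "down", "ns"))
  table
}

# Quintile assignment on a numeric vector: rank ascending (ties broken by
# id), split into five groups of floor(N/5) with remainders allotted to the
# lowest quintiles first.  Quintile I = lowest expression.
quintile_labels <- function(expr, id) {
  n <- length(expr)
  if (n == 0L) validation_error("empty table")
  sizes <- rep(n %/% 5L, 5L)
  r <- n %% 5L
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  ord <- order(expr, id)
  lab <- integer(n)
  lab[ord] <- rep(1:5, times = sizes)
  factor(c("I", "II", "III", "IV", "V")[lab],
         levels = c("I", "II", "III", "IV", "V"))
}

#' Assign wild-type expression quintiles
#'
#' Genes are ranked by `wt_expression` ascending and split into five groups
#' whose sizes differ by at most one (remainders go to the lowest
#' quintiles); ties are broken by gene id for determinism. Quintile I holds
#' the lowest-expressed genes.
#'
#' @param table gene table with `wt_expression` and `id` columns.
#' @return The table with a `quintile` factor column (I..V).
#' @export
assign_quintiles <- function(table) {
  if (!"wt_expression" %in% names(table))
    validation_error("table must have a 'wt_expression' column")
  table$quintile <- quintile_labels(table$wt_expression, table$id)
  table
}

#' Metagene occupancy profile
#'
#' Each gene body is linearly rescaled to `body_slots` positions (the track
#' is point-sampled at each slot center); flanks are taken at native bin
#' resolution (`ceiling(flank_bp / bin_size)` bins each side). The profile
#' is the per-position mean over the genes, ignoring positions that fall
#' outside a chromosome. Strand is ignored.
#'
#' @param track a `BinnedTrack`.
#' @param genes gene table rows to average (must lie on the track's
#'   assembly).
#' @param group label stored with the profile (e.g. a quintile).
#' @param body_slots number of scaled gene-body positions (default 100).
#' @param flank_bp flank width in bp (default 500).
#' @return A `MetageneProfile` data frame: `position` (index), `zone`
#'   (`upstream`/`body`/`downstream`), `mean`, `n`, `group`.
#' @export
metagene <- function(track, genes, group = NA_character_,
                     body_slots = 100L, flank_bp = 500) {
  stopifnot(inherits(track, "BinnedTrack"))
  bs <- track$bin_size
  fb <- if (flank_bp > 0) as.integer(ceiling(flank_bp / bs)) else 0L
  npos <- fb + body_slots + fb
  nb <- assembly_bins(track$assembly, bs)
  acc <- matrix(NA_real_, nrow(genes), npos)
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]
    j <- match(ch, track$assembly$name)
    if (is.na(j)) validation_error(sprintf("gene %s on unknown chromosome %s",
                                           genes$id[i], ch))
    len <- track$assembly$length[j]
    s <- genes$start[i]; e <- genes$end[i]
    if (s < 0 || e > len || s >= e)
      validation_error(sprintf("gene %s outside chromosome bounds", genes$id[i]))
    v <- track$values[[ch]]
    pick <- function(b) ifelse(b >= 1 & b <= nb[[ch]], v[pmax(pmin(b, nb[[ch]]), 1L)],
                               NA_real_)
    if (fb > 0) {
      up <- bp_to_bin(s, bs) - (fb:1)
      dn <- bp_to_bin(e - 1, bs) + (1:fb)
      acc[i, seq_len(fb)] <- pick(up)
      acc[i, fb + body_slots + seq_len(fb)] <- pick(dn)
    }
    centers <- s + (seq_len(body_slots) - 0.5) / body_slots * (e - s)
    acc[i, fb + seq_len(body_slots)] <- v[bp_to_bin(pmin(centers, len - 1e-9),
                                                    bs)]
  }
  zone <- c(rep("upstream", fb), rep("body", body_slots), rep("downstream", fb))
  out <- data.frame(position = seq_len(npos), zone = zone,
                    mean = colMeans(acc, na.rm = TRUE),
                    n = colSums(!is.na(acc)),
                    group = group, stringsAsFactors = FALSE)
  class(out) <- c("MetageneProfile", "data.frame")
  out
}

#' Per-gene H3K27me3 change over the gene body
#'
#' `mean(mut) - mean(wt)` over the bins overlapped by each gene body; a gene
#' shorter than one bin uses its single overlapping bin.
#'
#' @param wt,mut `BinnedTrack`s on the same grid.
#' @param genes gene table with `chrom`, `start`, `end` (0-based half-open).
#' @return Numeric vector of per-gene changes, in gene-table order.
#' @export
delta_k27me3 <- function(wt, mut, genes) {
  check_same_grid(wt, mut)
  bs <- wt$bin_size
  nb <- assembly_bins(wt$assembly, bs)
  vapply(seq_len(nrow(genes)), function(i) {
    ch <- genes$chrom[i]
    j <- match(ch, wt$assembly$name)
    if (is.na(j))
      validation_error(sprintf("gene %s on unknown chromosome", genes$id[i]))
    if (genes$start[i] < 0 || genes$end[i] > wt$assembly$length[j])
      validation_error(sprintf("gene %s outside chromosome bounds", genes$id[i]))
    b1 <- bp_to_bin(genes$start[i], bs)
    b2 <- max(b1, bp_to_bin(genes$end[i] - 1, bs))
    b2 <- min(b2, nb[[ch]])
    mean(mut$values[[ch]][b1:b2]) - mean(wt$values[[ch]][b1:b2])
  }, 0)
}

#' Correlation between expression and H3K27me3 changes
#'
#' Spearman (primary) and Pearson coefficients, with a seeded permutation
#' p-value for the Spearman coefficient (two-sided, label permutation).
#'
#' @param delta_expr,delta_k27me3 aligned numeric vectors (n >= 3).
#' @param n_perm number of permutations (default 999).
#' @param seed seed for the permutation stream.
#' @return List with `spearman`, `pearson`, `p_permutation`, `n`. Undefined
#'   correlations (zero variance) are reported as `NA`.
#' @export
correlate_changes <- function(delta_expr, delta_k27me3, n_perm = 999L,
                              seed = 1L) {
  n <- length(delta_expr)
  if (length(delta_k27me3) != n) dimension_error("vectors must be aligned")
  if (n < 3L) validation_error("need at least 3 observations")
  if (stats::sd(delta_expr) == 0 || stats::sd(delta_k27me3) == 0)
    return(list(spearman = NA_real_, pearson = NA_real_,
                p_permutation = NA_real_, n = n))
  rho <- stats::cor(delta_expr, delta_k27me3, method = "spearman")
  pea <- stats::cor(delta_expr, delta_k27me3, method = "pearson")
  p <- with_seed(substream_seed(seed, "perm"), {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      rb <- stats::cor(delta_expr, sample(delta_k27me3), method = "spearman")
      if (abs(rb) >= abs(rho) - 1e-12) hits <- hits + 1L
    }
    (hits + 1L) / (n_perm + 1L)
  })
  list(spearman = rho, pearson = pea, p_permutation = p, n = n)
}

#' Fraction of differentially expressed genes per expression quintile
#'
#' @param table gene table with `de_status` and `quintile` columns.
#' @return Named numeric vector (I..V) summing to 1 over the DE genes. With
#'   zero DE genes a vector of `NA` is returned with a warning and
#'   attribute `empty = TRUE`.
#' @export
quintile_fractions <- function(table) {
  if (!all(c("de_status", "quintile") %in% names(table)))
    validation_error("table needs 'de_status' and 'quintile' columns")
  de <- table[table$de_status %in% c("up", "down"), , drop = FALSE]
  lv <- c("I", "II", "III", "IV", "V")
  if (nrow(de) == 0L) {
    warning("no differentially expressed genes; empty quintile report")
    return(structure(stats::setNames(rep(NA_real_, 5), lv), empty = TRUE))
  }
  counts <- table(factor(as.character(de$quintile), levels = lv))
  stats::setNames(as.numeric(counts) / nrow(de), lv)
}

#' Overlap between a DE gene set and a reference gene set
#'
#' @param de_genes,reference_set character vectors of gene ids; duplicates
#'   are collapsed with a warning.
#' @return Named integer vector `(only_de, intersection, only_reference)`.
#' @export
gene_set_overlap <- function(de_genes, reference_set) {
  if (anyDuplicated(de_genes) || anyDuplicated(reference_set)) {
    warning("duplicate gene ids collapsed")
    de_genes <- unique(de_genes)
    reference_set <- unique(reference_set)
  }
  both <- intersect(de_genes, reference_set)
  c(only_de = length(de_genes) - length(both),
    intersection = length(both),
    only_reference = length(reference_set) - length(both))
}
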