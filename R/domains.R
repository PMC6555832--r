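# Presence cleanup: runs of present bins shorter than min_bins are dropped,
# then gaps of at most max_gap bins between present runs are bridged.
clean_presence <- function(p, min_bins, max_gap) {
  if (length(p) == 0L) return(p)
  r <- rle(p)
  r$values[r$values & r$lengths < min_bins] <- FALSE
  p <- inverse.rle(r)
  r <- rle(p)
  if (length(r$values) >= 3L) {
    gap <- which(!r$values & r$lengths <= max_gap)
    gap <- gap[gap > 1L & gap < length(r$values)]
    r$values[gap] <- TRUE
  }
  inverse.rle(r)
}

#' Classify the genome into the four H3K27me3 fate categories
#'
#' A bin is "present" in a condition when its (smoothed, input-normalized)
#' value exceeds `tau`; presence runs shorter than `min_bins` are dropped
#' and gaps of at most `max_gap` bins are bridged. Autosomal bins are then
#' labelled `i_maintained` (present in wild type and mutant), `ii_lost`
#' (present in wild type only) or `iii_never` (otherwise); X bins where the
#' wild-type signal is retained in the mutant are `iv_chrX_maintained`, all
#' other X bins `iii_never`. Every bin receives exactly one category.
#'
#' @param wt,mut normalized `BinnedTrack`s on the same grid.
#' @param tau enrichment threshold (default 0, i.e. enriched over input on a
#'   log-ratio track).
#' @param min_bins minimum run length in bins (default 5).
#' @param max_gap maximum bridged gap in bins (default 2).
#' @return A `DomainAnnotation`: list with `intervals` (chrom, start, end,
#'   category in bp, 0-based half-open), `bins` (per-chromosome factor of
#'   categories), the assembly, bin size and parameters.
#' @export
call_domains <- function(wt, mut, tau = 0, min_bins = 5L, max_gap = 2L) {
  check_same_grid(wt, mut)
  if (!is.finite(tau)) validation_error("tau must be finite")
  cats <- c("i_maintained", "ii_lost", "iii_never", "iv_chrX_maintained")
  assembly <- wt$assembly
  bins <- list()
  iv <- list()
  for (j in seq_len(nrow(assembly))) {
    ch <- assembly$name[j]
    wp <- clean_presence(wt$values[[ch]] > tau, min_bins, max_gap)
    mp <- clean_presence(mut$values[[ch]] > tau, min_bins, max_gap)
    lab <- if (assembly$class[j] == "X") {
      ifelse(wp & mp, "iv_chrX_maintained", "iii_never")
    } else {
      ifelse(wp & mp, "i_maintained", ifelse(wp, "ii_lost", "iii_never"))
    }
    bins[[ch]] <- factor(lab, levels = cats)
    r <- rle(lab)
    e_bin <- cumsum(r$lengths)
    s_bin <- c(0, e_bin[-length(e_bin)])
    iv[[ch]] <- data.frame(
      chrom = ch,
      start = s_bin * wt$bin_size,
      end = pmin(e_bin * wt$bin_size, assembly$length[j]),
      category = r$values, stringsAsFactors = FALSE)
  }
  structure(list(intervals = do.call(rbind, c(iv, make.row.names = FALSE)),
                 bins = bins, assembly = assembly, bin_size = wt$bin_size,
                 params = list(tau = tau, min_bins = min_bins,
                               max_gap = max_gap)),
            class = "DomainAnnotation")
}

#' Per-chromosome occupancy summary
#'
#' @param track a `BinnedTrack`.
#' @return Data frame with one row per chromosome: bin count, mean, median
#'   and quartiles of the bin values.
#' @export
chromosome_summary <- function(track) {
  stopifnot(inherits(track, "BinnedTrack"))
  rows <- lapply(seq_len(nrow(track$assembly)), function(j) {
    ch <- track$assembly$name[j]
    v <- track$values[[ch]]
    data.frame(chrom = ch, class = track$assembly$class[j],
               n_bins = length(v), mean = mean(v),
               median = stats::median(v),
               q25 = unname(stats::quantile(v, 0.25)),
               q75 = unname(stats::quantile(v, 0.75)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Occupancy summary per domain category
#'
#' @param tracks named list of `BinnedTrack`s sharing the annotation's grid.
#' @param domains a `DomainAnnotation` from [call_domains()].
#' @return Data frame with one row per (category, track): bin count, mean
#'   and median; empty categories are kept with `n_bins = 0` and `NA` stats.
#' @export
domain_summary <- function(tracks, domains) {
  stopifnot(inherits(domains, "DomainAnnotation"))
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    validation_error("tracks must be a named list")
  cats <- levels(domains$bins[[1]])
  cat_all <- unlist(lapply(domains$assembly$name,
                           function(ch) as.character(domains$bins[[ch]])),
                    use.names = FALSE)
  rows <- list()
  for (tn in names(tracks)) {
    tr <- tracks[[tn]]
    if (!same_assembly(tr$assembly, domains$assembly) ||
        tr$bin_size != domains$bin_size)
      dimension_error(sprintf("track '%s' does not share the domain grid", tn))
    v <- track_values(tr)
    for (cc in cats) {
      m <- cat_all == cc
      rows[[length(rows) + 1L]] <- data.frame(
        category = cc, track = tn, n_bins = sum(m),
        mean = if (any(m)) mean(v[m]) else NA_real_,
        median = if (any(m)) stats::median(v[m]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.DomainAnnotation <- function(x, ...) {
  tab <- table(unlist(lapply(x$bins, as.integer)))
  names(tab) <- levels(x$bins[[1]])[as.integer(names(tab))]
  cat(sprintf("DomainAnnotation: %d intervals @ %d bp bins\n",
              nrow(x$intervals), x$bin_size))
  print(tab)
  invisible(x)
}
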