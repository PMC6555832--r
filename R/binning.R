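#' Bin aligned-fragment placements into a raw coverage track
#'
#' Each bin value is the maximum per-base fragment depth observed inside the
#' bin (the default), so a fragment spanning a bin edge contributes to both
#' bins. The alternative statistic `"count"` counts fragments overlapping the
#' bin.
#'
#' @param placements named list (by chromosome) of two-column matrices or
#'   data frames of 0-based half-open `(start, end)` fragment intervals.
#'   Chromosomes without fragments may be omitted.
#' @param assembly a [genome_assembly()].
#' @param bin_size bin width in bp.
#' @param stat `"max"` (max per-base depth, default) or `"count"` (number of
#'   overlapping fragments).
#' @return A raw-state [binned_track()] whose `read_total` is the number of
#'   fragments.
#' @export
bin_coverage <- function(placements, assembly, bin_size, stat = c("max", "count")) {
  stat <- match.arg(stat)
  nb <- assembly_bins(assembly, bin_size)
  total <- 0L
  vals <- lapply(assembly$name, function(ch) {
    n <- nb[[ch]]
    len <- assembly$length[assembly$name == ch]
    out <- numeric(n)
    p <- placements[[ch]]
    if (is.null(p) || NROW(p) == 0L) return(out)
    p <- as.matrix(p)
    if (ncol(p) < 2L) validation_error("placements need start and end columns")
    s <- as.numeric(p[, 1]); e <- as.numeric(p[, 2])
    if (any(s < 0) || any(e > len) || any(s >= e))
      validation_error(sprintf(
        "chromosome %s: fragment interval out of bounds", ch))
    total <<- total + length(s)
    if (stat == "count") {
      first <- bp_to_bin(s, bin_size)
      last  <- bp_to_bin(e - 1, bin_size)
      for (i in seq_along(s)) {
        idx <- first[i]:last[i]
        out[idx] <- out[idx] + 1
      }
      return(out)
    }
    # per-base depth by difference array, then per-bin max
    delta <- numeric(len + 1L)
    for (i in seq_along(s)) {
      delta[s[i] + 1L] <- delta[s[i] + 1L] + 1
      delta[e[i] + 1L] <- delta[e[i] + 1L] - 1
    }
    depth <- cumsum(delta[seq_len(len)])
    binf <- bp_to_bin(seq_len(len) - 1L, bin_size)
    as.numeric(tapply(depth, binf, max))
  })
  names(vals) <- assembly$name
  binned_track(assembly, bin_size, vals, state = "raw", read_total = total)
}

#' Scale a raw track to a target library size
#'
#' Equal-total normalization: all values are multiplied by
#' `target_total / read_total`, emulating normalization of libraries to the
#' same number of reads.
#'
#' @param track raw `BinnedTrack` carrying a `read_total`.
#' @param target_total target library size.
#' @param read_total override for the track's stored library size.
#' @return A scaled-state `BinnedTrack` with `read_total = target_total`.
#' @export
scale_to_total <- function(track, target_total, read_total = track$read_total) {
  if (track$state != "raw") validation_error("scale_to_total expects a raw track")
  if (is.null(read_total) || !is.numeric(read_total))
    validation_error("read total unknown; supply read_total")
  if (read_total <= 0) oc_abort("zero read total", "oncochrom_normalization_error")
  f <- target_total / read_total
  vals <- lapply(track$values, function(v) v * f)
  binned_track(track$assembly, track$bin_size, vals, state = "scaled",
               read_total = target_total)
}

#' Input-normalize an IP track
#'
#' `delta` subtracts the input (robust to low-count bins); `logratio`
#' computes `log2((ip + pseudocount) / (input + pseudocount))`.
#'
#' @param ip,input scaled `BinnedTrack`s on the same grid.
#' @param method `"delta"` or `"logratio"`.
#' @param pseudocount added to both numerator and denominator in logratio
#'   mode (default 1).
#' @return A `BinnedTrack` in `delta` or `logratio` state.
#' @export
normalize_input <- function(ip, input, method = c("delta", "logratio"),
                            pseudocount = 1) {
  method <- match.arg(method)
  check_same_grid(ip, input)
  if (method == "delta") {
    map2_tracks(ip, input, `-`, state = "delta")
  } else {
    f <- function(a, b) {
      r <- log2((a + pseudocount) / (b + pseudocount))
      if (!all(is.finite(r)))
        validation_error("non-finite log ratio; use a positive pseudocount")
      r
    }
    map2_tracks(ip, input, f, state = "logratio")
  }
}

#' Merge replicate raw tracks
#'
#' Replicates are combined additively: per-bin values and read totals are
#' summed, emulating merging of alignment files before binning. Exact for
#' the count statistic; a documented approximation for the max statistic.
#'
#' @param tracks non-empty list of raw `BinnedTrack`s on one grid.
#' @param read_totals optional numeric vector overriding stored totals.
#' @return A raw `BinnedTrack`.
#' @export
merge_replicates <- function(tracks, read_totals = NULL) {
  if (length(tracks) < 1L) validation_error("need at least one track to merge")
  for (t in tracks[-1]) check_same_grid(tracks[[1]], t)
  if (is.null(read_totals))
    read_totals <- vapply(tracks, function(t)
      if (is.null(t$read_total)) NA_real_ else as.numeric(t$read_total), 0)
  acc <- tracks[[1]]$values
  for (t in tracks[-1])
    acc <- Map(`+`, acc, t$values)
  binned_track(tracks[[1]]$assembly, tracks[[1]]$bin_size, acc, state = "raw",
               read_total = if (all(is.finite(read_totals))) sum(read_totals))
}

#' Smooth a normalized track with a centered running mean
#'
#' The window shrinks at chromosome ends (edge truncation); chromosome
#' boundaries are never crossed.
#'
#' @param track a normalized (`delta`/`logratio`) or smoothed `BinnedTrack`.
#' @param window_bins odd window width in bins (default 5).
#' @return A smoothed-state `BinnedTrack`.
#' @export
smooth_track <- function(track, window_bins = 5L) {
  if (!is_count(window_bins) || window_bins %% 2 == 0)
    validation_error("window_bins must be a positive odd integer")
  if (!track$state %in% c("delta", "logratio", "smoothed"))
    validation_error("smooth_track expects a normalized track")
  half <- (window_bins - 1L) %/% 2L
  vals <- lapply(track$values, function(v) {
    n <- length(v)
    if (n == 0L || half == 0L) return(v)
    cs <- cumsum(c(0, v))
    i <- seq_len(n)
    lo <- pmax(i - half, 1L); hi <- pmin(i + half, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  })
  binned_track(track$assembly, track$bin_size, vals, state = "smoothed")
}

#' Re-bin a track to a coarser grid
#'
#' The value of a coarse bin is the mean of its constituent fine bins; a
#' partial trailing group is averaged over the members present.
#'
#' @param track a `BinnedTrack`.
#' @param new_bin_size integer multiple of the current bin size.
#' @return A `BinnedTrack` at the new bin size (state preserved).
#' @export
rebin <- function(track, new_bin_size) {
  if (!is_count(new_bin_size) || new_bin_size %% track$bin_size != 0)
    validation_error("new_bin_size must be an integer multiple of the bin size")
  if (new_bin_size == track$bin_size) return(track)
  k <- new_bin_size %/% track$bin_size
  nb_new <- assembly_bins(track$assembly, new_bin_size)
  vals <- lapply(track$assembly$name, function(ch) {
    v <- track$values[[ch]]
    grp <- (seq_along(v) - 1L) %/% k + 1L
    out <- as.numeric(tapply(v, grp, mean))
    stopifnot(length(out) == nb_new[[ch]])
    out
  })
  names(vals) <- track$assembly$name
  binned_track(track$assembly, new_bin_size, vals, state = track$state,
               read_total = track$read_total)
}

#' Genome-wide coverage uniformity report
#'
#' Compares two equal-total-scaled coverage tracks via per-bin
#' `log2((sample + pseudocount)/(reference + pseudocount))` and summarizes
#' dispersion, as used to assess whether a genome is evenly replicated.
#'
#' @param sample,reference `BinnedTrack`s on the same grid.
#' @param pseudocount added to both tracks before the ratio (default 1).
#' @param tau outlier threshold on `|log2 ratio|` (default 1, i.e. two-fold).
#' @return A list with the per-bin `log2_ratio` vector, `sd`, `mad`, and
#'   `outlier_fraction`.
#' @export
coverage_uniformity <- function(sample, reference, pseudocount = 1, tau = 1) {
  check_same_grid(sample, reference)
  lr <- unlist(Map(function(a, b) log2((a + pseudocount) / (b + pseudocount)),
                   sample$values, reference$values), use.names = FALSE)
  if (!all(is.finite(lr)))
    validation_error("non-finite log ratio; use a positive pseudocount")
  list(log2_ratio = lr,
       sd = stats::sd(lr),
       mad = stats::mad(lr),
       outlier_fraction = mean(abs(lr) > tau))
}
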