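#' Binned signal track
#'
#' A `BinnedTrack` holds one numeric value per fixed-width genomic bin,
#' organised per chromosome, together with the assembly it lives on, the bin
#' size, and a normalization-state tag. The state follows the processing
#' chain `raw -> scaled -> {delta | logratio} -> smoothed`. Trailing partial
#' bins are real bins: each chromosome has `ceiling(length / bin_size)` bins
#' and coordinates are 0-based half-open throughout.
#'
#' @param assembly a [genome_assembly()].
#' @param bin_size bin width in bp.
#' @param values named list of numeric vectors, one per chromosome, or a
#'   single value recycled to every bin.
#' @param state one of `"raw"`, `"scaled"`, `"delta"`, `"logratio"`,
#'   `"smoothed"`.
#' @param read_total optional library size carried alongside raw/scaled
#'   tracks, used by [scale_to_total()] and [merge_replicates()].
#'
#' @return An object of class `BinnedTrack`.
#' @export
binned_track <- function(assembly, bin_size, values, state = "raw",
                         read_total = NULL) {
  stopifnot(inherits(assembly, "GenomeAssembly"))
  nb <- assembly_bins(assembly, bin_size)
  if (!is.list(values)) {
    if (length(values) != 1L)
      validation_error("values must be a named list or a single scalar")
    values <- lapply(nb, function(n) rep(as.numeric(values), n))
  }
  if (!setequal(names(values), assembly$name))
    dimension_error("values must be named by chromosome, matching the assembly")
  values <- values[assembly$name]
  for (ch in assembly$name) {
    v <- values[[ch]]
    if (length(v) != nb[[ch]])
      dimension_error(sprintf(
        "chromosome %s: expected %d bins, got %d", ch, nb[[ch]], length(v)))
    if (state %in% c("delta", "logratio", "smoothed") && !all(is.finite(v)))
      validation_error(sprintf("chromosome %s: non-finite normalized values", ch))
    if (state %in% c("raw", "scaled") && any(v < 0, na.rm = TRUE))
      validation_error(sprintf("chromosome %s: raw/scaled values must be >= 0", ch))
    values[[ch]] <- as.numeric(v)
  }
  if (!state %in% c("raw", "scaled", "delta", "logratio", "smoothed"))
    validation_error("unknown track state")
  structure(list(assembly = assembly, bin_size = as.integer(bin_size),
                 values = values, state = state,
                 read_total = read_total),
            class = "BinnedTrack")
}

check_same_grid <- function(a, b) {
  if (!inherits(a, "BinnedTrack") || !inherits(b, "BinnedTrack"))
    validation_error("expected BinnedTrack objects")
  if (!same_assembly(a$assembly, b$assembly))
    dimension_error("tracks are on different assemblies")
  if (a$bin_size != b$bin_size)
    dimension_error("tracks have different bin sizes")
  invisible(TRUE)
}

#' Concatenate all bin values of a track into one vector
#'
#' @param track a `BinnedTrack`.
#' @param chroms chromosomes to include (default all, in assembly order).
#' @return Numeric vector of bin values.
#' @export
track_values <- function(track, chroms = NULL) {
  if (is.null(chroms)) chroms <- track$assembly$name
  unlist(track$values[chroms], use.names = FALSE)
}

# Map genomic bp positions to 1-based bin indices on one chromosome.
bp_to_bin <- function(pos, bin_size) as.integer(pos %/% bin_size) + 1L

# Replace values of one chromosome (internal).
set_chrom <- function(track, chrom, v) {
  track$values[[chrom]] <- v
  track
}

#' @export
print.BinnedTrack <- function(x, ...) {
  n <- sum(lengths(x$values))
  cat(sprintf("BinnedTrack: %d bins @ %d bp [%s], %d chromosomes\n",
              n, x$bin_size, x$state, nrow(x$assembly)))
  invisible(x)
}

#' Arithmetic-style map over two tracks on the same grid (internal helper).
#' @noRd
map2_tracks <- function(a, b, f, state) {
  check_same_grid(a, b)
  vals <- lapply(a$assembly$name, function(ch) f(a$values[[ch]], b$values[[ch]]))
  names(vals) <- a$assembly$name
  binned_track(a$assembly, a$bin_size, vals, state = state)
}
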