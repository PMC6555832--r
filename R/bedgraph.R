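#' Read a bedGraph file onto a fixed bin grid
#'
#' Parses a 4-column bedGraph (chrom, start, end, value; 0-based half-open).
#' Records must be aligned to the bin grid: starts on a bin boundary, ends on
#' a bin boundary or at the chromosome end, possibly spanning several bins
#' (as produced by run-merging writers). Bins not mentioned read as 0.
#'
#' @param path file path.
#' @param assembly a [genome_assembly()].
#' @param bin_size bin width in bp.
#' @param state state tag to stamp on the resulting track (default
#'   `"logratio"`, the state of finished normalized tracks).
#' @return A [binned_track()].
#' @export
read_bedgraph <- function(path, assembly, bin_size, state = "logratio") {
  if (!file.exists(path)) io_error(sprintf("no such file: %s", path))
  nb <- assembly_bins(assembly, bin_size)
  vals <- lapply(nb, numeric)
  seen <- lapply(nb, logical)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  for (i in which(keep)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 4L)
      parse_error(sprintf("%s:%d: expected 4 fields, got %d", path, i, length(f)))
    ch <- f[1]
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    v <- suppressWarnings(as.numeric(f[4]))
    if (anyNA(c(s, e, v)))
      parse_error(sprintf("%s:%d: non-numeric coordinate or value", path, i))
    j <- match(ch, assembly$name)
    if (is.na(j))
      parse_error(sprintf("%s:%d: unknown chromosome '%s'", path, i, ch))
    len <- assembly$length[j]
    if (s < 0 || e > len || s >= e)
      parse_error(sprintf("%s:%d: interval [%g,%g) out of bounds", path, i, s, e))
    if (s %% bin_size != 0 || (e %% bin_size != 0 && e != len))
      parse_error(sprintf(
        "%s:%d: interval [%g,%g) not aligned to %d bp grid", path, i, s, e,
        bin_size))
    b1 <- bp_to_bin(s, bin_size)
    b2 <- bp_to_bin(e - 1, bin_size)
    if (any(seen[[ch]][b1:b2]))
      parse_error(sprintf("%s:%d: overlapping records on %s", path, i, ch))
    seen[[ch]][b1:b2] <- TRUE
    vals[[ch]][b1:b2] <- v
  }
  binned_track(assembly, bin_size, vals, state = state)
}

#' Write a track as a bedGraph file
#'
#' Emits 0-based half-open grid-aligned records, merging runs of equal value;
#' the final record of each chromosome is clipped to the chromosome length.
#' Zero-value runs are written too, so `read_bedgraph(write_bedgraph(x))` is
#' an exact grid round-trip up to float formatting.
#'
#' @param track a `BinnedTrack`.
#' @param path output path.
#' @param drop_zero if `TRUE`, omit zero-value runs (smaller files; absent
#'   bins read back as 0 anyway). Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, drop_zero = FALSE) {
  con <- tryCatch(file(path, "wb"), error = function(e)
    io_error(sprintf("cannot open %s for writing: %s", path, conditionMessage(e))))
  on.exit(close(con))
  bs <- track$bin_size
  out <- character(0)
  for (j in seq_len(nrow(track$assembly))) {
    ch <- track$assembly$name[j]
    len <- track$assembly$length[j]
    v <- track$values[[ch]]
    if (length(v) == 0L) next
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- c(0, ends_bin[-length(ends_bin)])
    s <- starts_bin * bs
    e <- pmin(ends_bin * bs, len)
    keep <- if (drop_zero) r$values != 0 else rep(TRUE, length(r$values))
    if (any(keep))
      out <- c(out, sprintf("%s\t%s\t%s\t%s", ch,
                            format(s[keep], scientific = FALSE, trim = TRUE),
                            format(e[keep], scientific = FALSE, trim = TRUE),
                            vapply(r$values[keep], fmt_num, "")))
  }
  writeLines(out, con)
  invisible(path)
}
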