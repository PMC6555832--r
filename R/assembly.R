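#' Genome assembly for binned analyses
#'
#' A `GenomeAssembly` is an ordered set of chromosomes, each with a length in
#' base pairs and a class: `"autosome"` or `"X"`. The X/autosome partition is
#' used throughout the package (oncohistone depletion from X, per-partition
#' clustering, domain category iv).
#'
#' @param names character vector of unique chromosome names.
#' @param lengths integer vector of chromosome lengths in bp (all > 0).
#' @param classes character vector, one of `"autosome"` or `"X"` per
#'   chromosome; exactly one X and at least one autosome are required.
#'
#' @return An object of class `GenomeAssembly`: a data frame with columns
#'   `name`, `length`, `class`.
#' @export
genome_assembly <- function(names, lengths, classes) {
  if (length(names) == 0L) config_error("assembly needs at least one chromosome")
  if (length(names) != length(lengths) || length(names) != length(classes))
    config_error("names, lengths and classes must have equal length")
  if (anyDuplicated(names)) config_error("chromosome names must be unique")
  if (!all(is.finite(lengths)) || any(lengths <= 0) || any(lengths != floor(lengths)))
    config_error("chromosome lengths must be positive integers")
  if (!all(classes %in% c("autosome", "X")))
    config_error("chromosome class must be 'autosome' or 'X'")
  if (sum(classes == "X") != 1L)
    config_error("exactly one chromosome must have class 'X'")
  if (sum(classes == "autosome") < 1L)
    config_error("at least one autosome is required")
  structure(
    data.frame(name = as.character(names), length = as.numeric(lengths),
               class = as.character(classes), stringsAsFactors = FALSE),
    class = c("GenomeAssembly", "data.frame")
  )
}

#' Build the genome assembly described by a synthetic configuration
#'
#' @param config a [synthetic_config()] object.
#' @return A [genome_assembly()] with `n_autosomes` autosomes followed by one
#'   X chromosome.
#' @export
make_assembly <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  cs <- config$chromosomes
  if (cs$n_autosomes < 1L) config_error("need at least one autosome")
  n <- cs$n_autosomes
  auto_names <- paste0("chr", as.character(utils::as.roman(seq_len(n))))
  genome_assembly(
    names   = c(auto_names, "chrX"),
    lengths = c(rep(cs$autosome_length, n), cs$x_length),
    classes = c(rep("autosome", n), "X")
  )
}

#' Number of bins per chromosome at a given bin size
#'
#' Trailing partial bins are real bins (`ceiling(length / bin_size)`).
#'
#' @param assembly a `GenomeAssembly`.
#' @param bin_size bin width in bp.
#' @return Named integer vector of bin counts.
#' @export
assembly_bins <- function(assembly, bin_size) {
  stopifnot(inherits(assembly, "GenomeAssembly"))
  if (!is_count(bin_size)) validation_error("bin_size must be a positive integer")
  stats::setNames(as.integer(ceiling(assembly$length / bin_size)), assembly$name)
}

is_x_chrom <- function(assembly, name) {
  assembly$class[match(name, assembly$name)] == "X"
}

x_chrom <- function(assembly) assembly$name[assembly$class == "X"]
autosomes <- function(assembly) assembly$name[assembly$class == "autosome"]

same_assembly <- function(a, b) {
  identical(a$name, b$name) && identical(a$length, b$length) &&
    identical(a$class, b$class)
}

#' @export
print.GenomeAssembly <- function(x, ...) {
  cat(sprintf("GenomeAssembly: %d chromosomes, %.3g Mb total (X: %s)\n",
              nrow(x), sum(x$length) / 1e6, x$name[x$class == "X"]))
  print.data.frame(x, ...)
  invisible(x)
}
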