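#' Configuration of the synthetic chromatin world
#'
#' Bundles every parameter of the synthetic-data generators. Defaults describe
#' a scaled-down worm-like germ-line genome: five autosomes plus one X
#' (10 Mb total, ~1/10 of the real genome so that default runs stay fast),
#' blocky wild-type H3K27me3 domains on the autosomes with a uniformly high X
#' baseline, an oncohistone that is either depleted from X (H3.3 pattern) or
#' spread genome-wide (H3-like pattern), a mutant H3K27me3 track generated
#' from the packaged dependency model, several hundred differentially
#' expressed genes anti-correlated with the H3K27me3 change, and DAPI
#' intensities linear in DNA content.
#'
#' @param seed master integer seed; every generator derives a named substream
#'   from it, so outputs are bit-for-bit reproducible and adding a generator
#'   does not perturb the others.
#' @param bin_size bin width in bp for simulated tracks (default 1000, the
#'   resolution at which the dependency model operates).
#' @param n_autosomes,autosome_length,x_length chromosome layout in bp.
#' @param domain_mean_length mean length (bp) of a wild-type H3K27me3 domain;
#'   block lengths are geometric with this mean.
#' @param domain_fraction fraction of autosomal bp covered by wild-type
#'   H3K27me3 domains.
#' @param domain_level,background_level,x_baseline log2-ratio-like signal
#'   levels of autosomal domains, background, and the X chromosome.
#' @param onco_fraction fraction of autosomal bp covered by oncohistone
#'   domains.
#' @param onco_level log2-ratio-like oncohistone signal inside its domains.
#' @param onco_mean_length mean oncohistone domain length in bp.
#' @param onco_spread widening factor applied to oncohistone domains in
#'   H3-like mode (>= 1).
#' @param x_depletion_factor H3.3-mode ratio of X to autosomal mean
#'   oncohistone signal (noiseless construction guarantees the ratio).
#' @param noise_sd additive Gaussian noise SD on simulated wild-type and
#'   oncohistone tracks.
#' @param mut_noise_sd residual Gaussian noise SD added on top of the
#'   dependency-model image when simulating the mutant H3K27me3 track.
#' @param dependency numeric vector of 9 coefficients (A0..A8) to plant;
#'   defaults to the packaged coefficients, see [table1_model()].
#' @param n_genes,n_de gene count and number of differentially expressed
#'   genes.
#' @param expr_meanlog,expr_sdlog log-normal parameters of wild-type
#'   expression (normalized counts).
#' @param de_quintile_probs length-5 probabilities with which DE genes are
#'   drawn from expression quintiles I..V (defaults plant ~70% in II+III).
#' @param de_lfc_range range of |log2 fold change| for DE genes (both ends
#'   > 1 so that the fold-change filter is consistent with the labels).
#' @param anticorrelation fraction of DE genes whose expression-change sign
#'   is forced opposite to their gene-body H3K27me3 change.
#' @param dapi_slope,dapi_intercept linear map from DNA content (in n) to
#'   integrated DAPI intensity (arbitrary units).
#' @param dapi_cv coefficient of variation of intensities within a nucleus
#'   population (>= 0).
#' @param endomitotic_content DNA content (n) of the simulated endomitotic
#'   oocyte population.
#' @param n_nuclei nuclei per population in the DAPI table.
#'
#' @return An object of class `SyntheticConfig` (a validated nested list).
#' @export
synthetic_config <- function(seed = 1L,
                             bin_size = 1000L,
                             n_autosomes = 5L,
                             autosome_length = 1650000L,
                             x_length = 1750000L,
                             domain_mean_length = 20000L,
                             domain_fraction = 0.35,
                             domain_level = 1.5,
                             background_level = 0,
                             x_baseline = 2.0,
                             onco_fraction = 0.4,
                             onco_level = 1.5,
                             onco_mean_length = 15000L,
                             onco_spread = 2,
                             x_depletion_factor = 0.1,
                             noise_sd = 0.25,
                             mut_noise_sd = 0.1,
                             dependency = NULL,
                             n_genes = 2000L,
                             n_de = 500L,
                             expr_meanlog = 4,
                             expr_sdlog = 1.5,
                             de_quintile_probs = c(0.05, 0.35, 0.35, 0.15, 0.10),
                             de_lfc_range = c(1.2, 3),
                             anticorrelation = 1.0,
                             dapi_slope = 50,
                             dapi_intercept = 200,
                             dapi_cv = 0.1,
                             endomitotic_content = 64,
                             n_nuclei = 50L) {
  if (!is_count(seed) && !(is.numeric(seed) && seed == floor(seed)))
    config_error("seed must be an integer")
  if (!is_count(bin_size)) config_error("bin_size must be a positive integer")
  if (!is_count(n_autosomes)) config_error("n_autosomes must be a positive integer")
  frac_ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x >= 0 && x <= 1
  if (!frac_ok(domain_fraction)) config_error("domain_fraction must be in [0,1]")
  if (!frac_ok(onco_fraction)) config_error("onco_fraction must be in [0,1]")
  if (!frac_ok(x_depletion_factor))
    config_error("x_depletion_factor must be in [0,1]")
  if (!frac_ok(anticorrelation)) config_error("anticorrelation must be in [0,1]")
  if (!is.numeric(noise_sd) || noise_sd < 0) config_error("noise_sd must be >= 0")
  if (!is.numeric(mut_noise_sd) || mut_noise_sd < 0)
    config_error("mut_noise_sd must be >= 0")
  if (!is.numeric(dapi_cv) || dapi_cv < 0) config_error("dapi_cv must be >= 0")
  if (!is.numeric(onco_spread) || onco_spread < 1)
    config_error("onco_spread must be >= 1")
  if (autosome_length < 10 * bin_size || x_length < 10 * bin_size)
    config_error("each chromosome must span at least 10 bins")
  if (length(de_quintile_probs) != 5L || any(de_quintile_probs < 0))
    config_error("de_quintile_probs must be 5 non-negative values")
  de_quintile_probs <- de_quintile_probs / sum(de_quintile_probs)
  if (is.null(dependency)) dependency <- table1_coefficients()
  if (length(dependency) != 9L || !all(is.finite(dependency)))
    config_error("dependency must be 9 finite coefficients A0..A8")
  if (n_de > n_genes) config_error("n_de cannot exceed n_genes")

  structure(list(
    seed = as.integer(seed),
    bin_size = as.integer(bin_size),
    chromosomes = list(n_autosomes = as.integer(n_autosomes),
                       autosome_length = as.numeric(autosome_length),
                       x_length = as.numeric(x_length)),
    domains = list(mean_length = as.numeric(domain_mean_length),
                   fraction = domain_fraction,
                   level = domain_level,
                   background = background_level,
                   x_baseline = x_baseline),
    onco = list(fraction = onco_fraction,
                level = onco_level,
                mean_length = as.numeric(onco_mean_length),
                spread = onco_spread,
                x_depletion = x_depletion_factor),
    noise_sd = noise_sd,
    mut_noise_sd = mut_noise_sd,
    dependency = as.numeric(dependency),
    genes = list(n = as.integer(n_genes),
                 n_de = as.integer(n_de),
                 meanlog = expr_meanlog,
                 sdlog = expr_sdlog,
                 de_quintile_probs = de_quintile_probs,
                 de_lfc_range = as.numeric(de_lfc_range),
                 anticorrelation = anticorrelation),
    dapi = list(slope = dapi_slope,
                intercept = dapi_intercept,
                cv = dapi_cv,
                endomitotic_content = endomitotic_content,
                n_nuclei = as.integer(n_nuclei))
  ), class = "SyntheticConfig")
}

#' @export
print.SyntheticConfig <- function(x, ...) {
  cat(sprintf(
    "SyntheticConfig: seed %d, %d autosomes + X, bin %d bp, %d genes (%d DE)\n",
    x$seed, x$chromosomes$n_autosomes, x$bin_size, x$genes$n, x$genes$n_de))
  invisible(x)
}
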