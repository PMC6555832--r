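# Synthetic chromatin world: seeded generators for every pipeline input.
# All randomness goes through with_seed(substream_seed(seed, <stage>)), so
# each generator is reproducible on its own and independent of the others.

# Alternating background/domain blocks with geometric lengths (in bins).
# Returns list(values, domains = data.frame(start_bin, end_bin)).
alternating_blocks <- function(n_bins, mean_domain_bins, fraction,
                               level, background) {
  v <- rep(background, n_bins)
  doms <- list()
  if (fraction <= 0 || n_bins == 0L) {
    return(list(values = v, domains = data.frame(start_bin = integer(0),
                                                 end_bin = integer(0))))
  }
  if (fraction >= 1) {
    return(list(values = rep(level, n_bins),
                domains = data.frame(start_bin = 1L, end_bin = n_bins)))
  }
  mean_gap_bins <- mean_domain_bins * (1 - fraction) / fraction
  pos <- 1L
  in_domain <- stats::runif(1) < fraction  # unbiased phase at the start
  while (pos <= n_bins) {
    m <- if (in_domain) mean_domain_bins else mean_gap_bins
    len <- 1L + stats::rgeom(1L, 1 / max(m, 1))
    end <- min(pos + len - 1L, n_bins)
    if (in_domain) {
      v[pos:end] <- level
      doms[[length(doms) + 1L]] <- c(pos, end)
    }
    pos <- end + 1L
    in_domain <- !in_domain
  }
  doms <- if (length(doms)) {
    m <- do.call(rbind, doms)
    data.frame(start_bin = m[, 1], end_bin = m[, 2])
  } else data.frame(start_bin = integer(0), end_bin = integer(0))
  list(values = v, domains = doms)
}

#' Simulate the wild-type H3K27me3 landscape
#'
#' Autosomes carry blocky domains: alternating high/background runs with
#' geometric block lengths of the configured mean; the X chromosome sits at
#' a uniformly high baseline (PRC2-mediated X enrichment). Gaussian noise of
#' SD `config$noise_sd` is added on top. The planted noiseless signal and
#' domain intervals are attached as attributes `noiseless` and `domains`
#' for downstream oracles.
#'
#' @param assembly a [genome_assembly()] from [make_assembly()].
#' @param config a [synthetic_config()].
#' @return A logratio-state [binned_track()].
#' @export
simulate_wt_k27me3 <- function(assembly, config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  bs <- config$bin_size
  nb <- assembly_bins(assembly, bs)
  ds <- config$domains
  mean_bins <- max(1, ds$mean_length / bs)
  with_seed(substream_seed(config$seed, "wt_k27me3"), {
    noiseless <- list()
    domains <- list()
    for (j in seq_len(nrow(assembly))) {
      ch <- assembly$name[j]
      if (assembly$class[j] == "X") {
        noiseless[[ch]] <- rep(ds$x_baseline, nb[[ch]])
        domains[[ch]] <- data.frame(start_bin = 1L, end_bin = nb[[ch]])
      } else {
        blk <- alternating_blocks(nb[[ch]], mean_bins, ds$fraction,
                                  ds$level, ds$background)
        noiseless[[ch]] <- blk$values
        domains[[ch]] <- blk$domains
      }
    }
    vals <- lapply(noiseless, function(v)
      v + stats::rnorm(length(v), 0, config$noise_sd))
    tr <- binned_track(assembly, bs, vals, state = "logratio")
    attr(tr, "noiseless") <- noiseless
    attr(tr, "domains") <- domains
    tr
  })
}

# Sample oncohistone domain intervals on the autosomes, anti-placed against
# the wild-type signal: centers drawn with probability proportional to
# (max(wt) - wt), lengths geometric.
sample_onco_intervals <- function(assembly, nb, wt_noiseless, onco, bs) {
  mean_bins <- max(1, onco$mean_length / bs)
  auto <- autosomes(assembly)
  out <- list()
  for (ch in auto) {
    n <- nb[[ch]]
    w <- max(unlist(wt_noiseless, use.names = FALSE)) - wt_noiseless[[ch]]
    w[w < 0] <- 0
    if (sum(w) == 0) w <- rep(1, n)
    target <- onco$fraction * n
    n_dom <- max(if (onco$fraction > 0) 1L else 0L, round(target / mean_bins))
    if (n_dom == 0L) {
      out[[ch]] <- data.frame(start_bin = integer(0), end_bin = integer(0))
      next
    }
    centers <- sample.int(n, size = min(n_dom, n), replace = FALSE, prob = w)
    lens <- 1L + stats::rgeom(length(centers), 1 / mean_bins)
    s <- pmax(1L, centers - lens %/% 2L)
    e <- pmin(n, s + lens - 1L)
    out[[ch]] <- data.frame(start_bin = as.integer(s), end_bin = as.integer(e))
  }
  out
}

widen_intervals <- function(iv, spread, n_bins) {
  if (nrow(iv) == 0L || spread == 1) return(iv)
  len <- iv$end_bin - iv$start_bin + 1L
  new_len <- pmax(1L, as.integer(round(len * spread)))
  ctr <- (iv$start_bin + iv$end_bin) / 2
  s <- pmax(1L, as.integer(ceiling(ctr - new_len / 2)))
  e <- pmin(n_bins, as.integer(s + new_len - 1L))
  data.frame(start_bin = s, end_bin = e)
}

interval_mask <- function(iv, n_bins) {
  m <- logical(n_bins)
  for (i in seq_len(nrow(iv))) m[iv$start_bin[i]:iv$end_bin[i]] <- TRUE
  m
}

#' Simulate the oncohistone incorporation track
#'
#' Oncohistone domains are placed on the autosomes preferentially where the
#' wild-type H3K27me3 signal is low (centers sampled with probability
#' proportional to `max(wt) - wt`), emulating the anti-correlation between
#' the two marks. In `"H3.3"` mode the X chromosome carries a uniform low
#' level equal to `x_depletion_factor` times the autosomal mean, so the
#' noiseless X/autosome mean ratio equals the configured depletion. In
#' `"H3-like"` mode the same domain centers are used but domains are widened
#' by `onco_spread`, and the X level equals the autosomal mean (no
#' depletion).
#'
#' @param assembly a [genome_assembly()].
#' @param mode `"H3.3"` or `"H3-like"`.
#' @param config a [synthetic_config()].
#' @param wt the wild-type H3K27me3 track from [simulate_wt_k27me3()];
#'   its planted noiseless signal steers the anti-placement.
#' @return A logratio-state [binned_track()] with attributes `noiseless`,
#'   `intervals` (base domains, per chromosome, in bins) and
#'   `intervals_placed` (after any widening).
#' @export
simulate_oncohistone <- function(assembly, mode, config, wt) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (!mode %in% c("H3.3", "H3-like"))
    config_error(sprintf("unknown oncohistone mode '%s'", mode))
  if (!inherits(wt, "BinnedTrack") || !same_assembly(wt$assembly, assembly))
    dimension_error("wt track does not match the assembly")
  bs <- config$bin_size
  nb <- assembly_bins(assembly, bs)
  wt_noiseless <- attr(wt, "noiseless")
  if (is.null(wt_noiseless)) wt_noiseless <- wt$values
  # One shared substream for both modes: with spread = 1 the H3-like
  # footprint is bin-identical to the H3.3 one (except X retention).
  with_seed(substream_seed(config$seed, "oncohistone"), {
    base_iv <- sample_onco_intervals(assembly, nb, wt_noiseless, config$onco, bs)
    placed <- base_iv
    if (mode == "H3-like")
      placed <- Map(function(iv, ch) widen_intervals(iv, config$onco$spread,
                                                     nb[[ch]]),
                    base_iv, names(base_iv))
    noiseless <- list()
    for (ch in autosomes(assembly))
      noiseless[[ch]] <- ifelse(interval_mask(placed[[ch]], nb[[ch]]),
                                config$onco$level, 0)
    auto_mean <- mean(unlist(noiseless, use.names = FALSE))
    x_level <- if (mode == "H3.3") config$onco$x_depletion * auto_mean
               else auto_mean
    xc <- x_chrom(assembly)
    noiseless[[xc]] <- rep(x_level, nb[[xc]])
    noiseless <- noiseless[assembly$name]
    vals <- lapply(noiseless, function(v)
      v + stats::rnorm(length(v), 0, config$noise_sd))
    tr <- binned_track(assembly, bs, vals, state = "logratio")
    attr(tr, "noiseless") <- noiseless
    attr(tr, "intervals") <- base_iv
    attr(tr, "intervals_placed") <- placed
    tr
  })
}

#' Simulate the mutant H3K27me3 track from the dependency model
#'
#' Each bin value is `evaluate_dependency(model, x, y) + N(0, noise_sd)`,
#' with `x` the wild-type H3K27me3 and `y` the oncohistone track.
#'
#' @param wt,onco `BinnedTrack`s on the same grid.
#' @param model a [dependency_model()] (default the packaged reference).
#' @param noise_sd residual noise SD (0 gives the exact model image).
#' @param seed integer seed for the noise stream.
#' @return A logratio-state [binned_track()] with the exact model image
#'   attached as attribute `noiseless`.
#' @export
simulate_mut_k27me3 <- function(wt, onco, model = table1_model(),
                                noise_sd = 0.1, seed = 1L) {
  check_same_grid(wt, onco)
  if (noise_sd < 0) config_error("noise_sd must be >= 0")
  noiseless <- lapply(wt$assembly$name, function(ch)
    evaluate_dependency(model, wt$values[[ch]], onco$values[[ch]]))
  names(noiseless) <- wt$assembly$name
  vals <- with_seed(substream_seed(seed, "mut_k27me3"),
    lapply(noiseless, function(v)
      v + stats::rnorm(length(v), 0, noise_sd)))
  tr <- binned_track(wt$assembly, wt$bin_size, vals, state = "logratio")
  attr(tr, "noiseless") <- noiseless
  tr
}

#' Simulate the gene table with planted differential expression
#'
#' Genes are placed non-overlapping on one strand, with counts per
#' chromosome proportional to length. Wild-type expression is log-normal;
#' `n_de` genes are differentially expressed, drawn across expression
#' quintiles with the configured probabilities (defaults plant ~70% in
#' quintiles II+III), with the sign of the expression change opposite to
#' the gene-body H3K27me3 change for a fraction `anticorrelation` of them.
#' FDR and fold-change columns are generated consistent with the planted
#' labels, so [de_filter()] recovers them exactly.
#'
#' @param assembly a [genome_assembly()].
#' @param config a [synthetic_config()].
#' @param wt,mut wild-type and mutant H3K27me3 tracks (used for the planted
#'   anti-correlation).
#' @return A `GeneTable` data frame with planted `de_status` in column
#'   `planted_status` and the raw `fc`/`fdr` columns for [de_filter()].
#' @export
simulate_gene_table <- function(assembly, config, wt, mut) {
  stopifnot(inherits(config, "SyntheticConfig"))
  check_same_grid(wt, mut)
  g <- config$genes
  with_seed(substream_seed(config$seed, "genes"), {
    # allocate gene counts per chromosome by length
    share <- assembly$length / sum(assembly$length)
    counts <- floor(g$n * share)
    rem <- g$n - sum(counts)
    if (rem > 0) counts[order(-(g$n * share - counts))[seq_len(rem)]] <-
      counts[order(-(g$n * share - counts))[seq_len(rem)]] + 1
    rows <- list()
    for (j in seq_len(nrow(assembly))) {
      k <- counts[j]
      if (k == 0) next
      L <- assembly$length[j]
      lens <- round(stats::runif(k, 500, 5000))
      while (sum(lens) > 0.8 * L) lens <- pmax(200, round(lens / 2))
      gaps_raw <- stats::rexp(k + 1)
      gaps <- floor(gaps_raw / sum(gaps_raw) * (L - sum(lens)))
      starts <- cumsum(gaps[seq_len(k)] + c(0, lens[-k]))
      rows[[j]] <- data.frame(chrom = assembly$name[j],
                              start = as.numeric(starts),
                              end = as.numeric(starts + lens),
                              stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    n <- nrow(tab)
    tab$id <- sprintf("gene_%05d", seq_len(n))
    tab$strand <- "+"
    tab$wt_expression <- stats::rlnorm(n, g$meanlog, g$sdlog)
    tab <- tab[, c("id", "chrom", "start", "end", "strand", "wt_expression")]
    class(tab) <- c("GeneTable", "data.frame")

    q <- quintile_labels(tab$wt_expression, tab$id)
    delta <- delta_k27me3(wt, mut, tab)

    # pick DE genes quintile by quintile
    n_per_q <- floor(g$n_de * g$de_quintile_probs)
    short <- g$n_de - sum(n_per_q)
    if (short > 0) {
      extra <- order(-(g$n_de * g$de_quintile_probs - n_per_q))[seq_len(short)]
      n_per_q[extra] <- n_per_q[extra] + 1
    }
    de_idx <- integer(0)
    for (qi in 1:5) {
      pool <- which(as.integer(q) == qi)
      take <- min(n_per_q[qi], length(pool))
      if (take > 0) de_idx <- c(de_idx, sample(pool, take))
    }
    is_de <- seq_len(n) %in% de_idx

    lfc <- numeric(n)
    # ns genes: small changes, bounded away from the 2-fold threshold
    lfc[!is_de] <- pmax(-0.9, pmin(0.9, stats::rnorm(sum(!is_de), 0, 0.25)))
    # DE genes: |lfc| > 1 with sign opposite to the gene-body K27me3 change
    # and magnitude increasing with |change| (rank coupling), so the planted
    # expression/K27me3 relationship is monotone rather than sign-only.
    n_de_eff <- sum(is_de)
    mag <- g$de_lfc_range[1] + diff(g$de_lfc_range) *
      (rank(abs(delta[is_de]), ties.method = "first") - 0.5) / n_de_eff
    anti <- stats::runif(n_de_eff) < g$anticorrelation
    sgn <- ifelse(anti & abs(delta[is_de]) > 1e-12, -sign(delta[is_de]),
                  sample(c(-1, 1), n_de_eff, replace = TRUE))
    lfc[is_de] <- sgn * mag

    tab$mut_expression <- tab$wt_expression * 2^lfc
    tab$log2_fc <- lfc
    tab$fc <- 2^lfc
    tab$fdr <- ifelse(is_de, stats::runif(n, 0, 0.049),
                      stats::runif(n, 0.051, 1))
    tab$planted_status <- ifelse(!is_de, "ns", ifelse(lfc > 0, "up", "down"))
    tab$quintile <- q
    tab$delta_k27me3 <- delta
    # germ-line-specific flag: misregulated genes are mostly not germ line
    # specific, so the flag is drawn mainly from ns genes
    p_gl <- ifelse(is_de, 0.01, 0.10)
    tab$germline_specific <- stats::runif(n) < p_gl
    tab
  })
}

#' Simulate DAPI integrated-intensity measurements
#'
#' Three nucleus populations with known DNA content: diakinesis-stage
#' oocytes (4n), endoreduplicated intestine nuclei (32n), and endomitotic
#' oocytes (configured content). Intensities are normal around the linear
#' map `intercept + slope * content` with the configured coefficient of
#' variation.
#'
#' @param config a [synthetic_config()].
#' @return A data frame `(nucleus_id, population, true_content, intensity)`.
#' @export
simulate_dapi <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  dp <- config$dapi
  pops <- data.frame(
    population = c("oocyte_diakinesis", "intestine", "endomitotic"),
    content = c(4, 32, dp$endomitotic_content))
  with_seed(substream_seed(config$seed, "dapi"), {
    rows <- lapply(seq_len(nrow(pops)), function(i) {
      mu <- dp$intercept + dp$slope * pops$content[i]
      data.frame(
        nucleus_id = sprintf("%s_%03d", pops$population[i],
                             seq_len(dp$n_nuclei)),
        population = pops$population[i],
        true_content = pops$content[i],
        intensity = stats::rnorm(dp$n_nuclei, mu, dp$cv * mu),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Write a complete synthetic fixture set to disk
#'
#' Generates every pipeline input under the configuration and writes:
#' bedGraph tracks (wild-type H3K27me3, oncohistone in the requested mode,
#' mutant H3K27me3), the gene table and DAPI table as TSV, an assembly TSV,
#' and a JSON manifest (seed, config hash, file list). Re-running with the
#' same config produces byte-identical files.
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory (created if needed).
#' @param mode oncohistone mode, `"H3.3"` (default) or `"H3-like"`.
#' @return The manifest, invisibly.
#' @export
write_fixture_set <- function(config, out_dir, mode = "H3.3") {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    io_error(sprintf("cannot create output directory %s", out_dir))
  assembly <- make_assembly(config)
  wt <- simulate_wt_k27me3(assembly, config)
  onco <- simulate_oncohistone(assembly, mode, config, wt)
  mut <- simulate_mut_k27me3(wt, onco, dependency_model(config$dependency),
                             noise_sd = config$mut_noise_sd,
                             seed = config$seed)
  genes <- simulate_gene_table(assembly, config, wt, mut)
  dapi <- simulate_dapi(config)

  p <- function(f) file.path(out_dir, f)
  write_bedgraph(wt, p("wt_k27me3_logratio.bedgraph"))
  write_bedgraph(onco, p("oncohistone_logratio.bedgraph"))
  write_bedgraph(mut, p("mut_k27me3_logratio.bedgraph"))
  write_tsv <- function(df, f) utils::write.table(
    df, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv(as.data.frame(assembly), "assembly.tsv")
  gdf <- as.data.frame(genes)
  gdf$wt_expression <- fmt_num(gdf$wt_expression)
  gdf$mut_expression <- fmt_num(gdf$mut_expression)
  gdf$log2_fc <- fmt_num(gdf$log2_fc)
  gdf$fc <- fmt_num(gdf$fc)
  gdf$fdr <- fmt_num(gdf$fdr)
  gdf$delta_k27me3 <- fmt_num(gdf$delta_k27me3)
  write_tsv(gdf, "genes.tsv")
  ddf <- dapi
  ddf$intensity <- fmt_num(ddf$intensity)
  write_tsv(ddf, "dapi.tsv")

  manifest <- list(
    seed = config$seed,
    config_hash = config_hash(unclass(config)),
    mode = mode,
    bin_size = config$bin_size,
    files = list(
      wt_k27me3 = "wt_k27me3_logratio.bedgraph",
      oncohistone = "oncohistone_logratio.bedgraph",
      mut_k27me3 = "mut_k27me3_logratio.bedgraph",
      assembly = "assembly.tsv",
      genes = "genes.tsv",
      dapi = "dapi.tsv"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             p("manifest.json"))
  invisible(manifest)
}
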