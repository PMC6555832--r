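# Shared fixtures and independent oracles used across the suite.

tiny_assembly <- function() {
  genome_assembly(c("chr1", "chr2", "chrX"),
                  c(10000, 8000, 6000),
                  c("autosome", "autosome", "X"))
}

small_config <- function(seed = 7L, ...) {
  args <- utils::modifyList(
    list(bin_size = 1000L, n_autosomes = 2L, autosome_length = 100000L,
         x_length = 60000L, domain_mean_length = 10000L,
         onco_mean_length = 8000L, n_genes = 60L, n_de = 20L,
         n_nuclei = 20L),
    list(...))
  do.call(synthetic_config, c(list(seed = seed), args))
}

# Default stated world at full (10 Mb / 10,000 bin) scale.
default_world <- local({
  cache <- new.env()
  function(seed = 1L, mode = "H3.3") {
    key <- paste0(seed, "_", mode)
    if (!is.null(cache[[key]])) return(cache[[key]])
    cfg <- synthetic_config(seed = seed)
    assembly <- make_assembly(cfg)
    wt <- simulate_wt_k27me3(assembly, cfg)
    onco <- simulate_oncohistone(assembly, mode, cfg, wt)
    mut <- simulate_mut_k27me3(wt, onco, table1_model(),
                               noise_sd = cfg$mut_noise_sd, seed = cfg$seed)
    cache[[key]] <- list(config = cfg, assembly = assembly, wt = wt,
                         onco = onco, mut = mut)
    cache[[key]]
  }
})

random_logratio_track <- function(assembly, bin_size, seed) {
  nb <- assembly_bins(assembly, bin_size)
  vals <- with_seed_test(seed, lapply(nb, function(n) stats::rnorm(n)))
  binned_track(assembly, bin_size, vals, state = "logratio")
}

random_raw_track <- function(assembly, bin_size, seed, total = NULL) {
  nb <- assembly_bins(assembly, bin_size)
  vals <- with_seed_test(seed, lapply(nb, function(n)
    stats::rpois(n, 10) + stats::runif(n)))
  binned_track(assembly, bin_size, vals, state = "raw", read_total = total)
}

# Local seed sandbox for test-side randomness.
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Independent adjusted Rand index from the contingency-table closed form.
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(as.vector(tab))
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# Independent presence cleanup + category scan (explicit loops, no rle).
domain_scan_oracle <- function(wt_v, mut_v, tau, m, g, is_x) {
  clean <- function(p) {
    n <- length(p)
    # drop short TRUE runs
    i <- 1
    while (i <= n) {
      if (p[i]) {
        j <- i
        while (j < n && p[j + 1]) j <- j + 1
        if (j - i + 1 < m) p[i:j] <- FALSE
        i <- j + 1
      } else i <- i + 1
    }
    # bridge short FALSE gaps between TRUE runs
    q <- p
    i <- 1
    while (i <= n) {
      if (!p[i]) {
        j <- i
        while (j < n && !p[j + 1]) j <- j + 1
        if (i > 1 && j < n && (j - i + 1) <= g) q[i:j] <- TRUE
        i <- j + 1
      } else i <- i + 1
    }
    q
  }
  wp <- clean(wt_v > tau)
  mp <- clean(mut_v > tau)
  out <- character(length(wt_v))
  for (i in seq_along(wt_v)) {
    out[i] <- if (is_x) {
      if (wp[i] && mp[i]) "iv_chrX_maintained" else "iii_never"
    } else {
      if (wp[i] && mp[i]) "i_maintained"
      else if (wp[i]) "ii_lost" else "iii_never"
    }
  }
  out
}

# Enumerate all permutations of 1..n (tiny n only).
perms_oracle <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms_oracle(n - 1L))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}
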