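test_that("every generator is bit-for-bit reproducible under a fixed seed", {
  cfg <- small_config(seed = 42L)
  a <- make_assembly(cfg)
  wt1 <- simulate_wt_k27me3(a, cfg); wt2 <- simulate_wt_k27me3(a, cfg)
  expect_identical(wt1$values, wt2$values)
  on1 <- simulate_oncohistone(a, "H3.3", cfg, wt1)
  on2 <- simulate_oncohistone(a, "H3.3", cfg, wt2)
  expect_identical(on1$values, on2$values)
  m1 <- simulate_mut_k27me3(wt1, on1, seed = cfg$seed)
  m2 <- simulate_mut_k27me3(wt2, on2, seed = cfg$seed)
  expect_identical(m1$values, m2$values)
  g1 <- simulate_gene_table(a, cfg, wt1, m1)
  g2 <- simulate_gene_table(a, cfg, wt2, m2)
  expect_identical(g1, g2)
  expect_identical(simulate_dapi(cfg), simulate_dapi(cfg))
})

test_that("wild-type track: X baseline high, domain fraction honoured", {
  cfg <- small_config(seed = 5L)
  a <- make_assembly(cfg)
  wt <- simulate_wt_k27me3(a, cfg)
  expect_gt(mean(track_values(wt, "chrX")),
            mean(track_values(wt, c("chrI", "chrII"))))
  cfg0 <- small_config(seed = 5L, domain_fraction = 0, noise_sd = 0)
  wt0 <- simulate_wt_k27me3(make_assembly(cfg0), cfg0)
  expect_true(all(track_values(wt0, c("chrI", "chrII")) == 0))
})

test_that("planted wt domains are recovered by a run-length scan of the noiseless track", {
  cfg <- small_config(seed = 9L, noise_sd = 0)
  a <- make_assembly(cfg)
  wt <- simulate_wt_k27me3(a, cfg)
  mid <- (cfg$domains$level + cfg$domains$background) / 2
  for (ch in c("chrI", "chrII")) {
    r <- rle(wt$values[[ch]] > mid)
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1) + 1L)
    keep <- r$values
    oracle <- data.frame(start_bin = starts[keep], end_bin = ends[keep])
    planted <- attr(wt, "domains")[[ch]]
    expect_equal(unname(as.matrix(oracle)), unname(as.matrix(planted)))
  }
})

test_that("oncohistone H3.3 mode depletes X to the configured ratio", {
  cfg <- small_config(seed = 11L, noise_sd = 0, x_depletion_factor = 0.1)
  a <- make_assembly(cfg)
  wt <- simulate_wt_k27me3(a, cfg)
  on <- simulate_oncohistone(a, "H3.3", cfg, wt)
  ratio <- mean(track_values(on, "chrX")) /
    mean(track_values(on, c("chrI", "chrII")))
  expect_lte(ratio, 0.1 + 1e-12)
  expect_error(simulate_oncohistone(a, "H2A", cfg, wt),
               class = "oncochrom_config_error")
})

test_that("H3-like mode with spread 1 matches the H3.3 footprint except X retention", {
  cfg <- small_config(seed = 13L, noise_sd = 0, onco_spread = 1)
  a <- make_assembly(cfg)
  wt <- simulate_wt_k27me3(a, cfg)
  h33 <- simulate_oncohistone(a, "H3.3", cfg, wt)
  h3l <- simulate_oncohistone(a, "H3-like", cfg, wt)
  for (ch in c("chrI", "chrII"))
    expect_identical(h33$values[[ch]], h3l$values[[ch]])
  expect_gt(mean(track_values(h3l, "chrX")),
            mean(track_values(h33, "chrX")))
  # H3-like X is not depleted: X mean equals the autosomal mean
  expect_equal(mean(track_values(h3l, "chrX")),
               mean(track_values(h3l, c("chrI", "chrII"))))
})

test_that("widened H3-like domains cover the interval-union footprint", {
  cfg <- small_config(seed = 17L, noise_sd = 0, onco_spread = 2.5)
  a <- make_assembly(cfg)
  wt <- simulate_wt_k27me3(a, cfg)
  on <- simulate_oncohistone(a, "H3-like", cfg, wt)
  nb <- assembly_bins(a, cfg$bin_size)
  for (ch in c("chrI", "chrII")) {
    iv <- attr(on, "intervals_placed")[[ch]]
    covered <- logical(nb[[ch]])
    for (i in seq_len(nrow(iv))) covered[iv$start_bin[i]:iv$end_bin[i]] <- TRUE
    expect_equal(on$values[[ch]] > 0, covered)
  }
})

test_that("mutant track is the dependency image plus seed-controlled noise", {
  cfg <- small_config(seed = 19L)
  a <- make_assembly(cfg)
  wt <- simulate_wt_k27me3(a, cfg)
  on <- simulate_oncohistone(a, "H3.3", cfg, wt)
  model <- table1_model()
  m0 <- simulate_mut_k27me3(wt, on, model, noise_sd = 0, seed = 1L)
  expect_equal(m0$values$chrI,
               evaluate_dependency(model, wt$values$chrI, on$values$chrI))
  # x = y everywhere gives a constant track at A0
  const <- binned_track(a, cfg$bin_size, 1.25, state = "logratio")
  mc <- simulate_mut_k27me3(const, const, model, noise_sd = 0, seed = 1L)
  expect_true(all(track_values(mc) == -0.709110206))
  # sample SD of the injected noise within 3 SE of its closed form
  big <- synthetic_config(seed = 19L)
  bw <- default_world(seed = 19L)
  mn <- simulate_mut_k27me3(bw$wt, bw$onco, model, noise_sd = 0.1, seed = 7L)
  eps <- track_values(mn) - unlist(attr(mn, "noiseless"), use.names = FALSE)
  n <- length(eps)
  se_sd <- 0.1 / sqrt(2 * (n - 1))
  expect_lt(abs(sd(eps) - 0.1), 3 * se_sd)
  expect_error(simulate_mut_k27me3(wt, rebin(on, 2000)),
               class = "oncochrom_dimension_error")
})

test_that("gene table plants DE labels, signs and consistent statistics", {
  cfg <- small_config(seed = 23L)
  a <- make_assembly(cfg)
  wt <- simulate_wt_k27me3(a, cfg)
  mut <- simulate_mut_k27me3(wt, simulate_oncohistone(a, "H3.3", cfg, wt),
                             seed = cfg$seed)
  g <- simulate_gene_table(a, cfg, wt, mut)
  expect_equal(nrow(g), cfg$genes$n)
  # non-overlapping placement within bounds
  for (ch in unique(g$chrom)) {
    gc <- g[g$chrom == ch, ]
    gc <- gc[order(gc$start), ]
    expect_true(all(gc$start >= 0))
    expect_true(all(gc$end <= a$length[a$name == ch]))
    if (nrow(gc) > 1) expect_true(all(head(gc$end, -1) <= tail(gc$start, -1)))
  }
  # de_filter recovers the planted labels exactly
  gf <- de_filter(g)
  expect_identical(as.character(gf$de_status), g$planted_status)
  # anti-correlation strength 1: sign(dexpr) opposite to sign(dK27me3)
  de <- g[g$planted_status != "ns", ]
  nz <- abs(de$delta_k27me3) > 1e-12
  expect_true(all(sign(de$log2_fc[nz]) == -sign(de$delta_k27me3[nz])))
  # Spearman over DE genes negative, matching explicit rank computation
  rx <- rank(de$log2_fc); ry <- rank(de$delta_k27me3)
  rho_oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_lt(rho_oracle, 0)
  expect_equal(cor(de$log2_fc, de$delta_k27me3, method = "spearman"),
               rho_oracle)
  # n_de = 0 -> all ns
  cfg0 <- small_config(seed = 23L, n_de = 0L)
  g0 <- simulate_gene_table(a, cfg0, wt, mut)
  expect_true(all(g0$planted_status == "ns"))
})

test_that("DAPI simulation follows the linear content map", {
  cfg0 <- small_config(seed = 29L, dapi_cv = 0)
  d0 <- simulate_dapi(cfg0)
  oo <- d0$intensity[d0$population == "oocyte_diakinesis"]
  ii <- d0$intensity[d0$population == "intestine"]
  expect_true(all(oo == cfg0$dapi$intercept + cfg0$dapi$slope * 4))
  expect_true(all(ii == cfg0$dapi$intercept + cfg0$dapi$slope * 32))
  expect_true(all(d0$intensity[d0$population == "endomitotic"] > max(ii)))
  expect_error(small_config(dapi_cv = -0.1), class = "oncochrom_config_error")
  # noisy sample means within 3 SE of the population means (n = 50)
  cfg <- synthetic_config(seed = 29L, dapi_cv = 0.1, n_nuclei = 50L)
  d <- simulate_dapi(cfg)
  for (p in unique(d$population)) {
    x <- d$intensity[d$population == p]
    mu <- cfg$dapi$intercept +
      cfg$dapi$slope * d$true_content[d$population == p][1]
    expect_lt(abs(mean(x) - mu), 3 * (0.1 * mu) / sqrt(length(x)))
  }
})

test_that("write_fixture_set round-trips and is byte-identical on re-run", {
  cfg <- small_config(seed = 31L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  man <- write_fixture_set(cfg, d1)
  expect_equal(man$seed, cfg$seed)
  write_fixture_set(cfg, d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  a <- make_assembly(cfg)
  wt <- simulate_wt_k27me3(a, cfg)
  back <- read_bedgraph(file.path(d1, "wt_k27me3_logratio.bedgraph"),
                        a, cfg$bin_size)
  expect_equal(back$values, wt$values, tolerance = 1e-9)
  manifest <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(manifest$seed, cfg$seed)
})
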