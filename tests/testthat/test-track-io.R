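one_chrom <- function(len = 10000) {
  genome_assembly(c("c1", "cX"), c(len, 1000), c("autosome", "X"))
}

test_that("bin_coverage computes max per-base depth, fragments spanning edges", {
  a <- genome_assembly(c("c1", "cX"), c(100, 100), c("autosome", "X"))
  t1 <- bin_coverage(list(c1 = cbind(0, 10)), a, 100)
  expect_equal(t1$values$c1, 1)
  expect_equal(t1$values$cX, 0)
  t2 <- bin_coverage(list(c1 = rbind(c(0, 10), c(5, 15))), a, 100)
  expect_equal(t2$values$c1, 2)
  # spanning a bin edge contributes to both bins
  a2 <- genome_assembly(c("c1", "cX"), c(200, 100), c("autosome", "X"))
  t3 <- bin_coverage(list(c1 = cbind(90, 110)), a2, 100)
  expect_equal(t3$values$c1, c(1, 1))
  expect_error(bin_coverage(list(c1 = cbind(50, 150)), a, 100),
               class = "oncochrom_validation_error")
})

test_that("bin_coverage matches a per-base depth oracle on random fragments", {
  a <- one_chrom(10000)
  frags <- with_seed_test(11, {
    s <- sample(0:9900, 200, replace = TRUE)
    cbind(s, s + sample(50:100, 200, replace = TRUE))
  })
  tr <- bin_coverage(list(c1 = frags), a, 1000)
  depth <- numeric(10000)
  for (i in seq_len(nrow(frags)))
    depth[(frags[i, 1] + 1):frags[i, 2]] <- depth[(frags[i, 1] + 1):frags[i, 2]] + 1
  oracle <- vapply(1:10, function(b) max(depth[((b - 1) * 1000 + 1):(b * 1000)]), 0)
  expect_equal(tr$values$c1, oracle)
  # count statistic oracle
  trc <- bin_coverage(list(c1 = frags), a, 1000, stat = "count")
  oc <- vapply(1:10, function(b) {
    lo <- (b - 1) * 1000; hi <- b * 1000
    sum(frags[, 1] < hi & frags[, 2] > lo)
  }, 0)
  expect_equal(trc$values$c1, oc)
})

test_that("scale_to_total is exactly linear", {
  a <- one_chrom()
  tr <- random_raw_track(a, 1000, seed = 1, total = 5e5)
  expect_equal(scale_to_total(tr, 5e5)$values, tr$values)
  expect_equal(scale_to_total(tr, 1e6)$values$c1, tr$values$c1 * 2)
  expect_equal(scale_to_total(tr, 123456)$values$c1,
               tr$values$c1 * 123456 / 5e5)
  expect_error(scale_to_total(tr, 1e6, read_total = 0),
               class = "oncochrom_normalization_error")
})

test_that("normalize_input implements delta and logratio", {
  a <- one_chrom()
  ip <- random_raw_track(a, 1000, seed = 2, total = 1e6)
  ip$state <- "scaled"
  inp <- random_raw_track(a, 1000, seed = 3, total = 1e6)
  inp$state <- "scaled"
  expect_true(all(track_values(normalize_input(ip, ip, "delta")) == 0))
  two <- ip; two$values <- lapply(ip$values, function(v) 2 * v)
  expect_equal(track_values(normalize_input(two, ip, "logratio", pseudocount = 0)),
               rep(1, 11))
  # elementwise oracle with pseudocount 1
  lr <- normalize_input(ip, inp, "logratio", pseudocount = 1)
  expect_equal(lr$values$c1, log2((ip$values$c1 + 1) / (inp$values$c1 + 1)))
  dl <- normalize_input(ip, inp, "delta")
  expect_equal(dl$values$c1, ip$values$c1 - inp$values$c1)
  # antisymmetry at pseudocount 0 on positive tracks
  lr_ab <- normalize_input(ip, inp, "logratio", pseudocount = 0)
  lr_ba <- normalize_input(inp, ip, "logratio", pseudocount = 0)
  expect_equal(track_values(lr_ab), -track_values(lr_ba))
  b <- random_raw_track(genome_assembly(c("c1", "cX"), c(5000, 1000),
                                        c("autosome", "X")), 1000, seed = 4)
  b$state <- "scaled"
  expect_error(normalize_input(ip, b, "delta"),
               class = "oncochrom_dimension_error")
})

test_that("merge_replicates sums values and totals", {
  a <- one_chrom()
  t1 <- random_raw_track(a, 1000, seed = 5, total = 100)
  expect_equal(merge_replicates(list(t1))$values, t1$values)
  m2 <- merge_replicates(list(t1, t1))
  expect_equal(m2$values$c1, 2 * t1$values$c1)
  expect_equal(m2$read_total, 200)
  t2 <- random_raw_track(a, 1000, seed = 6, total = 50)
  t3 <- random_raw_track(a, 1000, seed = 7, total = 70)
  m3 <- merge_replicates(list(t1, t2, t3))
  expect_equal(m3$values$c1, t1$values$c1 + t2$values$c1 + t3$values$c1)
  expect_equal(m3$read_total, 220)
  expect_error(merge_replicates(list()), class = "oncochrom_validation_error")
})

test_that("smooth_track is a centered running mean with edge truncation", {
  a <- genome_assembly(c("c1", "cX"), c(100000, 1000), c("autosome", "X"))
  tr <- random_logratio_track(a, 1000, seed = 8)
  expect_equal(smooth_track(tr, 1L)$values, tr$values)
  ct <- binned_track(a, 1000, list(c1 = rep(2.5, 100), cX = rep(2.5, 1)),
                     state = "logratio")
  expect_equal(smooth_track(ct, 7L)$values$c1, rep(2.5, 100))
  sm <- smooth_track(tr, 5L)
  v <- tr$values$c1
  oracle <- vapply(seq_along(v), function(i) {
    w <- max(1, i - 2):min(length(v), i + 2)
    mean(v[w])
  }, 0)
  expect_equal(sm$values$c1, oracle)
  # never exceeds input range, never crosses chromosome boundaries
  expect_true(min(sm$values$c1) >= min(v) && max(sm$values$c1) <= max(v))
  expect_equal(sm$values$cX, tr$values$cX)
  expect_error(smooth_track(tr, 4L), class = "oncochrom_validation_error")
})

test_that("rebin averages constituent fine bins with the ceiling rule", {
  a <- genome_assembly(c("c1", "cX"), c(10000, 3500), c("autosome", "X"))
  tr <- binned_track(a, 1000, list(c1 = rep(2, 10), cX = rep(1, 4)),
                     state = "logratio")
  expect_identical(rebin(tr, 1000), tr)
  r <- rebin(tr, 10000)
  expect_equal(r$values$c1, 2)
  expect_equal(r$values$cX, 1)  # partial group averaged over members present
  rt <- random_logratio_track(a, 1000, seed = 9)
  r2 <- rebin(rt, 5000)
  oracle <- vapply(1:2, function(b) mean(rt$values$c1[((b - 1) * 5 + 1):(b * 5)]), 0)
  expect_equal(r2$values$c1, oracle)
  expect_equal(r2$values$cX, mean(rt$values$cX))
  expect_error(rebin(tr, 1500), class = "oncochrom_validation_error")
})

test_that("bedGraph round-trips and parses hand-written files", {
  a <- genome_assembly(c("c1", "cX"), c(5500, 3000), c("autosome", "X"))
  tr <- random_logratio_track(a, 1000, seed = 10)
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, f)
  back <- read_bedgraph(f, a, 1000)
  expect_equal(back$values$c1, tr$values$c1, tolerance = 1e-9)
  expect_equal(back$values$cX, tr$values$cX, tolerance = 1e-9)
  # writing the re-read track reproduces the file byte for byte
  f2 <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(back, f2)
  expect_identical(readLines(f), readLines(f2))
  # empty file reads as an all-zero track
  writeLines(character(0), f2)
  z <- read_bedgraph(f2, a, 1000)
  expect_true(all(track_values(z) == 0))
  # hand-written file with run-spanning record and partial trailing bin
  writeLines(c("c1\t0\t2000\t1.5",
               "c1\t3000\t4000\t-0.25",
               "cX\t0\t1000\t2",
               "cX\t2000\t3000\t0.5",
               "c1\t5000\t5500\t3"), f2)
  h <- read_bedgraph(f2, a, 1000)
  expect_equal(h$values$c1, c(1.5, 1.5, 0, -0.25, 0, 3))
  expect_equal(h$values$cX, c(2, 0, 0.5))
})

test_that("bedGraph parse errors carry line numbers", {
  a <- genome_assembly(c("c1", "cX"), c(5000, 3000), c("autosome", "X"))
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("c1\t0\t1000\t1", "chrUn\t0\t1000\t1"), f)
  expect_error(read_bedgraph(f, a, 1000), "2.*chrUn",
               class = "oncochrom_parse_error")
  writeLines(c("c1\t0\t2000\t1", "c1\t1000\t3000\t2"), f)
  expect_error(read_bedgraph(f, a, 1000), "overlap",
               class = "oncochrom_parse_error")
  writeLines("c1\t0\t1500\t1", f)
  expect_error(read_bedgraph(f, a, 1000), "aligned",
               class = "oncochrom_parse_error")
  writeLines("c1\t0\t1000", f)
  expect_error(read_bedgraph(f, a, 1000), "4 fields",
               class = "oncochrom_parse_error")
})

test_that("coverage_uniformity reports log ratios and dispersion", {
  a <- one_chrom()
  s <- random_raw_track(a, 1000, seed = 12)
  s$state <- "scaled"
  r <- coverage_uniformity(s, s)
  expect_true(all(r$log2_ratio == 0))
  expect_equal(r$outlier_fraction, 0)
  # one bin doubled -> exactly one bin at log2 ratio 1 (pseudocount 0)
  s2 <- s
  s2$values$c1[3] <- 2 * s$values$c1[3]
  r2 <- coverage_uniformity(s2, s, pseudocount = 0, tau = 0.5)
  expect_equal(sum(abs(r2$log2_ratio - 1) < 1e-12), 1L)
  expect_equal(r2$outlier_fraction, 1 / 11)
  # dispersion matches an elementwise recompute
  o <- random_raw_track(a, 1000, seed = 13)
  o$state <- "scaled"
  r3 <- coverage_uniformity(s, o, pseudocount = 1)
  lr <- log2((track_values(s) + 1) / (track_values(o) + 1))
  expect_equal(r3$sd, sd(lr))
  expect_equal(r3$mad, mad(lr))
})
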