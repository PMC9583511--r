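mk_1mb <- function(counts, gm, cell = "c1", fraction = "G1") {
  structure(list(cell = cell, condition = "control", fraction = fraction,
                 binsize = "1Mb", counts = as.integer(counts),
                 total = sum(counts), truth = NULL),
            class = "cell_profile")
}

test_that("bin proportions and the low-coverage exclusion behave as stated", {
  gm <- tiny_genome(c(chr1 = 1e7 * ceiling(100 / 10)))  # 100 x 1 Mb bins
  n <- nrow(bin_grid(gm, "1Mb"))
  eq <- normalize_cell_bins(mk_1mb(rep(50L, n), gm), gm)
  expect_equal(eq$prop, rep(1 / n, n))
  expect_true(all(eq$usable))

  cnt <- rep(100L, n); cnt[7] <- 1L
  one <- normalize_cell_bins(mk_1mb(cnt, gm), gm)
  expect_false(one$usable[7])
  expect_equal(sum(!one$usable), 1L)  # only the near-empty bin falls below

  expect_error(normalize_cell_bins(mk_1mb(rep(0L, n), gm), gm), "zero total")
})

test_that("sex-stratified quantiles treat X bins separately", {
  gm <- make_genome(list(chrom_lengths = c(chr1 = 9e7, chrX = 1e7)), seed = 1)
  bins <- bin_grid(gm, "1Mb")
  cnt <- ifelse(bins$chrom == "chrX", 50L, 100L)  # male: X at half coverage
  pooled <- normalize_cell_bins(mk_1mb(cnt, gm), gm)
  strat <- normalize_cell_bins(mk_1mb(cnt, gm), gm, sex_stratified = TRUE)
  expect_true(all(!pooled$usable[bins$chrom == "chrX"]))
  expect_true(all(strat$usable[bins$chrom == "chrX"]))
})

test_that("G1 correction factors invert the reference profile", {
  gm <- tiny_genome(c(chr1 = 1e8))
  n <- nrow(bin_grid(gm, "1Mb"))
  uni <- g1_correction_factors(list(normalize_cell_bins(mk_1mb(rep(10L, n), gm), gm)))
  expect_equal(uni$factor, rep(1, n))

  cnt <- rep(100, n); cnt[3] <- 50
  g1n <- list(prop = cnt / sum(cnt), usable = rep(TRUE, n))
  fac <- g1_correction_factors(list(g1n))
  avg <- mean(g1n$prop[fac$usable])
  expect_equal(fac$factor[3], avg / g1n$prop[3])
  expect_equal(fac$factor[3] / fac$factor[5], 2, tolerance = 1e-9)
  # applying the factors to the reference flattens it
  corr <- g1n$prop * fac$factor
  expect_lt(stats::sd(corr[fac$usable]) / mean(corr[fac$usable]), 1e-12)
  expect_error(g1_correction_factors(list()), "G1")
})

test_that("binarization picks the top-p fraction with deterministic ties", {
  # synthetic 8-bin case built directly
  norm <- list(prop = c(1:8) / 36, usable = rep(TRUE, 8))
  fac <- list(factor = rep(1, 8), usable = rep(TRUE, 8))
  b <- binarize_replication(norm, fac, 0.25)
  expect_equal(which(b$replicated), c(7L, 8L))
  b2 <- binarize_replication(norm, fac, 0.875)
  expect_equal(sum(b2$replicated), 7L)
  expect_false(b2$replicated[1])

  tied <- list(prop = rep(0.125, 8), usable = rep(TRUE, 8))
  expect_warning(bt <- binarize_replication(tied, fac, 0.5), "index order")
  expect_equal(which(bt$replicated), 1:4)
  expect_error(binarize_replication(norm, fac, 1.5), "in \\(0,1\\)")
})

test_that("RTF sums the four per-fraction proportions with quartile labels", {
  gm <- tiny_genome(c(chr1 = 2e7))
  n <- nrow(bin_grid(gm, "1Mb"))
  mk_call <- function(repl) list(replicated = repl, usable = rep(TRUE, n))
  all_on <- rep(TRUE, n); all_off <- rep(FALSE, n)
  half_a <- rep(c(TRUE, FALSE), length.out = n)
  half_b <- !half_a

  # bin 1 replicated in every cell of every fraction; bin 2 in none;
  # alternating half coverage gives RTF 2
  calls <- lapply(1:4, function(f) list(mk_call(half_a), mk_call(half_b)))
  names(calls) <- paste0("S", 1:4)
  rt <- replication_timing_factor(calls, gm)
  expect_equal(rt$rtf, rep(2, n))
  expect_true(all(rt$usable))

  calls2 <- lapply(1:4, function(f) list(mk_call(all_on), mk_call(all_on)))
  rt2 <- replication_timing_factor(calls2, gm)
  expect_equal(rt2$rtf, rep(4, n))
  calls3 <- lapply(1:4, function(f) list(mk_call(all_off)))
  rt3 <- replication_timing_factor(calls3, gm)
  expect_equal(rt3$rtf, rep(0, n))

  # graded profile: quartile categories partition and are monotone in RTF
  grade <- lapply(1:4, function(f)
    list(mk_call(seq_len(n) > n * (f - 1) / 4)))
  rtg <- replication_timing_factor(grade, gm)
  expect_true(all(rtg$rtf >= 0 & rtg$rtf <= 4))
  lev <- c("late", "mid-late", "mid-early", "early")
  expect_true(all(diff(match(rtg$quartile, lev)[order(rtg$rtf)]) >= 0))

  expect_error(replication_timing_factor(calls[1:3], gm), "four")
  calls_bad <- calls; calls_bad$S2 <- list()
  expect_error(replication_timing_factor(calls_bad, gm), "S2")
})

test_that("every binarized cell replicates its gate's expected fraction", {
  gm <- tiny_genome(c(chr1 = 5e7, chr2 = 5e7))
  rt_truth <- make_truth_rt(gm, seed = 3)
  g1 <- simulate_g1_cells(gm, NULL, n_cells = c(control = 5),
                          gc_bias_strength = 0, binsizes = "1Mb", seed = 4)
  sp <- simulate_sphase_cells(gm, rt_truth, n_cells = 8, seed = 5)
  prof <- compute_rt_profile(sp, g1, gm)
  calls <- attr(prof, "calls")
  ps <- c(S1 = 0.125, S2 = 0.375, S3 = 0.635, S4 = 0.875)
  for (f in names(calls)) for (cl in calls[[f]]) {
    n_use <- sum(cl$usable)
    expect_lte(abs(sum(cl$replicated) / n_use - ps[[f]]), 1 / n_use)
  }
})

test_that("delta RT flags only genuine extreme timing shifts", {
  gm <- tiny_genome(c(chr1 = 1e8, chr2 = 1e8))
  bins <- bin_grid(gm, "1Mb")
  n <- nrow(bins)
  base <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                     usable = TRUE, rtf = rep(2, n))
  same <- delta_rt(base, base)
  expect_true(all(same$delta_rt == 0))
  expect_true(all(same$extreme == "none"))

  shifted <- base
  shifted$rtf[10] <- 0
  d <- delta_rt(shifted, base)
  expect_equal(d$extreme[10], "later")
  expect_equal(sum(d$extreme == "later"), 1L)

  other <- base[-1, ]
  expect_error(delta_rt(base, other), "shape|grids")

  # continuous shifts flag ~2.5% per tail
  set.seed(9)
  t2 <- base; t2$rtf <- base$rtf + rnorm(n, 0, 0.2)
  d2 <- delta_rt(t2, base)
  expect_lte(abs(sum(d2$extreme == "later") / n - 0.025), 1 / n + 1e-9)
  expect_lte(abs(sum(d2$extreme == "earlier") / n - 0.025), 1 / n + 1e-9)
})
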