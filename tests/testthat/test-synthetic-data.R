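test_that("genome bin grids tile chromosomes with truncated last bins", {
  gm <- make_genome(list(chrom_lengths = c(chr1 = 1e8, chr2 = 1e8)), seed = 1)
  expect_equal(nrow(bin_grid(gm, "1Mb")), 200L)

  gm2 <- make_genome(list(chrom_lengths = c(chrA = 1.003e8)), seed = 1)
  b <- bin_grid(gm2, "1Mb")
  last <- b[nrow(b), ]
  expect_equal(last$end - last$start, 0.3e6)
  # contiguous, sorted, non-overlapping
  expect_true(all(b$start[-1] == b$end[-nrow(b)]))
  expect_true(all(gm2$chromosomes$cen_start >= 0 &
                    gm2$chromosomes$cen_end <= gm2$chromosomes$length))
})

test_that("genome generation is seed-deterministic and GC stays in range", {
  cfg <- list(chrom_lengths = c(chr1 = 2e7, chr2 = 2e7))
  g1 <- make_genome(cfg, seed = 7)
  g2 <- make_genome(cfg, seed = 7)
  g3 <- make_genome(cfg, seed = 8)
  expect_identical(g1$bins, g2$bins)
  expect_false(identical(g1$bins[["40kb"]]$gc, g3$bins[["40kb"]]$gc))
  gc <- bin_grid(g1, "40kb")$gc
  expect_true(all(gc >= 0.3 & gc <= 0.6))
})

test_that("invalid genome configs are rejected", {
  expect_error(make_genome(list(chrom_lengths = c(chr1 = -5))), "positive")
  expect_error(make_genome(list(chrom_lengths = c(chr1 = 5e6))), "10 Mb")
  expect_error(make_genome(list(chrom_lengths = c(chr1 = 2e7),
                                bin_sizes = c(big = 5e6))), "10 bins")
})

test_that("feature sets honour class sizes, forced silence and determinism", {
  gm <- tiny_genome()
  fs <- make_features(gm, list(n_giant = 3, n_large = 4,
                               silent_genes = list(cell_type_A = "gene_01_ordinary")),
                      seed = 3)
  giants <- fs$genes[fs$genes$class == "giant", ]
  expect_equal(nrow(giants), 3L)
  expect_true(all(giants$length > 1e6))
  expect_true(all(fs$genes$length[fs$genes$class == "large"] > 6e5))
  expect_equal(fs$genes$cell_type_A[fs$genes$name == "gene_01_ordinary"], 0)
  expect_true(all(fs$repeats$coverage >= 0 & fs$repeats$coverage <= 1))
  expect_true(all(fs$genes$end <=
    gm$chromosomes$length[match(fs$genes$chrom, gm$chromosomes$chrom)]))

  fs2 <- make_features(gm, list(n_giant = 3, n_large = 4,
                                silent_genes = list(cell_type_A = "gene_01_ordinary")),
                       seed = 3)
  f1 <- tempfile(); f2 <- tempfile()
  write_bed(fs$genes, f1); write_bed(fs2$genes, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("G1 count expectations follow copy state, width and GC bias", {
  gm <- tiny_genome(c(chr1 = 4e7))
  # flat expectation: diploid, no CNAs, no GC bias
  prof <- simulate_g1_cells(gm, NULL, n_cells = c(control = 30),
                            gc_bias_strength = 0, binsizes = "1Mb", seed = 2)
  m <- rowMeans(vapply(prof, `[[`, numeric(40), "counts"))
  full <- which(diff(c(bin_grid(gm, "1Mb")$start, 4e7)) == 1e6)
  expect_lt(max(abs(m[full] / mean(m[full]) - 1)), 0.15)

  # one-copy loss halves the expectation over its bins
  tr <- truth_cna("chr1", 5e6, 20e6, 1L, clonality = "clonal")
  prof2 <- simulate_g1_cells(gm, tr, n_cells = c(control = 30),
                             gc_bias_strength = 0, binsizes = "1Mb", seed = 3)
  m2 <- rowMeans(vapply(prof2, `[[`, numeric(40), "counts"))
  loss_bins <- 6:20
  norm_bins <- setdiff(full, 5:21)
  expect_lt(abs(mean(m2[loss_bins]) / mean(m2[norm_bins]) - 0.5), 0.05)

  # clonal trisomy is carried by every cell of its condition
  tr3 <- truth_cna("chr1", 0, 4e7, 3L, clonality = "clonal",
                   condition = "control")
  prof3 <- simulate_g1_cells(gm, tr3, n_cells = c(control = 10), seed = 4,
                             binsizes = "1Mb")
  expect_true(all(vapply(prof3, function(p) nrow(cell_truth(p)$cnas) == 1, TRUE)))
})

test_that("mean counts regress on state x width x GC bias with high R2", {
  gm <- tiny_genome(c(chr1 = 4e7))   # 1000 bins at 40 kb
  tr <- truth_cna("chr1", 10e6, 25e6, 3L, clonality = "clonal")
  prof <- simulate_g1_cells(gm, tr, n_cells = c(control = 100),
                            dispersion = 0.1, gc_bias_strength = 0.5,
                            binsizes = "40kb", seed = 11)
  bins <- bin_grid(gm, "40kb")
  m <- rowMeans(vapply(prof, `[[`, numeric(nrow(bins)), "counts"))
  state <- cell_truth(prof[[1]])$state
  x <- state * (bins$end - bins$start) * gc_bias_factor(bins$gc, 0.5)
  fit <- stats::lm(m ~ x)
  expect_gt(summary(fit)$r.squared, 0.95)
})

test_that("simulator is seed-deterministic and validates configs", {
  gm <- tiny_genome()
  a <- simulate_g1_cells(gm, NULL, n_cells = c(control = 2), seed = 9)
  b <- simulate_g1_cells(gm, NULL, n_cells = c(control = 2), seed = 9)
  expect_identical(lapply(a, `[[`, "counts"), lapply(b, `[[`, "counts"))
  expect_error(simulate_g1_cells(gm, NULL, n_cells = c(control = 1),
                                 reads_per_cell = 0), "reads_per_cell")
  bad <- truth_cna("chr1", 0, 1e6, 1L)
  bad$rate <- 1.5
  expect_error(simulate_g1_cells(gm, bad, n_cells = c(control = 1)),
               "incidence rate")
  outside <- truth_cna("chr1", 0, 9e7, 1L)
  expect_error(simulate_g1_cells(gm, outside, n_cells = c(control = 1)),
               "outside genome")
})

test_that("S-phase fractions replicate the expected share of the genome", {
  gm <- tiny_genome(c(chr1 = 5e7, chr2 = 5e7))
  rt <- make_truth_rt(gm, seed = 2)
  # zero noise, early gate: the earliest-timing 12.5% of bins
  sp <- simulate_sphase_cells(gm, rt,
                              fractions = data.frame(label = "S1", p = 0.125),
                              n_cells = 5, noise = 0, p_jitter = 0, seed = 3)
  for (p in sp) {
    repl <- cell_truth(p)$replicated
    expect_lte(abs(mean(repl) - 0.125), 0.02)
    expect_true(min(rt[repl]) >= max(rt[!repl]))
  }
  # constant timing: replicated set is a random subset of size ~ p
  spc <- simulate_sphase_cells(gm, rep(0.5, 100),
                               fractions = data.frame(label = "S2", p = 0.375),
                               n_cells = 5, noise = 0.05, p_jitter = 0, seed = 4)
  for (p in spc)
    expect_lte(abs(mean(cell_truth(p)$replicated) - 0.375), 0.05)
  expect_error(simulate_sphase_cells(gm, rt, fractions = data.frame()),
               "empty fraction")
  expect_error(simulate_sphase_cells(gm, rt,
    fractions = data.frame(label = "S1", p = 1.2)), "in \\(0,1\\)")
})

test_that("late-gate replicated sets nest the early-gate sets", {
  gm <- tiny_genome(c(chr1 = 5e7, chr2 = 5e7))
  rt <- make_truth_rt(gm, seed = 5)
  fr <- data.frame(label = c("S1", "S4"), p = c(0.125, 0.875))
  nest <- replicate(100, NA_real_)
  sp <- simulate_sphase_cells(gm, rt, fr, n_cells = 100, seed = 6)
  early <- Filter(function(p) p$fraction == "S1", sp)
  late <- Filter(function(p) p$fraction == "S4", sp)
  for (k in seq_len(100)) {
    e <- cell_truth(early[[k]])$replicated
    l <- cell_truth(late[[k]])$replicated
    nest[k] <- mean(l[e])   # share of early-replicated bins also late-replicated
  }
  expect_gt(mean(nest), 0.95)
})
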