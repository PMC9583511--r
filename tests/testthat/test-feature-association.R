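test_that("random controls are seeded, length-proportional and mask-aware", {
  gm <- tiny_genome(c(chr1 = 6e7, chr2 = 3e7, chr3 = 1e7 + 0e0))
  a <- generate_random_controls(gm, 200, seed = 4)
  b <- generate_random_controls(gm, 200, seed = 4)
  expect_identical(a, b)
  expect_true(all(a$end - a$start <= 1e6))
  expect_true(all(a$start >= 0))

  # per-chromosome counts proportional to length (chi-square GoF)
  big <- generate_random_controls(gm, 10000, seed = 5)
  obs <- table(factor(big$chrom, levels = gm$chromosomes$chrom))
  expect_gt(stats::chisq.test(obs, p = gm$chromosomes$length /
                                sum(gm$chromosomes$length))$p.value, 0.01)

  # a mask covering 10% of the genome drops ~10% of 500 draws
  mask <- data.frame(chrom = "chr1", start = 0, end = 1e7)
  kept <- vapply(1:1000, function(s)
    nrow(generate_random_controls(gm, 500, seed = s, exclusion_mask = mask)),
    0)
  expect_lt(abs(mean(kept) - 450), 5)

  expect_warning(
    empty <- generate_random_controls(gm, 10, seed = 1,
      exclusion_mask = data.frame(chrom = c("chr1", "chr2", "chr3"),
                                  start = 0, end = c(6e7, 3e7, 1e7))),
    "every control")
  expect_equal(nrow(empty), 0L)
})

test_that("breakpoint extraction follows the terminal-CNA rule", {
  gm <- tiny_genome(c(chr1 = 1e8))
  x <- segs(seg("c", "chr1", 10e6, 15e6, 1),    # small: both ends
            seg("c", "chr1", 80e6, 100e6, 1),   # large terminal: start only
            seg("c", "chr1", 0, 25e6, 3),       # large terminal at 0: end only
            seg("c", "chr1", 30e6, 52e6, 3))    # large interstitial: both
  bp <- extract_breakpoints(classify_cna(x, gm), gm)
  expect_equal(bp$pos[bp$cna_id == "cna_0001"], c(10e6, 15e6))
  expect_equal(bp$pos[bp$cna_id == "cna_0002"], 80e6)
  expect_equal(bp$role[bp$cna_id == "cna_0002"], "interstitial")
  expect_equal(bp$pos[bp$cna_id == "cna_0003"], 25e6)
  expect_equal(sort(bp$pos[bp$cna_id == "cna_0004"]), c(30e6, 52e6))
  # whole-chromosome event has no interstitial breakpoint
  whole <- extract_breakpoints(classify_cna(seg("c", "chr1", 0, 1e8, 1), gm), gm)
  expect_equal(nrow(whole), 0L)
})

test_that("feature distances are zero inside, minimal-gap outside", {
  gm <- tiny_genome(c(chr1 = 1e8))
  feats <- data.frame(chrom = "chr1", start = c(20e6, 50e6),
                      end = c(22e6, 53e6), name = c("g1", "g2"))
  bp <- data.frame(chrom = "chr1", pos = c(21e6, 19.75e6, 40e6),
                   cna_id = c("a", "a", "b"), cna_class = "small_loss",
                   role = "left", stringsAsFactors = FALSE)
  d <- distance_to_nearest(bp, feats)
  expect_equal(d$breakpoints$distance, c(0, 0.25e6, 10e6))
  # per-CNA distance is the minimum over its breakpoints
  expect_equal(d$per_cna$distance[d$per_cna$cna_id == "a"], 0)
  # order of the feature table does not matter
  d2 <- distance_to_nearest(bp, feats[2:1, ])
  expect_equal(d2$breakpoints$distance, d$breakpoints$distance)
  expect_error(distance_to_nearest(bp, feats[0, ]), "non-empty")

  # a CNA with breakpoint distances (0.4 Mb, 3 Mb) counts as within 1 Mb;
  # proportion-within is monotone in the cutoff
  bp2 <- data.frame(chrom = "chr1", pos = c(20.4e6 - 0.8e6, 25e6),
                    cna_id = "c", cna_class = "small_loss", role = c("left", "right"))
  d3 <- distance_to_nearest(bp2, feats, cutoff = 1e6)
  expect_equal(d3$proportion_within$proportion_within, 1)
  p_small <- distance_to_nearest(bp, feats, cutoff = 1e5)$proportion_within
  p_big <- distance_to_nearest(bp, feats, cutoff = 1e8)$proportion_within
  expect_true(all(p_big$proportion_within >= p_small$proportion_within))
  expect_equal(p_big$proportion_within, c(1))
})

test_that("window expression sums mean expression of overlapping genes", {
  gm <- tiny_genome(c(chr1 = 1e8))
  genes <- data.frame(chrom = "chr1", start = c(20e6, 20.5e6, 24e6, 20.9e6),
                      end = c(20.2e6, 20.7e6, 25e6, 21.5e6),
                      name = paste0("g", 1:4), typeA = c(5, 7, 100, 3))
  bp <- data.frame(chrom = "chr1", pos = c(20.4e6, 60e6))
  we <- window_expression(bp, genes, "typeA", gm)
  # g1 + g2 inside; g4 straddles the window edge (21.4 Mb) and is included
  expect_equal(we$window_expression, c(5 + 7 + 3, 0))
  expect_error(window_expression(bp, genes, "nope", gm), "expression column")
})

test_that("breakpoint positions are normalized within genes and signed outside", {
  genes <- data.frame(chrom = "chr1", start = c(10e6, 40e6),
                      end = c(11e6, 41e6), name = c("fwd", "rev"),
                      strand = c("+", "-"), class = "giant")
  bp <- data.frame(chrom = "chr1",
                   pos = c(10.5e6, 10e6, 9.7e6, 40.2e6, 41.3e6, 20e6))
  out <- breakpoint_position_in_gene(bp, genes)
  expect_equal(out$position[1], 0.5)          # midpoint
  expect_equal(out$position[2], 0.0)          # at the 5' end (+ strand)
  expect_equal(out$offset_mb[3], -0.3)        # upstream of the 5' end
  expect_equal(out$position[4], 0.8)          # - strand: 5' end is the right edge
  expect_equal(out$offset_mb[5], -0.3)        # beyond right edge of - gene: upstream
  expect_equal(nrow(out), 5L)                 # pos 20 Mb: no gene within 1 Mb
})

test_that("repeat-bin enrichment matches the closed-form chi-square", {
  gm <- tiny_genome(c(chr1 = 1.2e7, chr2 = 1.2e7))
  # 24 bins; after trimming chromosome ends, 20 remain (10 top, 10 bottom)
  reps <- bin_grid(gm, "1Mb")[, 1:3]
  reps$coverage <- rep(c(0.9, 0.1), each = 12)  # chr1 bins dense, chr2 sparse
  bp_at <- function(chrom, bins, class) data.frame(
    chrom = chrom, pos = bins * 1e6 + 5e5, cna_id = paste0(class, seq_along(bins)),
    cna_class = class, role = "left", stringsAsFactors = FALSE)
  # 8 of 10 breakpoints in the dense half: chi-square = 3.6 exactly
  bp <- rbind(bp_at("chr1", 1:8, "small_loss"), bp_at("chr2", 1:2, "small_loss"))
  out <- repeat_bin_enrichment(bp, reps)
  expect_equal(out$chisq, 3.6, tolerance = 1e-10)
  expect_equal(out$p, stats::pchisq(3.6, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(out$prop_top, 0.8)
  expect_false(out$dropped)

  # expected count below 5 in a group: comparison dropped
  bp_few <- bp_at("chr1", 1:6, "large_loss")
  out2 <- repeat_bin_enrichment(rbind(bp, bp_few), reps)
  expect_true(out2$dropped[out2$cna_class == "large_loss"])
  expect_true(is.na(out2$p_adj[out2$cna_class == "large_loss"]))

  # proportional split: chi-square 0, p 1
  bp_even <- rbind(bp_at("chr1", 1:5, "small_gain"), bp_at("chr2", 1:5, "small_gain"))
  out3 <- repeat_bin_enrichment(bp_even, reps)
  expect_equal(out3$chisq[out3$cna_class == "small_gain"], 0)
  expect_equal(out3$p[out3$cna_class == "small_gain"], 1)
})

test_that("uniformly placed breakpoints yield uniform enrichment p-values", {
  gm <- tiny_genome(c(chr1 = 5.2e7, chr2 = 5.2e7))
  reps <- bin_grid(gm, "1Mb")[, 1:3]
  set.seed(31)
  reps$coverage <- stats::runif(nrow(reps))
  inner <- do.call(rbind, lapply(split(reps, reps$chrom), function(r)
    r[-c(1, nrow(r)), ]))
  ps <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    idx <- sample(nrow(inner), 200, replace = TRUE)
    bp <- data.frame(chrom = inner$chrom[idx], pos = inner$start[idx] + 5e5,
                     cna_id = as.character(seq_along(idx)),
                     cna_class = "small_loss", role = "left")
    repeat_bin_enrichment(bp, reps)$p
  }, 0)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("group comparisons match rank-test oracles", {
  # all groups identical: H ~ 0, adjusted p ~ 1
  same <- list(small_loss = c(1, 2, 3), large_loss = c(1, 2, 3),
               control = c(1, 2, 3))
  r <- compare_groups(same)
  expect_lt(r$kw$statistic, 1e-10)
  expect_true(all(r$dunn$p_adj > 0.99))

  # a far-shifted class is detected by Dunn and by a permutation test
  set.seed(7)
  shifted <- list(small_loss = stats::runif(15, 0, 1),
                  large_loss = stats::runif(15, 40, 50),
                  control = stats::runif(30, 40, 50))
  r2 <- compare_groups(shifted)
  expect_lt(r2$dunn$p_adj[r2$dunn$group == "small_loss"], 0.01)
  p_perm <- perm_rank_test(shifted, "small_loss", "control", n_perm = 5000)
  expect_lt(p_perm, 0.01)

  # on random data the Dunn p agrees with the permutation p within
  # Monte-Carlo error plus the normal-approximation allowance
  set.seed(11)
  for (k in 1:20) {
    vals <- list(a = stats::rnorm(12, 0.3 * stats::runif(1)), b = stats::rnorm(12),
                 control = stats::rnorm(15))
    rk <- compare_groups(vals, p_adjust = "none")
    p_dunn <- rk$dunn$p[rk$dunn$group == "a"]
    p_perm <- perm_rank_test(vals, "a", "control", n_perm = 4000, seed = k)
    tol <- 4 * sqrt(p_perm * (1 - p_perm) / 4000) + 0.03
    expect_lt(abs(p_dunn - p_perm), tol)
  }

  # two groups: Kruskal-Wallis collapses to the Wilcoxon rank-sum test
  set.seed(13)
  for (k in 1:20) {
    x <- stats::rnorm(10 + k %% 5); y <- stats::rnorm(12)
    kw <- stats::kruskal.test(c(x, y), rep(1:2, c(length(x), 12)))
    wc <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
    expect_equal(kw$p.value, wc$p.value, tolerance = 1e-10)
  }

  expect_error(compare_groups(list(a = 1:3)), "2 non-empty")
  expect_error(compare_groups(list(a = 1:3, b = 1:3), control = "control"),
               "missing")
  # tiny groups are flagged, not dropped
  r3 <- compare_groups(list(a = c(1, 2), control = stats::rnorm(10)))
  expect_true(r3$dunn$low_n)
})
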