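# Shared fixtures and independent oracles for the test suite.

tiny_genome <- function(lens = c(chr1 = 5e7, chr2 = 4e7), seed = 1L, ...) {
  make_genome(c(list(chrom_lengths = lens), list(...)), seed = seed)
}

seg <- function(cell, chrom, start, end, state, ploidy = 2L,
                resolution = "500kb") {
  data.frame(cell = cell, chrom = chrom, start = start, end = end,
             state = as.integer(state), ploidy = as.integer(ploidy),
             resolution = resolution, n_bins = NA_integer_,
             stringsAsFactors = FALSE)
}

segs <- function(...) do.call(rbind, list(...))

# Brute-force oracle for clonal grouping: pairwise qualification matrix,
# transitive closure by boolean matrix powers, then the cell-count rule.
# Returns a canonical list of sorted member-index vectors.
brute_force_clonal <- function(segments, overlap = 0.5, min_cells = 3L) {
  n <- nrow(segments)
  if (n == 0) return(list())
  q <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { q[i, j] <- TRUE; next }
    if (segments$chrom[i] != segments$chrom[j]) next
    if (segments$state[i] != segments$state[j]) next
    inter <- min(segments$end[i], segments$end[j]) -
      max(segments$start[i], segments$start[j])
    if (inter <= 0) next
    ro <- min(inter / (segments$end[i] - segments$start[i]),
              inter / (segments$end[j] - segments$start[j]))
    q[i, j] <- ro >= overlap
  }
  reach <- q
  for (k in seq_len(n)) reach <- reach | (reach %*% reach > 0)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    comp[reach[i, ]] <- cid
  }
  groups <- split(seq_len(n), comp)
  keep <- vapply(groups, function(idx)
    length(unique(segments$cell[idx])) >= min_cells, TRUE)
  unname(lapply(groups[keep], sort))
}

# Canonical member sets from find_clonal output (members column holds
# semicolon-joined input row indices).
clonal_member_sets <- function(events) {
  if (nrow(events) == 0) return(list())
  unname(lapply(strsplit(events$members, ";"),
                function(x) sort(as.integer(x))))
}

# Permutation test of mean-pooled-rank difference between one group and
# the control, holding the other groups' values in the pool: an
# independent check on the Dunn z-test p-value.
perm_rank_test <- function(values, group, control, n_perm = 2000,
                           seed = 1L) {
  set.seed(seed)
  x <- unlist(values, use.names = FALSE)
  g <- rep(names(values), lengths(values))
  r <- rank(x)
  obs <- abs(mean(r[g == group]) - mean(r[g == control]))
  idx <- which(g %in% c(group, control))
  n1 <- sum(g == group)
  stat <- replicate(n_perm, {
    pick <- sample(idx, n1)
    abs(mean(r[pick]) - mean(r[setdiff(idx, pick)]))
  })
  (1 + sum(stat >= obs - 1e-12)) / (n_perm + 1)
}

# Convert realized ground-truth events of simulated cells into a
# classified-CNA-like table, bypassing sequencing noise.
truth_to_classified <- function(profiles, genome, size_threshold = 2e7) {
  rows <- lapply(profiles, function(p) {
    ev <- cell_truth(p)$cnas
    if (is.null(ev) || nrow(ev) == 0) return(NULL)
    data.frame(cell = p$cell, condition = p$condition, chrom = ev$chrom,
               start = ev$start, end = ev$end, state = ev$state,
               ploidy = 2L, resolution = p$binsize, n_bins = NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  cls <- classify_cna(out, genome, size_threshold = size_threshold)
  cls$condition <- out$condition
  cls
}
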