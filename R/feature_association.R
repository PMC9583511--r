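#' Randomly placed in-silico control coordinates
#'
#' Draws control breakpoint coordinates uniformly over the genome
#' (chromosome chosen proportional to length) and pairs each retained
#' coordinate with a 1-Mb interval centred on it, clipped at chromosome
#' ends. Coordinates falling into an exclusion mask (unmappable or
#' excluded bins) are dropped, not resampled, mirroring the loss of
#' random coordinates during mapping.
#'
#' @param genome A \code{genome_model}.
#' @param n Number of coordinates to draw (default 500).
#' @param seed Integer seed.
#' @param exclusion_mask Optional data.frame of intervals
#'   (chrom/start/end) in which coordinates are discarded.
#' @param interval_size Width of the paired control intervals (default
#'   1 Mb).
#' @return Data.frame: chrom, pos, start, end (interval), one row per
#'   retained coordinate.
#' @export
generate_random_controls <- function(genome, n = 500L, seed = 1L,
                                     exclusion_mask = NULL,
                                     interval_size = 1e6) {
  if (n <= 0) stop("invalid config: n must be > 0")
  chroms <- genome$chromosomes
  set.seed(seed)
  ci <- sample(nrow(chroms), n, replace = TRUE, prob = chroms$length)
  pos <- floor(stats::runif(n) * chroms$length[ci])
  chrom <- chroms$chrom[ci]
  if (!is.null(exclusion_mask) && nrow(exclusion_mask) > 0) {
    drop <- logical(n)
    for (k in seq_len(nrow(exclusion_mask))) {
      drop <- drop | (chrom == exclusion_mask$chrom[k] &
                        pos >= exclusion_mask$start[k] &
                        pos < exclusion_mask$end[k])
    }
    chrom <- chrom[!drop]; pos <- pos[!drop]; ci <- ci[!drop]
  }
  if (length(pos) == 0) {
    warning("exclusion mask removed every control coordinate")
    return(data.frame(chrom = character(), pos = numeric(),
                      start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  }
  half <- interval_size / 2
  start <- pmax(0, pos - half)
  end <- pmin(chroms$length[ci], pos + half)
  data.frame(chrom = chrom, pos = pos, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Extract breakpoints from classified CNAs
#'
#' Small CNAs contribute both boundaries; large terminal CNAs contribute
#' only their interstitial breakpoint (the chromosome end is not a
#' breakpoint); large interstitial CNAs contribute both boundaries.
#'
#' @param classified Classified CNA data.frame
#'   (\code{\link{classify_cna}}).
#' @param genome A \code{genome_model}.
#' @param terminal_tolerance Distance from a chromosome end treated as
#'   "at the end" (default one 500-kb bin, matching classification).
#' @return Data.frame: chrom, pos, cna_id, cna_class, role (left, right
#'   or interstitial).
#' @export
extract_breakpoints <- function(classified, genome, terminal_tolerance = 5e5) {
  empty <- data.frame(chrom = character(), pos = numeric(),
                      cna_id = character(), cna_class = character(),
                      role = character(), stringsAsFactors = FALSE)
  if (is.null(classified) || nrow(classified) == 0) return(empty)
  chroms <- genome$chromosomes
  len <- chroms$length[match(classified$chrom, chroms$chrom)]
  rows <- lapply(seq_len(nrow(classified)), function(k) {
    x <- classified[k, ]
    at_start <- x$start <= terminal_tolerance
    at_end <- x$end >= len[k] - terminal_tolerance
    if (x$size_class == "large" && x$terminal) {
      if (at_start && at_end) return(NULL)  # whole chromosome: no interstitial breakpoint
      pos <- if (at_end) x$start else x$end
      return(data.frame(chrom = x$chrom, pos = pos, cna_id = x$cna_id,
                        cna_class = x$cna_class, role = "interstitial",
                        stringsAsFactors = FALSE))
    }
    data.frame(chrom = rep(x$chrom, 2), pos = c(x$start, x$end),
               cna_id = x$cna_id, cna_class = x$cna_class,
               role = c("left", "right"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Distance from breakpoints to the nearest feature
#'
#' For each breakpoint, the distance to the nearest end of the nearest
#' feature interval (0 if the breakpoint lies inside a feature); per CNA,
#' the minimum over its breakpoints; and per CNA class, the proportion of
#' CNAs with a breakpoint within \code{cutoff} of a feature.
#'
#' @param breakpoints Breakpoint data.frame
#'   (\code{\link{extract_breakpoints}}) or control coordinates
#'   (chrom/pos).
#' @param features Interval data.frame (chrom/start/end).
#' @param cutoff Proximity cutoff in bp for the proportion summary
#'   (default 1 Mb).
#' @return List: \code{$breakpoints} (input plus \code{distance}, NA
#'   where the chromosome has no features), \code{$per_cna} (cna_id,
#'   cna_class, distance = min over breakpoints) when CNA ids are
#'   present, and \code{$proportion_within} (per class).
#' @export
distance_to_nearest <- function(breakpoints, features, cutoff = 1e6) {
  if (is.null(features) || nrow(features) == 0)
    stop("features must be non-empty")
  bp <- breakpoints
  if (nrow(bp) == 0)
    return(list(breakpoints = cbind(bp, distance = numeric(0)),
                per_cna = NULL, proportion_within = NULL))
  dist <- rep(NA_real_, nrow(bp))
  for (ch in unique(bp$chrom)) {
    bi <- which(bp$chrom == ch)
    fi <- which(features$chrom == ch)
    if (length(fi) == 0) next
    for (k in bi) {
      p <- bp$pos[k]
      inside <- any(features$start[fi] <= p & p < features$end[fi])
      dist[k] <- if (inside) 0 else
        min(pmin(abs(p - features$start[fi]), abs(p - features$end[fi])))
    }
  }
  bp$distance <- dist
  per_cna <- NULL
  prop <- NULL
  if ("cna_id" %in% names(bp)) {
    agg <- stats::aggregate(distance ~ cna_id + cna_class, data = bp,
                            FUN = function(d) suppressWarnings(min(d)),
                            na.action = stats::na.omit)
    per_cna <- agg[order(agg$cna_id), , drop = FALSE]
    rownames(per_cna) <- NULL
    prop <- do.call(rbind, lapply(split(per_cna, per_cna$cna_class),
      function(g) data.frame(cna_class = g$cna_class[1], n = nrow(g),
                             proportion_within = mean(g$distance <= cutoff),
                             stringsAsFactors = FALSE)))
    if (!is.null(prop)) rownames(prop) <- NULL
  }
  list(breakpoints = bp, per_cna = per_cna, proportion_within = prop)
}

#' Summed gene expression in a window around breakpoints
#'
#' Sums the per-gene mean expression of all genes overlapping a window
#' (default 2 Mb) centred on each breakpoint; genes overlapping the
#' window by at least 1 bp contribute their full mean expression.
#'
#' @param breakpoints Breakpoint or control data.frame (chrom/pos).
#' @param genes Gene data.frame with an expression column named by
#'   \code{cell_type}.
#' @param cell_type Name of the expression column to use.
#' @param genome A \code{genome_model} (for clipping at chromosome ends).
#' @param window Window width in bp (default 2 Mb).
#' @return Input data.frame with an added \code{window_expression}
#'   column (0 when no gene overlaps the window).
#' @export
window_expression <- function(breakpoints, genes, cell_type, genome,
                              window = 2e6) {
  if (!cell_type %in% names(genes))
    stop("no expression column '", cell_type, "' in genes")
  bp <- breakpoints
  if (nrow(bp) == 0) { bp$window_expression <- numeric(0); return(bp) }
  chroms <- genome$chromosomes
  len <- chroms$length[match(bp$chrom, chroms$chrom)]
  ws <- pmax(0, bp$pos - window / 2)
  we <- pmin(len, bp$pos + window / 2)
  expr <- numeric(nrow(bp))
  for (k in seq_len(nrow(bp))) {
    ov <- genes$chrom == bp$chrom[k] & genes$start < we[k] & genes$end > ws[k]
    expr[k] <- sum(genes[[cell_type]][ov])
  }
  bp$window_expression <- expr
  bp
}

#' Position of breakpoints relative to nearby large/giant genes
#'
#' For breakpoints of large terminal CNAs: if the breakpoint falls inside
#' a large or giant gene, its position is reported as the distance from
#' the gene's 5' end divided by gene length (0 = promoter end, 1 = 3'
#' end); breakpoints within \code{proximity} of a gene but outside it get
#' a signed offset in Mb (negative upstream of the 5' end, positive
#' downstream of the 3' end). Breakpoints with no gene within reach are
#' excluded.
#'
#' @param breakpoints Breakpoint data.frame (chrom/pos).
#' @param genes Gene data.frame with strand, restricted by the caller to
#'   large/giant genes if desired.
#' @param proximity Maximum distance to a gene in bp (default 1 Mb).
#' @return Data.frame: chrom, pos, gene, location ("inside" or
#'   "outside"), position (in [0,1] inside), offset_mb (signed, outside).
#' @export
breakpoint_position_in_gene <- function(breakpoints, genes, proximity = 1e6) {
  out <- list()
  for (k in seq_len(nrow(breakpoints))) {
    p <- breakpoints$pos[k]
    gi <- which(genes$chrom == breakpoints$chrom[k])
    if (length(gi) == 0) next
    gap <- pmax(genes$start[gi] - p, p - genes$end[gi], 0)
    j <- gi[which.min(gap)]
    if (min(gap) > proximity) next
    fwd <- genes$strand[j] == "+"
    if (genes$start[j] <= p && p < genes$end[j]) {
      from5 <- if (fwd) p - genes$start[j] else genes$end[j] - p
      out[[length(out) + 1L]] <- data.frame(
        chrom = breakpoints$chrom[k], pos = p, gene = genes$name[j],
        location = "inside", position = from5 / (genes$end[j] - genes$start[j]),
        offset_mb = NA_real_, stringsAsFactors = FALSE)
    } else {
      before5 <- if (fwd) p < genes$start[j] else p >= genes$end[j]
      d <- min(abs(p - genes$start[j]), abs(p - genes$end[j]))
      out[[length(out) + 1L]] <- data.frame(
        chrom = breakpoints$chrom[k], pos = p, gene = genes$name[j],
        location = "outside", position = NA_real_,
        offset_mb = (if (before5) -d else d) / 1e6,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), pos = numeric(), gene = character(),
                      location = character(), position = numeric(),
                      offset_mb = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Breakpoint enrichment in repeat-dense genome bins
#'
#' Ranks 1-Mb bins by secondary-structure repeat coverage (after
#' removing the first and last bin of every chromosome), splits them at
#' the \code{top_fraction} rank boundary, and tests, per CNA class,
#' whether breakpoints concentrate in the repeat-dense half with a
#' 1-degree-of-freedom chi-square goodness-of-fit test against the split
#' of bins. Classes with any expected group count below \code{min_group}
#' are dropped; p-values are Benjamini-Hochberg adjusted across the
#' tested classes.
#'
#' @param breakpoints Breakpoint data.frame with \code{cna_class}.
#' @param repeats Per-1-Mb-bin data.frame (chrom/start/end/coverage).
#' @param top_fraction Fraction of bins in the repeat-dense group
#'   (default 0.5).
#' @param min_group Minimum expected count per group (default 5).
#' @return Data.frame: cna_class, n (breakpoints in retained bins),
#'   n_top, prop_top, expected_top, chisq, p, p_adj, dropped.
#' @export
repeat_bin_enrichment <- function(breakpoints, repeats, top_fraction = 0.5,
                                  min_group = 5L) {
  reps <- do.call(rbind, lapply(split(repeats, repeats$chrom), function(r) {
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) > 2) r[-c(1, nrow(r)), , drop = FALSE] else r[0, , drop = FALSE]
  }))
  nb <- nrow(reps)
  if (nb == 0) stop("no bins left after removing chromosome-end bins")
  n_top <- floor(top_fraction * nb)
  top_idx <- rank(-reps$coverage, ties.method = "first") <= n_top
  classes <- unique(breakpoints$cna_class)
  rows <- lapply(classes, function(cl) {
    bp <- breakpoints[breakpoints$cna_class == cl, , drop = FALSE]
    in_top <- logical(nrow(bp)); in_bins <- logical(nrow(bp))
    for (k in seq_len(nrow(bp))) {
      hit <- which(reps$chrom == bp$chrom[k] & reps$start <= bp$pos[k] &
                     bp$pos[k] < reps$end)
      if (length(hit)) { in_bins[k] <- TRUE; in_top[k] <- top_idx[hit[1]] }
    }
    n <- sum(in_bins)
    if (n == 0) return(NULL)  # class skipped
    obs <- c(sum(in_top), n - sum(in_top))
    exp <- n * c(n_top, nb - n_top) / nb
    dropped <- any(exp < min_group)
    chisq <- sum((obs - exp)^2 / exp)
    data.frame(cna_class = cl, n = n, n_top = obs[1], prop_top = obs[1] / n,
               expected_top = exp[1], chisq = chisq,
               p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
               dropped = dropped, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(cna_class = character(), n = integer(), n_top = integer(),
                      prop_top = numeric(), expected_top = numeric(),
                      chisq = numeric(), p = numeric(), p_adj = numeric(),
                      dropped = logical(), stringsAsFactors = FALSE))
  out$p_adj <- NA_real_
  tested <- !out$dropped
  out$p_adj[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  rownames(out) <- NULL
  out
}

#' Dunn's post hoc test of each group against a control
#'
#' Rank-based pairwise z-tests on the pooled (tie-corrected) ranks of all
#' groups, comparing each non-control group with the control, with
#' multiplicity correction -- the post hoc companion to the
#' Kruskal-Wallis test.
#'
#' @param values Named list of numeric vectors (groups), including the
#'   control group.
#' @param control Name of the control group.
#' @param p_adjust Multiplicity correction (default "bonferroni", the
#'   classical Dunn correction).
#' @return Data.frame: group, n, median, z, p, p_adj, low_n flag.
#' @export
dunn_test <- function(values, control, p_adjust = "bonferroni") {
  stopifnot(control %in% names(values))
  groups <- names(values)
  x <- unlist(values, use.names = FALSE)
  g <- factor(rep(groups, lengths(values)), levels = groups)
  N <- length(x)
  r <- rank(x)
  tie_tab <- table(r)
  ties <- sum(tie_tab^3 - tie_tab)
  varc <- N * (N + 1) / 12 - ties / (12 * (N - 1))
  mean_rank <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  others <- setdiff(groups, control)
  z <- (mean_rank[others] - mean_rank[control]) /
    sqrt(varc * (1 / n[others] + 1 / n[control]))
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group = others, n = as.integer(n[others]),
             median = vapply(values[others], stats::median, 0),
             z = as.numeric(z), p = as.numeric(p),
             p_adj = stats::p.adjust(p, method = p_adjust),
             low_n = as.integer(n[others]) < 3,
             stringsAsFactors = FALSE)
}

#' Compare CNA-class value distributions against in-silico controls
#'
#' Kruskal-Wallis test across all groups (CNA classes plus control),
#' followed by Dunn's post hoc comparison of each class against the
#' control with multiplicity correction. Used for breakpoint-to-feature
#' distances, window expression and per-breakpoint replication timing.
#'
#' @param values Named list of numeric vectors, one per CNA class plus
#'   the control.
#' @param control Name of the control group (default "control").
#' @param p_adjust Dunn correction method (default "bonferroni").
#' @return List of class \code{association_result}: \code{$kw}
#'   (statistic, df, p), \code{$dunn} (per-class table), \code{$groups}.
#' @export
compare_groups <- function(values, control = "control",
                           p_adjust = "bonferroni") {
  values <- values[lengths(values) > 0]
  if (length(values) < 2) stop("need at least 2 non-empty groups")
  if (!control %in% names(values)) stop("control group '", control, "' missing")
  x <- unlist(values, use.names = FALSE)
  g <- factor(rep(names(values), lengths(values)), levels = names(values))
  kw <- stats::kruskal.test(x, g)
  structure(list(
    kw = data.frame(statistic = unname(kw$statistic),
                    df = unname(kw$parameter), p = kw$p.value),
    dunn = dunn_test(values, control, p_adjust),
    groups = data.frame(group = names(values), n = lengths(values),
                        median = vapply(values, stats::median, 0),
                        row.names = NULL, stringsAsFactors = FALSE)),
    class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared = %.3f, df = %d, p = %.3g\n",
              x$kw$statistic, x$kw$df, x$kw$p))
  cat("Dunn's post hoc vs control:\n")
  print(x$dunn, row.names = FALSE)
  invisible(x)
}
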