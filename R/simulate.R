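#' Construct a ground-truth CNA record
#'
#' Ground-truth CNAs drive the read-count simulator and are retrievable
#' per simulated cell for oracle tests. Clonal events are carried by every
#' cell of their condition(s); sub-clonal events by a configured fraction
#' of cells; de-novo events arise independently per cell at a per-cell
#' incidence rate.
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval in bp.
#' @param state Integer copy state (>= 0) of the event.
#' @param clonality One of \code{"clonal"}, \code{"subclonal"},
#'   \code{"de_novo"}.
#' @param condition Condition label(s) the event is assigned to; use
#'   \code{"*"} for all conditions.
#' @param cell_fraction For sub-clonal events, the fraction of cells
#'   carrying the event (default 0.3).
#' @param rate For de-novo events, per-cell incidence rate in [0, 1].
#' @return One-row data.frame; rows from repeated calls can be
#'   \code{rbind}-ed into a truth table.
#' @export
truth_cna <- function(chrom, start, end, state, clonality = "de_novo",
                      condition = "*", cell_fraction = 0.3, rate = 0.1) {
  stopifnot(end > start, state >= 0,
            clonality %in% c("clonal", "subclonal", "de_novo"))
  if (clonality == "de_novo" && (rate < 0 || rate > 1))
    stop("invalid config: de_novo incidence rate must be in [0,1]")
  data.frame(chrom = chrom, start = start, end = end, state = as.integer(state),
             clonality = clonality, condition = paste(condition, collapse = ","),
             cell_fraction = cell_fraction, rate = rate,
             stringsAsFactors = FALSE)
}

#' Draw random ground-truth CNAs on a genome
#'
#' Event intervals are drawn uniformly (chromosome chosen proportional to
#' length) and snapped to a bin grid so that caller-recovery oracles can
#' compare boundaries bin-for-bin.
#'
#' @param genome A \code{genome_model}.
#' @param n Number of events.
#' @param size_range Length-2 numeric, event size range in bp.
#' @param states Candidate copy states to sample from (baseline-2 cells:
#'   1 = loss, 3 = gain).
#' @param snap Bin width (bp) to snap interval boundaries to.
#' @param min_gap Minimum separation between drawn events in bp (default
#'   3 Mb): closer same-state events would merge into one segment under
#'   any segmentation, leaving the ground truth unidentifiable.
#' @param avoid Optional data.frame of intervals (chrom/start/end) that
#'   events must not overlap (e.g. padded centromeres).
#' @inheritParams truth_cna
#' @param seed Integer seed.
#' @return Truth-CNA data.frame (see \code{\link{truth_cna}}).
#' @export
random_truth_cnas <- function(genome, n, size_range = c(2e6, 3e7),
                              states = c(1L, 3L), snap = 5e5,
                              min_gap = 3e6, clonality = "de_novo",
                              condition = "*", cell_fraction = 0.3,
                              rate = 0.1, avoid = NULL, seed = 1L) {
  chroms <- genome$chromosomes
  set.seed(seed)
  out <- vector("list", n)
  k <- 0L
  guard <- 0L
  while (k < n && guard < 50L * n + 100L) {
    guard <- guard + 1L
    size <- round(stats::runif(1, size_range[1], size_range[2]) / snap) * snap
    size <- max(size, snap * ceiling(size_range[1] / snap))
    i <- sample(nrow(chroms), 1, prob = chroms$length)
    max_start <- chroms$length[i] - size
    if (max_start <= 0) next
    s <- floor(stats::runif(1, 0, max_start) / snap) * snap
    e <- min(s + size, chroms$length[i])
    if (!is.null(avoid)) {
      hit <- avoid$chrom == chroms$chrom[i] & avoid$start < e & avoid$end > s
      if (any(hit)) next
    }
    if (k > 0) {  # keep events on distinct regions to avoid stacked states
      prev <- do.call(rbind, out[seq_len(k)])
      if (any(prev$chrom == chroms$chrom[i] & prev$start < e + min_gap &
              prev$end > s - min_gap)) next
    }
    k <- k + 1L
    out[[k]] <- truth_cna(chroms$chrom[i], s, e, sample(states, 1),
                          clonality = clonality, condition = condition,
                          cell_fraction = cell_fraction, rate = rate)
  }
  if (k < n) warning("placed only ", k, " of ", n, " requested events")
  if (k == 0) return(NULL)
  do.call(rbind, out[seq_len(k)])
}

#' Multiplicative GC bias factor
#'
#' Unimodal bias of sequencing coverage as a function of bin GC fraction:
#' bins at the optimum GC are unaffected, AT- or GC-rich bins lose
#' coverage. \code{strength = 0} gives no bias.
#'
#' @param gc Numeric vector of GC fractions in [0, 1].
#' @param strength Non-negative bias strength.
#' @param optimum GC fraction of maximal coverage (default 0.45).
#' @param width Width of the bias curve (default 0.15).
#' @return Positive factors, 1 at the optimum.
#' @export
gc_bias_factor <- function(gc, strength = 0.3, optimum = 0.45, width = 0.15) {
  exp(-strength * ((gc - optimum) / width)^2)
}

.realize_events <- function(truth, condition) {
  if (is.null(truth) || nrow(truth) == 0) return(truth[0, ])
  cond_ok <- vapply(strsplit(truth$condition, ","), function(cs)
    "*" %in% cs || condition %in% cs, TRUE)
  keep <- logical(nrow(truth))
  for (j in seq_len(nrow(truth))) {
    if (!cond_ok[j]) next
    keep[j] <- switch(truth$clonality[j],
      clonal = TRUE,
      subclonal = stats::runif(1) < truth$cell_fraction[j],
      de_novo = stats::runif(1) < truth$rate[j])
  }
  truth[keep, , drop = FALSE]
}

.copy_state_per_bin <- function(bins, events, baseline) {
  state <- rep(as.integer(baseline), nrow(bins))
  if (is.null(events) || nrow(events) == 0) return(state)
  for (j in seq_len(nrow(events))) {
    ov <- bins$chrom == events$chrom[j] &
      (pmin(bins$end, events$end[j]) - pmax(bins$start, events$start[j])) >
        (bins$end - bins$start) / 2
    state[ov] <- events$state[j]
  }
  state
}

.draw_counts <- function(lambda, dispersion) {
  n <- length(lambda)
  if (dispersion <= 0) return(stats::rpois(n, lambda))
  stats::rnbinom(n, mu = lambda, size = 1 / dispersion)
}

#' Simulate G1-sorted single-cell binned read counts
#'
#' Draws per-bin read counts for G1 cells on a diploid baseline carrying
#' injected clonal, sub-clonal and de-novo CNAs. The expected count of a
#' bin is proportional to copy state x bin width x GC bias; counts are
#' negative-binomial around that expectation. Each cell records its
#' realized CNA set as retrievable ground truth.
#'
#' @param genome A \code{genome_model}.
#' @param truth Truth-CNA data.frame (\code{\link{truth_cna}}), or NULL.
#' @param n_cells Named integer vector: cells per condition, e.g.
#'   \code{c(control = 50, treated = 50)}.
#' @param reads_per_cell Expected total reads per cell.
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param gc_bias_strength Strength of the multiplicative GC bias
#'   (\code{\link{gc_bias_factor}}).
#' @param binsizes Bin-grid labels to emit counts on; each cell yields one
#'   profile per requested resolution, sharing the realized CNA set.
#' @param baseline Baseline ploidy (default 2).
#' @param seed Integer seed.
#' @return List of \code{cell_profile} objects: each has \code{$cell},
#'   \code{$condition}, \code{$fraction} ("G1"), \code{$binsize},
#'   \code{$counts}, \code{$total} and \code{$truth$cnas} (realized
#'   events).
#' @export
simulate_g1_cells <- function(genome, truth = NULL, n_cells = c(control = 10),
                              reads_per_cell = 1e5, dispersion = 0.01,
                              gc_bias_strength = 0.3, binsizes = "500kb",
                              baseline = 2L, seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  if (reads_per_cell <= 0) stop("invalid config: reads_per_cell must be > 0")
  if (!is.null(truth)) {
    bad <- !truth$chrom %in% genome$chromosomes$chrom |
      truth$end > genome$chromosomes$length[match(truth$chrom, genome$chromosomes$chrom)]
    if (any(bad)) stop("invalid config: truth intervals outside genome")
    dn <- truth$clonality == "de_novo"
    if (any(truth$rate[dn] < 0 | truth$rate[dn] > 1))
      stop("invalid config: de_novo incidence rate must be in [0,1]")
  }
  if (is.null(names(n_cells))) names(n_cells) <- paste0("cond", seq_along(n_cells))
  grids <- lapply(binsizes, function(b) bin_grid(genome, b))
  names(grids) <- binsizes

  set.seed(seed)
  profiles <- list()
  for (cond in names(n_cells)) {
    for (ci in seq_len(n_cells[[cond]])) {
      id <- sprintf("%s_G1_%03d", cond, ci)
      events <- .realize_events(truth, cond)
      for (b in binsizes) {
        bins <- grids[[b]]
        state <- .copy_state_per_bin(bins, events, baseline)
        lam <- state * (bins$end - bins$start) *
          gc_bias_factor(bins$gc, gc_bias_strength)
        tot <- sum(lam)
        lam <- if (tot > 0) lam / tot * reads_per_cell else lam
        counts <- .draw_counts(lam, dispersion)
        profiles[[length(profiles) + 1L]] <- structure(
          list(cell = id, condition = cond, fraction = "G1", binsize = b,
               counts = as.integer(counts), total = sum(counts),
               truth = list(cnas = events, state = state, replicated = NULL)),
          class = "cell_profile")
      }
    }
  }
  profiles
}

#' Smooth ground-truth replication-timing profile
#'
#' One value per 1-Mb bin in [0, 1], 1 = earliest-replicating. Built from
#' the same smooth-spline construction as the GC track so neighbouring
#' bins have correlated timing, as in real replication-timing profiles.
#'
#' @param genome A \code{genome_model} (must carry a "1Mb" grid).
#' @param seed Integer seed.
#' @return Numeric vector, one value per 1-Mb bin.
#' @export
make_truth_rt <- function(genome, seed = 1L) {
  bins <- bin_grid(genome, "1Mb")
  set.seed(seed)
  out <- numeric(nrow(bins))
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    mids <- (bins$start[idx] + bins$end[idx]) / 2
    knots <- seq(min(mids) - 1e6, max(mids) + 1e6, by = 4e6)
    f <- stats::splinefun(knots, stats::rnorm(length(knots)), method = "natural")
    out[idx] <- stats::pnorm(f(mids) / 1.2)
  }
  out
}

#' Simulate S-phase-fraction single cells with partially replicated genomes
#'
#' Emulates FACS-sorted S-phase populations: for each cell a replication
#' progression threshold is drawn near its fraction's expected replicated
#' genome proportion p; 1-Mb bins whose ground-truth timing (plus per-bin
#' noise) exceeds the threshold are replicated and their expected read
#' counts doubled. Each cell records its replicated bin set as ground
#' truth.
#'
#' @param genome A \code{genome_model}.
#' @param truth_rt Per-1-Mb-bin timing in [0, 1] (1 = earliest), e.g. from
#'   \code{\link{make_truth_rt}}.
#' @param fractions Data.frame with columns \code{label} and \code{p}
#'   (expected replicated fraction, increasing, each in (0, 1)); default
#'   the four S-phase gates at p = 0.125, 0.375, 0.635, 0.875.
#' @param n_cells Cells per fraction (scalar or vector matching
#'   \code{fractions}).
#' @param reads_per_cell Expected total reads per cell.
#' @param dispersion Negative-binomial dispersion.
#' @param noise SD of the per-bin timing jitter.
#' @param p_jitter SD of the per-cell progression jitter around p.
#' @param gc_bias_strength GC bias strength (default 0: the 1-Mb timing
#'   analysis corrects mappability via G1 cells, not GC).
#' @param condition Condition label for the simulated cells.
#' @param seed Integer seed.
#' @return List of \code{cell_profile} objects on the 1-Mb grid with
#'   \code{$fraction} set to the fraction label and
#'   \code{$truth$replicated} the logical replicated-bin vector.
#' @export
simulate_sphase_cells <- function(genome, truth_rt,
                                  fractions = data.frame(
                                    label = c("S1", "S2", "S3", "S4"),
                                    p = c(0.125, 0.375, 0.635, 0.875)),
                                  n_cells = 20, reads_per_cell = 1e5,
                                  dispersion = 0.01, noise = 0.05,
                                  p_jitter = 0.02, gc_bias_strength = 0,
                                  condition = "control", seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  if (is.null(fractions) || nrow(fractions) == 0)
    stop("invalid config: empty fraction list")
  if (any(fractions$p <= 0 | fractions$p >= 1))
    stop("invalid config: each expected fraction p must be in (0,1)")
  if (is.unsorted(fractions$p, strictly = TRUE))
    stop("invalid config: fractions must be ordered by increasing p")
  bins <- bin_grid(genome, "1Mb")
  if (length(truth_rt) != nrow(bins))
    stop("truth_rt length must equal the number of 1-Mb bins")
  if (length(n_cells) == 1) n_cells <- rep(n_cells, nrow(fractions))

  set.seed(seed)
  width <- bins$end - bins$start
  gcb <- gc_bias_factor(bins$gc, gc_bias_strength)
  profiles <- list()
  for (fi in seq_len(nrow(fractions))) {
    for (ci in seq_len(n_cells[fi])) {
      id <- sprintf("%s_%s_%03d", condition, fractions$label[fi], ci)
      pc <- min(max(fractions$p[fi] + stats::rnorm(1, 0, p_jitter), 0.02), 0.98)
      v <- truth_rt + stats::rnorm(length(truth_rt), 0, noise)
      tau <- stats::quantile(v, 1 - pc, names = FALSE)
      repl <- v > tau
      lam <- (1 + repl) * width * gcb
      lam <- lam / sum(lam) * reads_per_cell
      counts <- .draw_counts(lam, dispersion)
      profiles[[length(profiles) + 1L]] <- structure(
        list(cell = id, condition = condition, fraction = fractions$label[fi],
             binsize = "1Mb", counts = as.integer(counts), total = sum(counts),
             truth = list(cnas = NULL, replicated = repl)),
        class = "cell_profile")
    }
  }
  profiles
}

#' @export
print.cell_profile <- function(x, ...) {
  cat(sprintf("cell_profile %s [%s, %s] %s: %d bins, %d reads\n",
              x$cell, x$condition, x$fraction, x$binsize,
              length(x$counts), x$total))
  invisible(x)
}

#' Retrieve a simulated cell's ground truth
#'
#' @param profile A \code{cell_profile} from the simulator.
#' @return List with \code{$cnas} (realized CNA events, G1 cells) and
#'   \code{$replicated} (logical replicated-bin vector, S-phase cells).
#' @export
cell_truth <- function(profile) {
  stopifnot(inherits(profile, "cell_profile"))
  profile$truth
}
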