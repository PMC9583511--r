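#' GC-correct a binned read-count profile
#'
#' Divides each bin's count by the median count of bins in the same
#' GC-content decile, then rescales so the genome-wide mean count is
#' preserved. Bins falling in a decile whose median count is zero cannot
#' be corrected and are flagged missing (NA).
#'
#' The decile medians are estimated in two passes: a first pass corrects
#' with the plain per-decile medians, a preliminary relative copy number
#' (half-integer multiples of the modal corrected coverage) is read off
#' that pass, and the medians are then re-estimated from counts descaled
#' by it. This keeps the correction from absorbing genuine copy-number
#' signal when a sizeable share of a cell's genome is off-baseline (e.g.
#' a large gain concentrated in one GC decile).
#'
#' @param profile A \code{cell_profile}.
#' @param genome A \code{genome_model} sharing the profile's bin grid.
#' @return Numeric vector of corrected per-bin values (NA = missing).
#' @export
gc_correct <- function(profile, genome) {
  stopifnot(inherits(profile, "cell_profile"))
  bins <- bin_grid(genome, profile$binsize)
  counts <- profile$counts
  if (length(counts) != nrow(bins))
    stop("shape error: profile and genome bin grids differ in length")
  breaks <- unique(stats::quantile(bins$gc, probs = seq(0, 1, 0.1), names = FALSE))
  if (length(breaks) < 2) {
    decile <- rep(1L, length(counts))
  } else {
    decile <- cut(bins$gc, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  }
  correct_with <- function(base) {
    med <- tapply(base, decile, stats::median, na.rm = TRUE)
    m <- as.numeric(med[as.character(decile)])
    corrected <- ifelse(!is.na(m) & m > 0, counts / m, NA_real_)
    use <- !is.na(corrected)
    if (any(use)) {
      scale <- mean(counts[use]) / mean(corrected[use])
      corrected[use] <- corrected[use] * scale
    }
    corrected
  }
  pass1 <- correct_with(counts)
  v <- pass1[!is.na(pass1)]
  if (length(v) < 10) return(pass1)
  dens <- stats::density(v, n = 512)
  modal <- dens$x[which.max(dens$y)]
  if (modal <= 0) return(pass1)
  rel_copy <- round(2 * pass1 / modal) / 2
  base2 <- ifelse(!is.na(rel_copy) & rel_copy > 0, counts / rel_copy, NA_real_)
  correct_with(base2)
}

#' Per-cell spikiness of a binned count profile
#'
#' Mean absolute difference of consecutive bin counts after normalizing
#' by the mean count; high values indicate noisy, low-quality libraries.
#'
#' @param counts Non-negative integer vector of per-bin counts.
#' @return Non-negative scalar (NA if the profile has no reads).
#' @export
spikiness <- function(counts) {
  m <- mean(counts)
  if (!is.finite(m) || m <= 0) return(NA_real_)
  mean(abs(diff(counts / m)))
}

#' Quality-filter single-cell profiles
#'
#' Keeps cells with at least \code{min_reads} total reads and spikiness at
#' most \code{max_spikiness}; the report covers every input cell with the
#' reason(s) for failure.
#'
#' @param profiles List of \code{cell_profile}.
#' @param min_reads Minimum total read count (default 10000).
#' @param max_spikiness Maximum spikiness (default 0.35).
#' @return List with \code{$kept} (passing profiles) and \code{$report}
#'   (data.frame: cell, binsize, total_reads, spikiness, pass, reason).
#' @export
qc_filter <- function(profiles, min_reads = 1e4, max_spikiness = 0.35) {
  if (min_reads <= 0 || max_spikiness <= 0)
    stop("invalid config: QC thresholds must be positive")
  if (length(profiles) == 0)
    return(list(kept = list(),
                report = data.frame(cell = character(), binsize = character(),
                                    total_reads = numeric(), spikiness = numeric(),
                                    pass = logical(), reason = character(),
                                    stringsAsFactors = FALSE)))
  rows <- lapply(profiles, function(p) {
    sp <- spikiness(p$counts)
    reasons <- character()
    if (p$total < min_reads) reasons <- c(reasons, "low_reads")
    if (is.na(sp) || sp > max_spikiness) reasons <- c(reasons, "high_spikiness")
    data.frame(cell = p$cell, binsize = p$binsize, total_reads = p$total,
               spikiness = sp, pass = length(reasons) == 0,
               reason = paste(reasons, collapse = ","),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  list(kept = profiles[report$pass], report = report)
}

.viterbi <- function(loge, log_self, log_switch, log_init) {
  n <- nrow(loge); K <- ncol(loge)
  back <- matrix(0L, n, K)
  delta <- log_init + loge[1, ]
  if (n > 1) {
    for (t in 2:n) {
      stay <- delta + log_self
      # for state k: best predecessor is either k itself (stay) or the best
      # other state (top-2 trick avoids the full K x K max)
      m1 <- max(delta); w1 <- which.max(delta)
      d2 <- delta; d2[w1] <- -Inf
      m2 <- max(d2); w2 <- if (is.finite(m2)) which.max(d2) else w1
      new_delta <- numeric(K)
      for (k in seq_len(K)) {
        off_m <- if (k == w1) m2 else m1
        off_w <- if (k == w1) w2 else w1
        if (stay[k] >= off_m + log_switch) {
          new_delta[k] <- stay[k]; back[t, k] <- k
        } else {
          new_delta[k] <- off_m + log_switch; back[t, k] <- off_w
        }
      }
      delta <- new_delta + loge[t, ]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1) for (t in (n - 1):1) path[t] <- back[t + 1, path[t + 1]]
  path
}

#' Call integer copy-number segments from corrected bin values
#'
#' Hidden-Markov-model segmentation: hidden states are integer copy
#' numbers 0..\code{max_state} with Gaussian emissions whose means are
#' proportional to the state (state 0 at a small floor) and whose shared
#' scale is estimated robustly from the data; the most likely state path
#' is decoded by global maximum-likelihood (Viterbi) decoding per
#' chromosome. Runs of non-baseline state are merged into segments;
#' missing bins inside a run are bridged. Calling is invariant to scaling
#' all values by a constant.
#'
#' @param values Corrected per-bin values (NA = missing), aligned to the
#'   \code{binsize} grid of \code{genome}.
#' @param genome A \code{genome_model}.
#' @param binsize Bin-grid label of \code{values} ("40kb" or "500kb").
#' @param cell Cell identifier recorded in the output.
#' @param baseline Baseline ploidy (default 2); segments at baseline are
#'   not emitted as CNAs.
#' @param baseline_by_chrom Optional named vector overriding the baseline
#'   per chromosome (e.g. a trisomic chromosome at 3).
#' @param max_state Largest copy state modelled (default 8).
#' @param switch_prob Per-bin probability of leaving the current state;
#'   default 4e-4 at 40 kb, scaled linearly with bin size. Small values
#'   favour long segments, matching the >= Mb scale of replication-stress
#'   CNAs.
#' @param min_bins Minimum segment length in bins (default 2; single-bin
#'   events are indistinguishable from noise at low coverage).
#' @return Data.frame of CNA segments (cell, chrom, start, end, state,
#'   ploidy, resolution, n_bins), with the decoded per-bin state vector
#'   attached as attribute \code{"states"} (NA at unusable bins).
#' @export
call_segments <- function(values, genome, binsize, cell = "cell",
                          baseline = 2L, baseline_by_chrom = NULL,
                          max_state = 8L, switch_prob = NULL,
                          min_bins = 2L) {
  bins <- bin_grid(genome, binsize)
  if (length(values) != nrow(bins))
    stop("shape error: values and bin grid differ in length")
  if (any(values < 0, na.rm = TRUE)) stop("corrected values must be non-negative")
  if (max_state < baseline + 1) stop("max_state must be >= baseline + 1")
  bs <- genome$bin_sizes[[binsize]]
  if (is.null(switch_prob)) switch_prob <- min(0.2, 4e-4 * bs / 4e4)

  usable_all <- !is.na(values)
  v_all <- values[usable_all]
  if (length(v_all) < 10) stop("fewer than 10 usable bins in total")
  # per-copy emission scale anchored on the modal coverage cluster: the
  # most common copy state is taken to be the baseline ploidy (relative
  # depth alone cannot distinguish, say, a fully triploid cell from a
  # diploid one). Scale-equivariant, so calling is depth-invariant.
  dens <- stats::density(v_all, n = 512)
  anchor <- dens$x[which.max(dens$y)]
  if (anchor <= 0) anchor <- stats::median(v_all[v_all > 0])
  mu1 <- anchor / baseline
  sdiffs <- unlist(lapply(split(values, bins$chrom), function(v) {
    v <- v[!is.na(v)]; if (length(v) > 1) abs(diff(v)) else numeric()
  }))
  sigma <- 1.4826 * stats::median(sdiffs) / sqrt(2)
  if (!is.finite(sigma) || sigma <= 0) sigma <- 0.05 * mu1
  sigma <- max(sigma, 1e-8 * max(mu1, 1))

  K <- max_state + 1L
  state_means <- c(0.05 * mu1, seq_len(max_state) * mu1)
  # emission scale grows with the state, as count noise does: variance
  # m + phi m^2 (negative-binomial form), with phi calibrated so the
  # baseline state reproduces the robustly estimated sigma
  m_b <- baseline * mu1
  phi <- max(0, (sigma^2 - m_b) / m_b^2)
  state_sds <- sqrt(pmax(state_means + phi * state_means^2, (0.05 * sigma)^2))
  if (phi == 0) state_sds <- sigma * sqrt(pmax(state_means, 0.05 * mu1) / m_b)
  log_self <- log1p(-switch_prob)
  log_switch <- log(switch_prob / (K - 1))
  log_init <- rep(log(0.1 / (K - 1)), K)
  log_init[baseline + 1L] <- log(0.9)

  states <- rep(NA_integer_, nrow(bins))
  segs <- list()
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    use <- idx[!is.na(values[idx])]
    if (length(use) < 10) {
      warning("chromosome ", ch, " skipped: fewer than 10 usable bins")
      next
    }
    bl <- as.integer(baseline_by_chrom[ch] %||% baseline)
    v <- values[use]
    loge <- vapply(seq_len(K), function(k)
      stats::dnorm(v, state_means[k], state_sds[k], log = TRUE),
      numeric(length(v)))
    li <- log_init
    if (bl != baseline) {
      li <- rep(log(0.1 / (K - 1)), K); li[bl + 1L] <- log(0.9)
    }
    path <- .viterbi(loge, log_self, log_switch, li) - 1L
    states[use] <- path
    r <- rle(path)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (r$values[j] == bl || r$lengths[j] < min_bins) next
      first <- use[starts[j]]; last <- use[stops[j]]
      segs[[length(segs) + 1L]] <- data.frame(
        cell = cell, chrom = ch, start = bins$start[first], end = bins$end[last],
        state = r$values[j], ploidy = bl, resolution = binsize,
        n_bins = r$lengths[j], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(cell = character(), chrom = character(), start = numeric(),
               end = numeric(), state = integer(), ploidy = integer(),
               resolution = character(), n_bins = integer(),
               stringsAsFactors = FALSE)
  attr(out, "states") <- states
  out
}

#' GC-correct and segment a set of cells
#'
#' Convenience wrapper running \code{\link{gc_correct}} and
#' \code{\link{call_segments}} over a list of profiles at one resolution.
#'
#' @param profiles List of \code{cell_profile} at a single bin size.
#' @param genome A \code{genome_model}.
#' @param ... Passed to \code{\link{call_segments}}.
#' @return Combined segment data.frame across cells; the per-cell decoded
#'   state vectors are attached as attribute \code{"states"} (a named
#'   list).
#' @export
call_cells <- function(profiles, genome, ...) {
  if (length(profiles) == 0)
    return(call_segments(numeric(0), genome, "500kb")[0, ])
  binsize <- unique(vapply(profiles, `[[`, "", "binsize"))
  if (length(binsize) != 1)
    stop("all profiles must share one bin size; found: ",
         paste(binsize, collapse = ", "))
  per_cell <- lapply(profiles, function(p) {
    call_segments(gc_correct(p, genome), genome, binsize, cell = p$cell, ...)
  })
  out <- do.call(rbind, per_cell)
  rownames(out) <- NULL
  st <- lapply(per_cell, attr, "states")
  names(st) <- vapply(profiles, `[[`, "", "cell")
  attr(out, "states") <- st
  out
}
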