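#' Per-cell bin read proportions with low-coverage exclusion
#'
#' Converts a 1-Mb binned count profile into per-bin read proportions and
#' masks bins whose proportion falls below the per-cell 0.1 quantile
#' (poorly mappable or deleted bins). With \code{sex_stratified}, the
#' quantile is computed separately for autosomes and the X chromosome, as
#' appropriate for male samples where X bins sit at half the autosomal
#' coverage.
#'
#' @param profile A \code{cell_profile} on the 1-Mb grid.
#' @param genome A \code{genome_model}.
#' @param low_quantile Exclusion quantile (default 0.1).
#' @param sex_stratified Compute quantiles separately for autosomes and
#'   X (default FALSE; the all-autosome default simulation needs none).
#' @param sex_chroms Chromosome names treated as X when stratifying.
#' @return List with \code{$prop} (per-bin proportions) and
#'   \code{$usable} (logical mask).
#' @export
normalize_cell_bins <- function(profile, genome, low_quantile = 0.1,
                                sex_stratified = FALSE,
                                sex_chroms = c("chrX", "X")) {
  stopifnot(inherits(profile, "cell_profile"))
  bins <- bin_grid(genome, profile$binsize)
  if (length(profile$counts) != nrow(bins))
    stop("shape error: profile and genome bin grids differ in length")
  if (profile$total <= 0) stop("cell rejected: zero total reads")
  prop <- profile$counts / profile$total
  usable <- logical(length(prop))
  groups <- if (sex_stratified) bins$chrom %in% sex_chroms else
    rep(FALSE, nrow(bins))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    q <- stats::quantile(prop[idx], low_quantile, names = FALSE)
    usable[idx] <- prop[idx] >= q
  }
  list(prop = prop, usable = usable)
}

#' G1-derived per-bin correction factors
#'
#' Median-centering correction for variable mappability, with G1 cells as
#' the reference: each bin's factor is the average read proportion over
#' all usable bins divided by that bin's mean G1 proportion. Applying the
#' factors to the G1 reference itself yields a flat profile.
#'
#' @param g1_norm List of \code{\link{normalize_cell_bins}} outputs for
#'   the G1 cells (at least one).
#' @return List with \code{$factor} (per-bin multiplicative factor, NA
#'   where undefined) and \code{$usable} (bins with a defined factor).
#' @export
g1_correction_factors <- function(g1_norm) {
  if (length(g1_norm) == 0) stop("at least one G1 cell is required")
  prop <- vapply(g1_norm, `[[`, numeric(length(g1_norm[[1]]$prop)), "prop")
  usab <- vapply(g1_norm, `[[`, logical(length(g1_norm[[1]]$usable)), "usable")
  prop <- matrix(prop, ncol = length(g1_norm))
  usab <- matrix(usab, ncol = length(g1_norm))
  prop[!usab] <- NA
  bin_mean <- rowMeans(prop, na.rm = TRUE)
  bin_mean[is.nan(bin_mean)] <- NA
  usable <- !is.na(bin_mean) & bin_mean > 0
  avg <- mean(bin_mean[usable])
  factor <- ifelse(usable, avg / bin_mean, NA_real_)
  list(factor = factor, usable = usable)
}

#' Binarize a cell's replication state per bin
#'
#' Multiplies the cell's bin proportions by the G1 correction factors and
#' designates as "replicated" the bins above the (1 - p) empirical
#' quantile of the corrected proportions, so that a fraction p of the
#' cell's usable genome is called replicated -- p being the fraction of
#' the genome expected to be replicated in that cell's S-phase gate.
#' Bins tied at the cutoff are admitted in index order until exactly
#' \code{floor(p * n_usable)} bins are called, which keeps every cell's
#' replicated fraction within one bin of p even when integer counts
#' produce ties; when all values are tied the whole set is chosen this
#' way (with a warning).
#'
#' @param norm Output of \code{\link{normalize_cell_bins}} for the cell.
#' @param factors Output of \code{\link{g1_correction_factors}}.
#' @param p Expected replicated fraction in (0, 1) for the cell's
#'   S-phase gate (0.125, 0.375, 0.635 or 0.875 for the four gates).
#' @return List with \code{$replicated} (logical per bin, FALSE at
#'   unusable bins), \code{$usable}, and \code{$corrected}.
#' @export
binarize_replication <- function(norm, factors, p) {
  if (p <= 0 || p >= 1) stop("invalid config: p must be in (0,1)")
  corrected <- norm$prop * factors$factor
  usable <- norm$usable & factors$usable & !is.na(corrected)
  v <- corrected[usable]
  n <- length(v)
  if (n == 0) stop("no usable bins")
  k <- floor(p * n)
  if (length(unique(v)) == 1)
    warning("all corrected proportions equal; replicated set chosen by index order")
  r <- rank(-v, ties.method = "first")
  repl_usable <- r <= k
  replicated <- logical(length(corrected))
  replicated[usable] <- repl_usable
  list(replicated = replicated, usable = usable, corrected = corrected)
}

#' Replication timing factor (RTF) across S-phase fractions
#'
#' For every 1-Mb bin and S-phase fraction, the proportion of that
#' fraction's cells calling the bin replicated is computed; the RTF is
#' the sum of the four per-fraction proportions, ranging 0 (never
#' replicated, latest) to 4 (replicated in every cell of every fraction,
#' earliest). The observed RTF range is split into four equal intervals
#' to give quartile categories late, mid-late, mid-early, early.
#'
#' @param calls Named list (one element per fraction, in increasing-p
#'   order) of lists of \code{\link{binarize_replication}} outputs, one
#'   per cell.
#' @param genome A \code{genome_model}.
#' @return Data.frame of class \code{rt_profile}: chrom, start, end,
#'   usable, one \code{prop_<fraction>} column per fraction, rtf,
#'   quartile.
#' @export
replication_timing_factor <- function(calls, genome) {
  if (length(calls) != 4)
    stop("four S-phase fractions are required; got ", length(calls))
  if (is.null(names(calls))) names(calls) <- paste0("S", seq_along(calls))
  for (f in names(calls))
    if (length(calls[[f]]) == 0) stop("fraction ", f, " has zero cells")
  bins <- bin_grid(genome, "1Mb")
  nb <- nrow(bins)
  props <- matrix(NA_real_, nb, length(calls),
                  dimnames = list(NULL, names(calls)))
  usable_all <- rep(TRUE, nb)
  for (f in seq_along(calls)) {
    repl <- vapply(calls[[f]], function(x) as.numeric(x$replicated), numeric(nb))
    usab <- vapply(calls[[f]], function(x) x$usable, logical(nb))
    repl <- matrix(repl, ncol = length(calls[[f]]))
    usab <- matrix(usab, ncol = length(calls[[f]]))
    repl[!usab] <- NA
    n_use <- rowSums(usab)
    props[, f] <- ifelse(n_use > 0, rowSums(repl, na.rm = TRUE) / n_use, NA)
    usable_all <- usable_all & n_use > 0
  }
  rtf <- rowSums(props)
  rtf[!usable_all] <- NA
  out <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                    usable = usable_all, stringsAsFactors = FALSE)
  for (f in names(calls)) out[[paste0("prop_", f)]] <- props[, f]
  out$rtf <- rtf
  rng <- range(rtf[usable_all])
  cats <- c("late", "mid-late", "mid-early", "early")
  if (diff(rng) == 0) {
    out$quartile <- ifelse(usable_all, "late", NA_character_)
  } else {
    brk <- seq(rng[1], rng[2], length.out = 5)
    idx <- pmin(findInterval(rtf, brk, rightmost.closed = TRUE), 4L)
    out$quartile <- ifelse(usable_all, cats[idx], NA_character_)
  }
  class(out) <- c("rt_profile", class(out))
  out
}

#' Full replication-timing profile from simulated or real cells
#'
#' Convenience wrapper: normalizes G1 and S-phase cells, derives G1
#' correction factors, binarizes each S-phase cell at its gate's expected
#' replicated fraction, and computes the RTF profile.
#'
#' @param sphase List of \code{cell_profile} on the 1-Mb grid with
#'   fraction labels matching \code{fractions$label}.
#' @param g1 List of G1 \code{cell_profile} on the 1-Mb grid.
#' @param genome A \code{genome_model}.
#' @param fractions Data.frame(label, p) in increasing-p order; default
#'   the four gates at 0.125, 0.375, 0.635, 0.875.
#' @param low_quantile,sex_stratified Passed to
#'   \code{\link{normalize_cell_bins}}.
#' @return An \code{rt_profile} (see
#'   \code{\link{replication_timing_factor}}), with the per-cell
#'   binarizations attached as attribute \code{"calls"}.
#' @export
compute_rt_profile <- function(sphase, g1, genome,
                               fractions = data.frame(
                                 label = c("S1", "S2", "S3", "S4"),
                                 p = c(0.125, 0.375, 0.635, 0.875)),
                               low_quantile = 0.1, sex_stratified = FALSE) {
  g1_norm <- lapply(g1, normalize_cell_bins, genome = genome,
                    low_quantile = low_quantile,
                    sex_stratified = sex_stratified)
  factors <- g1_correction_factors(g1_norm)
  calls <- lapply(seq_len(nrow(fractions)), function(fi) {
    cells <- Filter(function(p) p$fraction == fractions$label[fi], sphase)
    if (length(cells) == 0)
      stop("fraction ", fractions$label[fi], " has zero cells")
    lapply(cells, function(p) {
      binarize_replication(
        normalize_cell_bins(p, genome, low_quantile, sex_stratified),
        factors, fractions$p[fi])
    })
  })
  names(calls) <- fractions$label
  out <- replication_timing_factor(calls, genome)
  attr(out, "calls") <- calls
  out
}

#' Replication-timing shift (delta RT) between conditions
#'
#' Per-bin difference of treated minus control RTF on mutually usable
#' bins; bins in the extreme tails of the empirical delta-RT
#' distribution (\code{extreme_total}/2 at each end) are flagged as
#' shifted to much later ("later") or much earlier ("earlier")
#' replication under treatment. A constant delta-RT yields no flags.
#'
#' @param rtf_treated,rtf_control \code{rt_profile}s on the same grid.
#' @param extreme_total Total flagged fraction in (0, 1); default 0.05,
#'   i.e. 2.5\% per tail.
#' @return Data.frame: chrom, start, end, usable, delta_rt, extreme
#'   (\code{"later"}, \code{"earlier"} or \code{"none"}).
#' @export
delta_rt <- function(rtf_treated, rtf_control, extreme_total = 0.05) {
  if (nrow(rtf_treated) != nrow(rtf_control) ||
      any(rtf_treated$start != rtf_control$start) ||
      any(rtf_treated$chrom != rtf_control$chrom))
    stop("shape error: RT profiles are on different grids")
  if (extreme_total <= 0 || extreme_total >= 1)
    stop("extreme_total must be in (0,1)")
  usable <- rtf_treated$usable & rtf_control$usable
  d <- ifelse(usable, rtf_treated$rtf - rtf_control$rtf, NA_real_)
  out <- data.frame(chrom = rtf_treated$chrom, start = rtf_treated$start,
                    end = rtf_treated$end, usable = usable, delta_rt = d,
                    extreme = ifelse(usable, "none", NA_character_),
                    stringsAsFactors = FALSE)
  v <- d[usable]
  if (length(v) > 0 && diff(range(v)) > 0) {
    a <- extreme_total / 2
    qlo <- stats::quantile(v, a, type = 1, names = FALSE)
    qhi <- stats::quantile(v, 1 - a, type = 1, names = FALSE)
    out$extreme[usable & d < qlo] <- "later"
    out$extreme[usable & d > qhi] <- "earlier"
  }
  out
}
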