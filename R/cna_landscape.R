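#' Classify CNAs by size, direction and terminality
#'
#' Adds the analysis classes to masked CNA segments: size class small
#' (< 20 Mb) or large (>= 20 Mb), direction gain/loss by the sign of
#' (state - baseline ploidy), and a terminal flag set when one boundary
#' lies within \code{terminal_tolerance} of a chromosome end (large
#' terminal CNAs extend from a single interstitial breakpoint to the
#' chromosome end).
#'
#' @param segments Segment data.frame (cell, chrom, start, end, state,
#'   ploidy, ...).
#' @param genome A \code{genome_model}.
#' @param size_threshold Size boundary in bp (default 20 Mb; exactly
#'   20 Mb is large).
#' @param terminal_tolerance Distance from a chromosome end still counted
#'   as terminal, in bp (default one 500-kb bin).
#' @return Input data.frame with added columns \code{size_mb},
#'   \code{size_class}, \code{direction}, \code{terminal} and
#'   \code{cna_class} (e.g. "small_loss"), plus a \code{cna_id}.
#' @export
classify_cna <- function(segments, genome, size_threshold = 2e7,
                         terminal_tolerance = 5e5) {
  chroms <- genome$chromosomes
  out <- segments
  if (is.null(out) || nrow(out) == 0) {
    for (col in c("cna_id", "size_mb", "size_class", "direction",
                  "terminal", "cna_class"))
      out[[col]] <- vector(if (col %in% c("size_mb")) "numeric" else
        if (col == "terminal") "logical" else "character", 0)
    return(out)
  }
  m <- match(out$chrom, chroms$chrom)
  if (anyNA(m) || any(out$start < 0) || any(out$end > chroms$length[m]))
    stop("invalid input: segment outside genome")
  if (any(out$state == out$ploidy))
    stop("invalid input: segment at baseline ploidy is not a CNA")
  size <- out$end - out$start
  out$cna_id <- sprintf("cna_%04d", seq_len(nrow(out)))
  out$size_mb <- size / 1e6
  out$size_class <- ifelse(size >= size_threshold, "large", "small")
  out$direction <- ifelse(out$state > out$ploidy, "gain", "loss")
  out$terminal <- out$start <= terminal_tolerance |
    out$end >= chroms$length[m] - terminal_tolerance
  out$cna_class <- paste(out$size_class, out$direction, sep = "_")
  out
}

#' Per-cell CNA rates and fold changes by class
#'
#' Counts CNAs per (condition, class), normalizes by the number of cells
#' sequenced per condition, and reports the fold change of each treated
#' condition's rate over the control rate.
#'
#' @param classified Classified CNA data.frame (\code{\link{classify_cna}})
#'   with a \code{condition} column.
#' @param cells_per_condition Named vector: cells sequenced per condition.
#' @param control Control condition label.
#' @return Data.frame: condition, cna_class, count, cells, rate,
#'   fold_change (NA with \code{fold_undefined = TRUE} when the control
#'   rate is 0).
#' @export
compute_rates <- function(classified, cells_per_condition, control) {
  if (!control %in% names(cells_per_condition))
    stop("invalid config: unknown control label '", control, "'")
  if (any(cells_per_condition <= 0))
    stop("invalid config: cells sequenced must be > 0 per condition")
  classes <- c("small_gain", "small_loss", "large_gain", "large_loss")
  grid <- expand.grid(condition = names(cells_per_condition),
                      cna_class = classes, stringsAsFactors = FALSE)
  grid$count <- mapply(function(cond, cl)
    sum(classified$condition == cond & classified$cna_class == cl),
    grid$condition, grid$cna_class)
  grid$cells <- as.numeric(cells_per_condition[grid$condition])
  grid$rate <- grid$count / grid$cells
  ctrl_rate <- setNames(grid$rate[grid$condition == control],
                        grid$cna_class[grid$condition == control])
  grid$fold_change <- ifelse(ctrl_rate[grid$cna_class] > 0,
                             grid$rate / ctrl_rate[grid$cna_class], NA_real_)
  grid$fold_undefined <- ctrl_rate[grid$cna_class] == 0 & grid$rate > 0
  rownames(grid) <- NULL
  grid[order(grid$condition, grid$cna_class), , drop = FALSE]
}

#' Chromosome-level and genome-bin CNA distributions
#'
#' Summarizes where CNAs fall: a per-chromosome table of small/large
#' counts (with chromosome length, to check size independence) and a
#' per-bin pileup track counting, for each genomic bin, how many cells
#' carry an overlapping CNA, split by direction.
#'
#' @param classified Classified CNA data.frame.
#' @param genome A \code{genome_model}.
#' @param pileup_binsize Pileup grid label (default "1Mb").
#' @return List with \code{$per_chrom} (chrom, length, n_small, n_large,
#'   n_total) and \code{$pileup} (chrom, start, end, n_gain, n_loss).
#' @export
summarize_distribution <- function(classified, genome,
                                   pileup_binsize = "1Mb") {
  chroms <- genome$chromosomes
  per_chrom <- data.frame(
    chrom = chroms$chrom, length = chroms$length,
    n_small = vapply(chroms$chrom, function(ch)
      sum(classified$chrom == ch & classified$size_class == "small"), 0),
    n_large = vapply(chroms$chrom, function(ch)
      sum(classified$chrom == ch & classified$size_class == "large"), 0),
    stringsAsFactors = FALSE)
  per_chrom$n_total <- per_chrom$n_small + per_chrom$n_large
  rownames(per_chrom) <- NULL

  bins <- bin_grid(genome, pileup_binsize)
  pile <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                     n_gain = 0L, n_loss = 0L, stringsAsFactors = FALSE)
  if (!is.null(classified) && nrow(classified) > 0) {
    bg <- .as_granges(bins)
    cg <- .as_granges(classified)
    hits <- GenomicRanges::findOverlaps(bg, cg)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    gain <- classified$direction[si] == "gain"
    tg <- table(factor(qi[gain], levels = seq_len(nrow(bins))))
    tl <- table(factor(qi[!gain], levels = seq_len(nrow(bins))))
    pile$n_gain <- as.integer(tg)
    pile$n_loss <- as.integer(tl)
  }
  list(per_chrom = per_chrom, pileup = pile)
}
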