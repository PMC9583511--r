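#' Build a synthetic genome model
#'
#' Constructs a multi-chromosome genome with fixed-width bin grids and a
#' smooth, spatially correlated GC-content track, suitable for simulating
#' binned single-cell read counts. All coordinates are 0-based, half-open
#' (BED convention).
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{chrom_lengths}{Named numeric vector of chromosome lengths in bp
#'       (each >= 10 Mb).}
#'     \item{centromere_frac}{Position of the centromere midpoint as a
#'       fraction of chromosome length (default 0.4); the centromere
#'       interval spans \code{centromere_width} bp around it.}
#'     \item{centromere_width}{Width of the centromere interval in bp
#'       (default 3 Mb).}
#'     \item{bin_sizes}{Named numeric vector of bin widths in bp; default
#'       \code{c("40kb" = 4e4, "500kb" = 5e5, "1Mb" = 1e6)}. Every bin size
#'       must tile each chromosome into at least 10 bins.}
#'     \item{gc_range}{Length-2 numeric, range of the GC track (default
#'       \code{c(0.3, 0.6)}).}
#'   }
#' @param seed Integer seed; the genome is deterministic given
#'   \code{config} and \code{seed}.
#'
#' @return An object of class \code{genome_model}: a list with
#'   \code{$chromosomes} (data.frame: chrom, length, cen_start, cen_end),
#'   \code{$bins} (named list of data.frames chrom/start/end/gc, one per
#'   bin size), and \code{$bin_sizes}.
#'
#' @details The GC field is a single smooth function per chromosome
#'   (cubic spline through Gaussian knots every 2 Mb, mapped through the
#'   normal CDF into \code{gc_range}); every bin grid evaluates the same
#'   field at its bin midpoints, so GC tracks are mutually consistent
#'   across resolutions. The last bin of each chromosome is truncated at
#'   the chromosome end.
#'
#' @examples
#' gm <- make_genome(list(chrom_lengths = c(chr1 = 5e7, chr2 = 4e7)), seed = 1)
#' nrow(bin_grid(gm, "1Mb"))
#' @export
make_genome <- function(config, seed = 1L) {
  lens <- config$chrom_lengths
  if (is.null(lens) || length(lens) == 0 || any(!is.finite(lens)) || any(lens <= 0))
    stop("invalid config: chrom_lengths must be positive")
  if (is.null(names(lens))) names(lens) <- paste0("chr", seq_along(lens))
  if (any(lens < 1e7)) stop("invalid config: chromosome lengths must be >= 10 Mb")
  bin_sizes <- config$bin_sizes
  if (is.null(bin_sizes)) bin_sizes <- c("40kb" = 4e4, "500kb" = 5e5, "1Mb" = 1e6)
  if (any(bin_sizes <= 0)) stop("invalid config: bin sizes must be positive")
  for (bs in bin_sizes) {
    if (any(floor(lens / bs) < 10))
      stop("invalid config: every chromosome must span >= 10 bins at each bin size")
  }
  cen_frac <- config$centromere_frac %||% 0.4
  cen_width <- config$centromere_width %||% 3e6
  gc_range <- config$gc_range %||% c(0.3, 0.6)

  chroms <- data.frame(
    chrom = names(lens),
    length = as.numeric(lens),
    cen_start = pmax(0, round(lens * cen_frac - cen_width / 2)),
    cen_end = pmin(as.numeric(lens), round(lens * cen_frac + cen_width / 2)),
    stringsAsFactors = FALSE
  )
  rownames(chroms) <- NULL

  # one smooth GC field per chromosome, shared by all bin grids: a
  # long-range (Mb-scale, isochore-like) component plus a short-range
  # component, so that any GC stratum draws bins dispersed across the
  # genome rather than one contiguous block
  set.seed(seed)
  gc_fun <- lapply(seq_len(nrow(chroms)), function(i) {
    len <- chroms$length[i]
    mk <- function(spacing) {
      knots <- seq(0, len, by = spacing)
      if (knots[length(knots)] < len) knots <- c(knots, len)
      stats::splinefun(knots, stats::rnorm(length(knots)), method = "natural")
    }
    f_long <- mk(2e6); f_short <- mk(3e5)
    function(x) gc_range[1] + diff(gc_range) *
      stats::pnorm((0.8 * f_long(x) + 0.6 * f_short(x)) / 1.2)
  })
  names(gc_fun) <- chroms$chrom

  bins <- lapply(bin_sizes, function(bs) {
    out <- lapply(seq_len(nrow(chroms)), function(i) {
      len <- chroms$length[i]
      starts <- seq(0, len - 1, by = bs)
      ends <- pmin(starts + bs, len)
      data.frame(chrom = chroms$chrom[i], start = starts, end = ends,
                 gc = gc_fun[[i]]((starts + ends) / 2),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  names(bins) <- names(bin_sizes)

  structure(list(chromosomes = chroms, bins = bins, bin_sizes = bin_sizes),
            class = "genome_model")
}

#' Retrieve a bin grid from a genome model
#'
#' @param genome A \code{genome_model}.
#' @param binsize Bin-size label, e.g. \code{"40kb"}, \code{"500kb"},
#'   \code{"1Mb"}.
#' @return Data.frame with columns chrom, start, end, gc (0-based
#'   half-open).
#' @export
bin_grid <- function(genome, binsize) {
  stopifnot(inherits(genome, "genome_model"))
  if (!binsize %in% names(genome$bins))
    stop("unknown bin size '", binsize, "'; available: ",
         paste(names(genome$bins), collapse = ", "))
  genome$bins[[binsize]]
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", nrow(x$chromosomes), "chromosomes,",
      format(sum(x$chromosomes$length), big.mark = ","), "bp\n")
  cat("bin grids:", paste(sprintf("%s (%d bins)", names(x$bins),
                                  vapply(x$bins, nrow, 1L)), collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# data.frame of 0-based half-open intervals -> GRanges (1-based closed)
.as_granges <- function(df, chrom = "chrom", start = "start", end = "end") {
  GenomicRanges::GRanges(
    seqnames = df[[chrom]],
    ranges = IRanges::IRanges(start = df[[start]] + 1, end = df[[end]])
  )
}
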