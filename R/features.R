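#' Generate a synthetic genomic feature set
#'
#' Builds gene annotations (ordinary, large > 600 kb, giant > 1 Mb) with
#' per-cell-type mean expression, common-fragile-site (CFS) and
#' early-replicating-fragile-site (ERFS) intervals, and a per-1-Mb-bin
#' secondary-structure repeat-coverage track, mimicking the annotation
#' tables a real analysis would assemble from genome-browser resources.
#'
#' @param genome A \code{genome_model}.
#' @param config List of options, all optional:
#'   \describe{
#'     \item{n_ordinary, n_large, n_giant}{Gene counts per class (defaults
#'       40, 6, 3). Large genes are drawn in (600 kb, 1 Mb], giant genes in
#'       (1 Mb, 2 Mb], ordinary genes in [5 kb, 500 kb].}
#'     \item{cell_types}{Character vector of cell-type labels for
#'       expression profiles (default \code{c("cell_type_A",
#'       "cell_type_B")}).}
#'     \item{silent_fraction}{Probability that a gene is silent (expression
#'       0) in a given cell type (default 0.3).}
#'     \item{silent_genes}{Optional named list (by cell type) of gene names
#'       forced to expression 0 in that cell type.}
#'     \item{n_cfs, n_erfs}{Fragile-site interval counts (defaults 8, 8).}
#'   }
#' @param seed Integer seed; output is deterministic given config + seed.
#'
#' @return An object of class \code{feature_set}: list with
#'   \code{$genes} (chrom, start, end, name, strand, length, class,
#'   one expression column per cell type), \code{$cfs}, \code{$erfs}
#'   (interval data.frames), and \code{$repeats} (per-1-Mb-bin chrom,
#'   start, end, coverage in [0,1]).
#' @export
make_features <- function(genome, config = list(), seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  n_ordinary <- config$n_ordinary %||% 40L
  n_large <- config$n_large %||% 6L
  n_giant <- config$n_giant %||% 3L
  cell_types <- config$cell_types %||% c("cell_type_A", "cell_type_B")
  silent_fraction <- config$silent_fraction %||% 0.3
  n_cfs <- config$n_cfs %||% 8L
  n_erfs <- config$n_erfs %||% 8L
  chroms <- genome$chromosomes

  set.seed(seed)
  draw_len <- function(class) {
    switch(class,
      ordinary = stats::runif(1, 5e3, 5e5),
      large = stats::runif(1, 6e5 + 1, 1e6),
      giant = stats::runif(1, 1e6 + 1, 2e6))
  }
  classes <- c(rep("ordinary", n_ordinary), rep("large", n_large),
               rep("giant", n_giant))
  place <- function(len) {
    ok <- chroms$length > len
    if (!any(ok)) stop("invalid config: requested gene longer than every chromosome")
    i <- sample(which(ok), 1, prob = chroms$length[ok])
    start <- floor(stats::runif(1, 0, chroms$length[i] - len))
    c(i, start)
  }
  genes <- do.call(rbind, lapply(seq_along(classes), function(k) {
    len <- round(draw_len(classes[k]))
    if (len >= max(chroms$length))
      stop("invalid config: requested gene longer than its chromosome")
    p <- place(len)
    data.frame(chrom = chroms$chrom[p[1]], start = p[2], end = p[2] + len,
               name = sprintf("gene_%02d_%s", k, classes[k]),
               strand = sample(c("+", "-"), 1),
               length = len, class = classes[k], stringsAsFactors = FALSE)
  }))
  for (ct in cell_types) {
    silent <- stats::runif(nrow(genes)) < silent_fraction
    expr <- ifelse(silent, 0, round(stats::rlnorm(nrow(genes), 2, 1), 3))
    forced <- config$silent_genes[[ct]]
    if (!is.null(forced)) expr[genes$name %in% forced] <- 0
    genes[[ct]] <- expr
  }
  rownames(genes) <- NULL

  rand_intervals <- function(n, min_w = 3e5, max_w = 2e6) {
    do.call(rbind, lapply(seq_len(n), function(k) {
      w <- round(stats::runif(1, min_w, max_w))
      i <- sample(nrow(chroms), 1, prob = chroms$length)
      s <- floor(stats::runif(1, 0, chroms$length[i] - w))
      data.frame(chrom = chroms$chrom[i], start = s, end = s + w,
                 name = sprintf("site_%02d", k), stringsAsFactors = FALSE)
    }))
  }
  cfs <- rand_intervals(n_cfs)
  erfs <- rand_intervals(n_erfs)

  rep_bins <- bin_grid(genome, "1Mb")
  repeats <- data.frame(chrom = rep_bins$chrom, start = rep_bins$start,
                        end = rep_bins$end,
                        coverage = stats::rbeta(nrow(rep_bins), 0.8, 4),
                        stringsAsFactors = FALSE)

  structure(list(genes = genes, cfs = cfs, erfs = erfs, repeats = repeats,
                 cell_types = cell_types),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("feature_set:", nrow(x$genes), "genes (",
      sum(x$genes$class == "large"), "large,",
      sum(x$genes$class == "giant"), "giant ),",
      nrow(x$cfs), "CFS,", nrow(x$erfs), "ERFS,",
      nrow(x$repeats), "repeat bins\n")
  invisible(x)
}
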