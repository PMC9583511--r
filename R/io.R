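#' Write a count matrix as TSV
#'
#' Bins as rows (chrom, start, end) and cells as columns; the standard
#' exchange format of the pipeline.
#'
#' @param profiles List of \code{cell_profile} on a single bin grid.
#' @param genome A \code{genome_model}.
#' @param path Output file.
#' @return Invisibly, the written data.frame.
#' @export
write_counts_tsv <- function(profiles, genome, path) {
  stopifnot(length(profiles) > 0)
  binsize <- unique(vapply(profiles, `[[`, "", "binsize"))
  stopifnot(length(binsize) == 1)
  bins <- bin_grid(genome, binsize)
  mat <- vapply(profiles, `[[`, numeric(nrow(bins)), "counts")
  colnames(mat) <- vapply(profiles, `[[`, "", "cell")
  out <- cbind(bins[c("chrom", "start", "end")], as.data.frame(mat,
               check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Read a count matrix TSV back into cell profiles
#'
#' @param path TSV written by \code{\link{write_counts_tsv}}.
#' @param binsize Bin-grid label of the matrix.
#' @param conditions Optional named vector mapping cell id to condition.
#' @param fractions Optional named vector mapping cell id to
#'   cell-cycle-fraction label (default "G1").
#' @return List of \code{cell_profile} (without simulation ground truth).
#' @export
read_counts_tsv <- function(path, binsize, conditions = NULL,
                            fractions = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  cells <- setdiff(names(df), c("chrom", "start", "end"))
  lapply(cells, function(cl) {
    counts <- as.integer(df[[cl]])
    structure(list(cell = cl,
                   condition = unname(conditions[cl] %||% NA_character_),
                   fraction = unname(fractions[cl] %||% "G1"),
                   binsize = binsize, counts = counts, total = sum(counts),
                   truth = NULL),
              class = "cell_profile")
  })
}

#' Write CNA segments as BED-like TSV
#'
#' @param segments Segment data.frame.
#' @param path Output file.
#' @export
write_segments_tsv <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(segments)
}

#' Read a segment TSV
#'
#' @param path File written by \code{\link{write_segments_tsv}}.
#' @return Segment data.frame.
#' @export
read_segments_tsv <- function(path) utils::read.delim(path)

#' Write intervals in BED format
#'
#' Three BED columns plus an optional name column; coordinates are
#' already 0-based half-open throughout the package.
#'
#' @param df Data.frame with chrom/start/end and optionally name.
#' @param path Output file.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(df))
  utils::write.table(df[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(df)
}

#' Write a per-bin track in bedGraph format
#'
#' @param df Data.frame with chrom/start/end.
#' @param value_col Name of the value column.
#' @param path Output file.
#' @export
write_bedgraph <- function(df, value_col, path) {
  keep <- !is.na(df[[value_col]])
  utils::write.table(df[keep, c("chrom", "start", "end", value_col)], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(df)
}

#' Write a genome model as plain-text tables
#'
#' @param genome A \code{genome_model}.
#' @param dir Output directory (created if needed).
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(genome$chromosomes, file.path(dir, "chromosomes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (b in names(genome$bins))
    utils::write.table(genome$bins[[b]], file.path(dir, paste0("bins_", b, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(genome)
}

#' Read a genome model written by \code{\link{write_genome}}
#'
#' @param dir Directory containing chromosomes.tsv and bins_*.tsv.
#' @return A \code{genome_model}.
#' @export
read_genome <- function(dir) {
  chroms <- utils::read.delim(file.path(dir, "chromosomes.tsv"))
  bin_files <- list.files(dir, pattern = "^bins_.*\\.tsv$", full.names = TRUE)
  bins <- lapply(bin_files, utils::read.delim)
  names(bins) <- sub("^bins_(.*)\\.tsv$", "\\1", basename(bin_files))
  sizes <- vapply(bins, function(b) {
    w <- b$end - b$start
    as.numeric(stats::median(w))
  }, 0)
  structure(list(chromosomes = chroms, bins = bins, bin_sizes = sizes),
            class = "genome_model")
}

#' Write / read a feature set as plain-text tables
#'
#' @param features A \code{feature_set}.
#' @param dir Output directory.
#' @export
write_features <- function(features, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("genes", "cfs", "erfs", "repeats"))
    utils::write.table(features[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(features)
}

#' @rdname write_features
#' @export
read_features <- function(dir) {
  out <- lapply(c(genes = "genes", cfs = "cfs", erfs = "erfs",
                  repeats = "repeats"), function(nm)
    utils::read.delim(file.path(dir, paste0(nm, ".tsv"))))
  out$cell_types <- setdiff(names(out$genes),
                            c("chrom", "start", "end", "name", "strand",
                              "length", "class"))
  structure(out, class = "feature_set")
}
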