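#' @importFrom stats median quantile setNames
NULL

# reciprocal overlap fraction of two interval vectors (same chromosome
# assumed); fraction of BOTH intervals covered by the intersection
.recip_overlap <- function(s1, e1, s2, e2) {
  inter <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  pmin(inter / (e1 - s1), inter / (e2 - s2))
}

#' Identify clonal CNAs among control cells
#'
#' Control-cell segments that share the same integer copy state and
#' overlap reciprocally by at least \code{overlap_threshold} are grouped
#' by single linkage; groups supported by at least \code{min_cells}
#' distinct control cells ("more than two" at the default 3) become
#' clonal events whose representative interval is the union of their
#' members.
#'
#' @param control_segments Segment data.frame from control cells only.
#' @param overlap_threshold Minimum reciprocal overlap (default 0.5).
#' @param min_cells Minimum number of distinct supporting control cells
#'   (default 3).
#' @param match \code{"state"} (identical integer copy state, default) or
#'   \code{"direction"} (same sign relative to baseline).
#' @return Data.frame of clonal events: chrom, start, end, state,
#'   n_cells, members (semicolon-joined row ids of member segments).
#' @export
find_clonal <- function(control_segments, overlap_threshold = 0.5,
                        min_cells = 3L, match = c("state", "direction")) {
  match <- match.arg(match)
  segs <- control_segments
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      state = integer(), n_cells = integer(),
                      members = character(), stringsAsFactors = FALSE)
  if (is.null(segs) || nrow(segs) == 0) return(empty)
  segs$.id <- seq_len(nrow(segs))
  key <- if (match == "state") segs$state else sign(segs$state - segs$ploidy)

  gr <- .as_granges(segs)
  hits <- GenomicRanges::findOverlaps(gr, gr)
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  keep <- i < j & key[i] == key[j] &
    .recip_overlap(segs$start[i], segs$end[i], segs$start[j], segs$end[j]) >=
      overlap_threshold
  i <- i[keep]; j <- j[keep]

  g <- igraph::make_empty_graph(n = nrow(segs), directed = FALSE)
  if (length(i)) g <- igraph::add_edges(g, rbind(i, j))
  comp <- igraph::components(g)$membership

  out <- lapply(split(seq_len(nrow(segs)), comp), function(idx) {
    if (length(unique(segs$cell[idx])) < min_cells) return(NULL)
    data.frame(chrom = segs$chrom[idx[1]],
               start = min(segs$start[idx]), end = max(segs$end[idx]),
               state = segs$state[idx[1]],
               n_cells = length(unique(segs$cell[idx])),
               members = paste(segs$.id[idx], collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Mask clonal CNAs from a segment set
#'
#' Removes every segment that matches a clonal event in copy state and
#' overlaps it reciprocally by at least the threshold. Idempotent; output
#' is a subset of the input.
#'
#' @param segments Segment data.frame (any condition).
#' @param clonal Clonal events from \code{\link{find_clonal}}.
#' @param overlap_threshold Minimum reciprocal overlap (default 0.5).
#' @return Filtered segment data.frame.
#' @export
mask_clonal <- function(segments, clonal, overlap_threshold = 0.5) {
  if (is.null(segments) || nrow(segments) == 0) return(segments)
  if (is.null(clonal) || nrow(clonal) == 0) return(segments)
  drop <- logical(nrow(segments))
  for (k in seq_len(nrow(clonal))) {
    cand <- segments$chrom == clonal$chrom[k] & segments$state == clonal$state[k]
    if (!any(cand)) next
    ro <- .recip_overlap(segments$start[cand], segments$end[cand],
                         clonal$start[k], clonal$end[k])
    drop[which(cand)[ro >= overlap_threshold]] <- TRUE
  }
  segments[!drop, , drop = FALSE]
}

#' Remove chromosome-end and centromere mapping artifacts
#'
#' Removes (a) segments touching a chromosome end whose length is below
#' \code{min_terminal_size} and (b) segments intersecting a centromere
#' interval expanded by \code{centromere_pad} on both sides; both mimic
#' repetitive-sequence mapping artifacts at telomeres and centromeres.
#'
#' @param segments Segment data.frame.
#' @param genome A \code{genome_model} (provides chromosome lengths and
#'   centromere intervals).
#' @param min_terminal_size Minimum length of a chromosome-end segment
#'   (default 1 Mb).
#' @param centromere_pad Pad around centromeres (default 1 Mb).
#' @return Filtered segment data.frame.
#' @export
filter_boundary_artifacts <- function(segments, genome,
                                      min_terminal_size = 1e6,
                                      centromere_pad = 1e6) {
  if (is.null(segments) || nrow(segments) == 0) return(segments)
  chroms <- genome$chromosomes
  m <- match(segments$chrom, chroms$chrom)
  if (anyNA(m) || any(segments$start < 0) ||
      any(segments$end > chroms$length[m]))
    stop("invalid input: segment outside chromosome bounds")
  len <- chroms$length[m]
  touches_end <- segments$start == 0 | segments$end == len
  small_terminal <- touches_end & (segments$end - segments$start) < min_terminal_size
  cs <- chroms$cen_start[m] - centromere_pad
  ce <- chroms$cen_end[m] + centromere_pad
  near_cen <- segments$start < ce & segments$end > cs
  segments[!(small_terminal | near_cen), , drop = FALSE]
}

#' Drop hypermutated cells
#'
#' Cells with more than \code{max_cnas} surviving CNAs are removed
#' entirely (likely catastrophic or low-quality libraries), except in
#' siRNA mode where elevated background rates are expected.
#'
#' @param segments Segment data.frame (after clonal masking and artifact
#'   filtering).
#' @param max_cnas Maximum CNAs per cell (default 10).
#' @param sirna_mode If TRUE, no cells are dropped.
#' @return List with \code{$kept} (segments) and \code{$dropped_cells}
#'   (character vector).
#' @export
filter_hypermutated_cells <- function(segments, max_cnas = 10L,
                                      sirna_mode = FALSE) {
  if (is.null(segments) || nrow(segments) == 0)
    return(list(kept = segments, dropped_cells = character()))
  counts <- table(segments$cell)
  dropped <- if (sirna_mode) character() else
    names(counts)[counts > max_cnas]
  list(kept = segments[!segments$cell %in% dropped, , drop = FALSE],
       dropped_cells = dropped)
}

#' Refine low-resolution breakpoints with high-resolution calls
#'
#' For each 500-kb segment of a cell, collects same-state 40-kb segments
#' of the same cell at least a fraction \code{match_overlap} of whose
#' length overlaps the 500-kb segment; if any exist, the left boundary is
#' reset to the leftmost matching high-resolution left boundary and the
#' right boundary to the rightmost matching right boundary. The overlap
#' requirement is relative to the high-resolution segment so that a long
#' 500-kb call adopts the boundaries of all the focal 40-kb calls it
#' covers. Unmatched segments are returned unchanged. A logical
#' \code{refined} column records which segments moved.
#'
#' @param low_res Segment data.frame at 500 kb, single cell.
#' @param high_res Segment data.frame at 40 kb, same cell.
#' @param match_overlap Minimum overlapping fraction of the
#'   high-resolution segment (default 0.5).
#' @return \code{low_res} with possibly updated boundaries and a
#'   \code{refined} column.
#' @export
refine_breakpoints <- function(low_res, high_res, match_overlap = 0.5) {
  if (is.null(low_res) || nrow(low_res) == 0) {
    if (!is.null(low_res)) low_res$refined <- logical(0)
    return(low_res)
  }
  cells <- unique(c(low_res$cell, if (!is.null(high_res)) high_res$cell))
  if (length(cells) > 1)
    stop("invalid input: refine_breakpoints operates on a single cell; ",
         "use refine_all for multi-cell tables")
  low_res$refined <- FALSE
  if (is.null(high_res) || nrow(high_res) == 0) return(low_res)
  for (k in seq_len(nrow(low_res))) {
    cand <- high_res$chrom == low_res$chrom[k] &
      high_res$state == low_res$state[k]
    if (!any(cand)) next
    inter <- pmax(0, pmin(low_res$end[k], high_res$end[cand]) -
                    pmax(low_res$start[k], high_res$start[cand]))
    frac <- inter / (high_res$end[cand] - high_res$start[cand])
    hit <- which(cand)[frac >= match_overlap]
    if (!length(hit)) next
    low_res$start[k] <- min(high_res$start[hit])
    low_res$end[k] <- max(high_res$end[hit])
    low_res$refined[k] <- TRUE
  }
  low_res
}

#' Refine breakpoints across many cells
#'
#' Applies \code{\link{refine_breakpoints}} cell by cell.
#'
#' @inheritParams refine_breakpoints
#' @param low_res,high_res Multi-cell segment data.frames at 500 kb and
#'   40 kb.
#' @return Refined low-resolution table with a \code{refined} column.
#' @export
refine_all <- function(low_res, high_res, match_overlap = 0.5) {
  if (is.null(low_res) || nrow(low_res) == 0) {
    if (!is.null(low_res)) low_res$refined <- logical(0)
    return(low_res)
  }
  out <- lapply(split(low_res, low_res$cell), function(lo) {
    hi <- high_res[high_res$cell == lo$cell[1], , drop = FALSE]
    refine_breakpoints(lo, hi, match_overlap)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$cell, out$chrom, out$start), , drop = FALSE]
}

#' Full clonal-masking pipeline
#'
#' Runs the masking stages in their canonical order: clonal events are
#' learned from control cells and masked from all cells, boundary
#' (telomere/centromere) artifacts are removed, hypermutated cells are
#' dropped, and (optionally) surviving 500-kb boundaries are refined with
#' 40-kb calls.
#'
#' @param segments Multi-cell segment data.frame at the analysis
#'   resolution (500 kb).
#' @param cell_conditions Named character vector mapping cell id to
#'   condition label.
#' @param control Control condition label.
#' @param genome A \code{genome_model}.
#' @param high_res Optional 40-kb segment table for refinement.
#' @param overlap_threshold,min_cells,min_terminal_size,centromere_pad,
#'   max_cnas,sirna_mode,match_overlap Stage parameters (see the
#'   stage functions).
#' @return List: \code{$segments} (masked, filtered, refined),
#'   \code{$clonal} (clonal events), \code{$dropped_cells}, and
#'   \code{$log} (per-stage in/out counts).
#' @export
mask_cnas <- function(segments, cell_conditions, control, genome,
                      high_res = NULL, overlap_threshold = 0.5,
                      min_cells = 3L, min_terminal_size = 1e6,
                      centromere_pad = 1e6, max_cnas = 10L,
                      sirna_mode = FALSE, match_overlap = 0.5) {
  if (!control %in% cell_conditions)
    stop("unknown control label '", control, "'")
  n0 <- nrow(segments)
  ctrl_cells <- names(cell_conditions)[cell_conditions == control]
  clonal <- find_clonal(segments[segments$cell %in% ctrl_cells, , drop = FALSE],
                        overlap_threshold, min_cells)
  masked <- mask_clonal(segments, clonal, overlap_threshold)
  n1 <- nrow(masked)
  filtered <- filter_boundary_artifacts(masked, genome, min_terminal_size,
                                        centromere_pad)
  n2 <- nrow(filtered)
  hm <- filter_hypermutated_cells(filtered, max_cnas, sirna_mode)
  n3 <- nrow(hm$kept)
  out <- hm$kept
  if (!is.null(high_res)) out <- refine_all(out, high_res, match_overlap)
  log <- data.frame(
    stage = c("clonal_mask", "boundary_artifacts", "hypermutated_cells"),
    n_in = c(n0, n1, n2), n_out = c(n1, n2, n3),
    stringsAsFactors = FALSE)
  list(segments = out, clonal = clonal, dropped_cells = hm$dropped_cells,
       log = log)
}
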