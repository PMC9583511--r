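#' Default pipeline configuration
#'
#' Returns the full nested configuration for \code{\link{run_pipeline}}
#' with every stage parameter at its default. The defaults describe a
#' two-condition (control vs treated) synthetic experiment on a compact
#' two-chromosome genome: clonal and sub-clonal events shared with the
#' control population, plus treatment-induced de-novo CNAs, and four
#' S-phase fractions for replication timing.
#'
#' @param seed Top-level seed; every stage derives its own seed from it.
#' @return Nested list; serialize with \code{\link{write_config}}.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    outdir = tempfile("repstress_run_"),
    control = "control",
    genome = list(chrom_lengths = c(chr1 = 1e8, chr2 = 1e8)),
    features = list(n_ordinary = 40, n_large = 6, n_giant = 3,
                    cell_types = c("cell_type_A", "cell_type_B"),
                    silent_fraction = 0.3),
    simulate = list(
      n_cells = c(control = 25, treated = 25),
      reads_per_cell = 1e5, dispersion = 0.01, gc_bias_strength = 0.3,
      n_clonal = 2, n_subclonal = 2, subclonal_fraction = 0.3,
      n_de_novo_background = 2, de_novo_background_rate = 0.03,
      n_de_novo_induced = 5, de_novo_induced_rate = 0.15,
      sphase = list(enabled = TRUE, n_cells = 15, noise = 0.05,
                    n_g1_ref = 10)),
    call = list(max_state = 8, min_bins = 2, min_reads = 1e4,
                max_spikiness = 0.35),
    mask = list(overlap = 0.5, min_cells = 3, max_cnas = 10,
                sirna_mode = FALSE, refine = TRUE,
                min_terminal_size = 1e6, centromere_pad = 1e6),
    landscape = list(size_threshold = 2e7),
    rt = list(fractions = c(0.125, 0.375, 0.635, 0.875),
              low_quantile = 0.1, extreme_total = 0.05),
    associate = list(n_controls = 500, window = 2e6, cutoff = 1e6,
                     top_fraction = 0.5, min_group = 5,
                     cell_type = "cell_type_A"))
}

#' Read / write a pipeline configuration
#'
#' Configurations are plain-text YAML and round-trip unchanged.
#'
#' @param path File path.
#' @return \code{read_config}: the configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$genome$chrom_lengths))
    cfg$genome$chrom_lengths <- unlist(cfg$genome$chrom_lengths)
  if (!is.null(cfg$simulate$n_cells))
    cfg$simulate$n_cells <- unlist(cfg$simulate$n_cells)
  cfg
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  # named atomic vectors must become YAML maps, or their names are lost
  mapify <- function(x) {
    if (is.list(x)) lapply(x, mapify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(mapify(config), path)
  invisible(path)
}

.stage_seed <- function(seed, offset) (as.integer(seed) + offset) %% .Machine$integer.max

#' Run the full replication-stress CNA pipeline
#'
#' Executes simulate (optional) -> QC -> copy-number calling at 500 kb
#' and 40 kb -> clonal masking with breakpoint refinement -> CNA
#' classification, rates and distributions -> replication timing
#' (optional) -> breakpoint-feature association, writing all
#' intermediate tables and a structured log to the configured output
#' directory. Deterministic given the configuration seed.
#'
#' @param config Configuration list (\code{\link{default_config}}).
#' @return Invisibly, a report list: \code{$rates}, \code{$distribution},
#'   \code{$classified}, \code{$clonal}, \code{$rt}, \code{$delta_rt},
#'   \code{$association}, \code{$qc}, \code{$log},
#'   \code{$cell_accounting}, plus the simulated objects under
#'   \code{$inputs}.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- config
  if (is.null(cfg$control)) stop("config missing control label")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  note <- function(stage, what, n_in, n_out) {
    log[[length(log) + 1L]] <<- data.frame(stage = stage, what = what,
                                           n_in = n_in, n_out = n_out,
                                           stringsAsFactors = FALSE)
    message(sprintf("[%s] %s: %d -> %d", stage, what, n_in, n_out))
  }

  # --- simulate -------------------------------------------------------
  genome <- make_genome(cfg$genome, seed = .stage_seed(cfg$seed, 11L))
  features <- make_features(genome, cfg$features, seed = .stage_seed(cfg$seed, 12L))
  sim <- cfg$simulate
  cen <- genome$chromosomes
  avoid <- data.frame(chrom = cen$chrom, start = cen$cen_start - 2e6,
                      end = cen$cen_end + 2e6, stringsAsFactors = FALSE)
  truth <- NULL
  ev_spec <- list(
    list(sim$n_clonal, "clonal", "*", 1, 13L),
    list(sim$n_subclonal, "subclonal", "*", sim$subclonal_fraction, 14L),
    list(sim$n_de_novo_background, "de_novo", "*",
         sim$de_novo_background_rate, 15L),
    list(sim$n_de_novo_induced, "de_novo", "treated",
         sim$de_novo_induced_rate, 16L))
  for (sp in ev_spec) {
    if (sp[[1]] < 1) next
    tr <- random_truth_cnas(genome, sp[[1]], clonality = sp[[2]],
                            condition = sp[[3]], cell_fraction = sp[[4]],
                            rate = sp[[4]], avoid = avoid,
                            seed = .stage_seed(cfg$seed, sp[[5]]))
    if (is.null(tr)) next
    truth <- rbind(truth, tr)
    # later event classes must not stack on earlier ones
    avoid <- rbind(avoid, data.frame(chrom = tr$chrom, start = tr$start - 1e6,
                                     end = tr$end + 1e6,
                                     stringsAsFactors = FALSE))
  }
  profiles <- simulate_g1_cells(genome, truth, n_cells = sim$n_cells,
                                reads_per_cell = sim$reads_per_cell,
                                dispersion = sim$dispersion,
                                gc_bias_strength = sim$gc_bias_strength,
                                binsizes = c("500kb", "40kb"),
                                seed = .stage_seed(cfg$seed, 17L))
  p500 <- Filter(function(p) p$binsize == "500kb", profiles)
  p40 <- Filter(function(p) p$binsize == "40kb", profiles)
  cell_conditions <- stats::setNames(
    vapply(p500, `[[`, "", "condition"), vapply(p500, `[[`, "", "cell"))
  if (!cfg$control %in% cell_conditions)
    stop("mask stage: control label '", cfg$control,
         "' matches no simulated condition")
  write_counts_tsv(p500, genome, file.path(cfg$outdir, "counts_500kb.tsv"))
  write_genome(genome, file.path(cfg$outdir, "genome"))

  # --- QC + call ------------------------------------------------------
  qc <- qc_filter(p500, min_reads = cfg$call$min_reads,
                  max_spikiness = cfg$call$max_spikiness)
  note("call", "cells_pass_qc", length(p500), length(qc$kept))
  kept_cells <- vapply(qc$kept, `[[`, "", "cell")
  segs500 <- call_cells(qc$kept, genome, max_state = cfg$call$max_state,
                        min_bins = cfg$call$min_bins)
  segs40 <- call_cells(Filter(function(p) p$cell %in% kept_cells, p40),
                       genome, max_state = cfg$call$max_state,
                       min_bins = cfg$call$min_bins)
  note("call", "segments_500kb", length(qc$kept), nrow(segs500))
  write_segments_tsv(segs500, file.path(cfg$outdir, "segments_500kb.tsv"))
  write_segments_tsv(segs40, file.path(cfg$outdir, "segments_40kb.tsv"))

  # --- mask + refine --------------------------------------------------
  masked <- mask_cnas(segs500, cell_conditions[kept_cells], cfg$control,
                      genome,
                      high_res = if (isTRUE(cfg$mask$refine)) segs40 else NULL,
                      overlap_threshold = cfg$mask$overlap,
                      min_cells = cfg$mask$min_cells,
                      min_terminal_size = cfg$mask$min_terminal_size,
                      centromere_pad = cfg$mask$centromere_pad,
                      max_cnas = cfg$mask$max_cnas,
                      sirna_mode = isTRUE(cfg$mask$sirna_mode))
  for (k in seq_len(nrow(masked$log)))
    note("mask", masked$log$stage[k], masked$log$n_in[k], masked$log$n_out[k])
  write_segments_tsv(masked$segments, file.path(cfg$outdir, "segments_masked.tsv"))

  # --- landscape ------------------------------------------------------
  classified <- classify_cna(masked$segments, genome,
                             size_threshold = cfg$landscape$size_threshold)
  classified$condition <- unname(cell_conditions[classified$cell])
  analysed_cells <- setdiff(kept_cells, masked$dropped_cells)
  cells_per_condition <- table(cell_conditions[analysed_cells])
  rates <- compute_rates(classified, cells_per_condition, cfg$control)
  distribution <- summarize_distribution(classified, genome)
  utils::write.table(rates, file.path(cfg$outdir, "rates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(distribution$per_chrom,
                     file.path(cfg$outdir, "distribution_per_chrom.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bedgraph(cbind(distribution$pileup,
                       n_total = distribution$pileup$n_gain +
                         distribution$pileup$n_loss),
                 "n_total", file.path(cfg$outdir, "pileup.bedGraph"))

  # --- replication timing ---------------------------------------------
  rt <- NULL; drt <- NULL; truth_rt <- NULL
  if (isTRUE(sim$sphase$enabled)) {
    truth_rt <- make_truth_rt(genome, seed = .stage_seed(cfg$seed, 21L))
    fr <- data.frame(label = c("S1", "S2", "S3", "S4"), p = cfg$rt$fractions)
    g1_ref <- simulate_g1_cells(genome, NULL,
                                n_cells = c(control = sim$sphase$n_g1_ref),
                                reads_per_cell = sim$reads_per_cell,
                                dispersion = sim$dispersion,
                                gc_bias_strength = 0, binsizes = "1Mb",
                                seed = .stage_seed(cfg$seed, 22L))
    sp_c <- simulate_sphase_cells(genome, truth_rt, fr,
                                  n_cells = sim$sphase$n_cells,
                                  reads_per_cell = sim$reads_per_cell,
                                  dispersion = sim$dispersion,
                                  noise = sim$sphase$noise,
                                  condition = "control",
                                  seed = .stage_seed(cfg$seed, 23L))
    sp_t <- simulate_sphase_cells(genome, truth_rt, fr,
                                  n_cells = sim$sphase$n_cells,
                                  reads_per_cell = sim$reads_per_cell,
                                  dispersion = sim$dispersion,
                                  noise = sim$sphase$noise,
                                  condition = "treated",
                                  seed = .stage_seed(cfg$seed, 24L))
    rt <- compute_rt_profile(sp_c, g1_ref, genome, fr,
                             low_quantile = cfg$rt$low_quantile)
    rt_t <- compute_rt_profile(sp_t, g1_ref, genome, fr,
                               low_quantile = cfg$rt$low_quantile)
    drt <- delta_rt(rt_t, rt, extreme_total = cfg$rt$extreme_total)
    note("rt", "usable_bins", nrow(rt), sum(rt$usable))
    utils::write.table(rt, file.path(cfg$outdir, "rt_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_bedgraph(rt, "rtf", file.path(cfg$outdir, "rtf.bedGraph"))
    utils::write.table(drt, file.path(cfg$outdir, "delta_rt.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- association ----------------------------------------------------
  assoc <- list()
  treated_cnas <- classified[classified$condition != cfg$control, , drop = FALSE]
  bp <- extract_breakpoints(treated_cnas, genome)
  controls <- generate_random_controls(genome, cfg$associate$n_controls,
                                       seed = .stage_seed(cfg$seed, 31L))
  note("associate", "breakpoints", nrow(treated_cnas), nrow(bp))
  if (nrow(bp) > 0) {
    lg <- features$genes[features$genes$class %in% c("large", "giant"), ]
    for (feat in c("genes", "cfs", "erfs")) {
      fset <- if (feat == "genes") lg else features[[feat]]
      d_bp <- distance_to_nearest(bp, fset, cutoff = cfg$associate$cutoff)
      d_ctrl <- distance_to_nearest(controls, fset)
      vals <- split(d_bp$per_cna$distance, d_bp$per_cna$cna_class)
      vals$control <- d_ctrl$breakpoints$distance[!is.na(d_ctrl$breakpoints$distance)]
      vals <- lapply(vals, function(v) v[!is.na(v)])
      assoc[[paste0("distance_", feat)]] <-
        list(result = tryCatch(compare_groups(vals), error = function(e) NULL),
             per_cna = d_bp$per_cna, proportion_within = d_bp$proportion_within)
    }
    we_bp <- window_expression(bp, features$genes, cfg$associate$cell_type,
                               genome, window = cfg$associate$window)
    we_ctrl <- window_expression(controls, features$genes,
                                 cfg$associate$cell_type, genome,
                                 window = cfg$associate$window)
    vals <- split(we_bp$window_expression, we_bp$cna_class)
    vals$control <- we_ctrl$window_expression
    assoc$expression <- list(
      result = tryCatch(compare_groups(vals), error = function(e) NULL),
      breakpoints = we_bp)
    assoc$repeats <- repeat_bin_enrichment(bp, features$repeats,
                                           top_fraction = cfg$associate$top_fraction,
                                           min_group = cfg$associate$min_group)
    if (!is.null(rt)) {
      rtf_at <- function(chrom, pos) {
        idx <- which(rt$chrom == chrom & rt$start <= pos & pos < rt$end)
        if (length(idx) && rt$usable[idx[1]]) rt$rtf[idx[1]] else NA_real_
      }
      bp_rtf <- mapply(rtf_at, bp$chrom, bp$pos)
      ctrl_rtf <- mapply(rtf_at, controls$chrom, controls$pos)
      vals <- split(bp_rtf, bp$cna_class)
      vals$control <- ctrl_rtf
      vals <- lapply(vals, function(v) v[!is.na(v)])
      assoc$rtf <- list(
        result = tryCatch(compare_groups(vals), error = function(e) NULL),
        breakpoint_rtf = data.frame(bp, rtf = bp_rtf))
    }
    assoc$repeats_path <- file.path(cfg$outdir, "repeat_enrichment.tsv")
    utils::write.table(assoc$repeats, assoc$repeats_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  # --- accounting -----------------------------------------------------
  cell_accounting <- data.frame(
    condition = names(table(cell_conditions)),
    n_in = as.integer(table(cell_conditions)),
    n_failed_qc = vapply(names(table(cell_conditions)), function(cd)
      sum(!qc$report$pass & cell_conditions[qc$report$cell] == cd), 0L),
    n_hypermutated = vapply(names(table(cell_conditions)), function(cd)
      sum(cell_conditions[masked$dropped_cells] == cd), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  cell_accounting$n_analysed <- cell_accounting$n_in -
    cell_accounting$n_failed_qc - cell_accounting$n_hypermutated

  log_df <- do.call(rbind, log)
  utils::write.table(log_df, file.path(cfg$outdir, "pipeline_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cell_accounting,
                     file.path(cfg$outdir, "cell_accounting.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(rates = rates, distribution = distribution,
                 classified = classified, clonal = masked$clonal,
                 rt = rt, delta_rt = drt, association = assoc,
                 qc = qc$report, log = log_df,
                 cell_accounting = cell_accounting,
                 inputs = list(genome = genome, features = features,
                               truth = truth, truth_rt = truth_rt,
                               cell_conditions = cell_conditions),
                 outdir = cfg$outdir))
}
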