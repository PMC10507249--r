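#' Run the full analysis pipeline
#'
#' Chains the enabled stages on synthetic (or on-disk) data and writes
#' per-stage TSV tables plus a machine-readable JSON run summary to the
#' configured output directory. Identical config + seed produce
#' byte-identical numeric outputs.
#'
#' Stages: `simulate` (oocyte + granulosa cohorts), `qc` (Ct gating and
#' cell filters), `quantify` (RPM/log2, spike-in copy model), `bias`
#' (fresh-vs-section artifact report), `model` (size model + matching),
#' `deg` (positional DEGs), `junctions` (TMM exon profiling).
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, the run summary list (also written as
#'   `summary.json`).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  validate_config(cfg)
  out <- cfg$io$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  th <- cfg$thresholds
  grid <- seq(cfg$diameter_grid$start, cfg$diameter_grid$stop,
              by = cfg$diameter_grid$step)
  summary <- list(seed = cfg$seed,
                  package_version = as.character(utils::packageVersion("lcmtx")),
                  thresholds = th, stages = list())
  scfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))

  ooc <- gran <- NULL
  if (isTRUE(cfg$stages$simulate)) {
    ooc <- gen_oocyte_cohort(scfg)
    gran <- gen_granulosa_cohort(scfg)
    write_count_matrix(ooc$counts, file.path(out, "oocyte_counts.tsv"))
    write_count_matrix(gran$counts, file.path(out, "granulosa_counts.tsv"))
    write_metadata(ooc$records, file.path(out, "oocyte_metadata.tsv"))
    write_metadata(gran$records, file.path(out, "granulosa_metadata.tsv"))
    jsonlite::write_json(ooc$truth["retarded"],
                         file.path(out, "oocyte_truth.json"), auto_unbox = TRUE)
    summary$stages$simulate <- list(n_oocytes = ncol(gene_counts(ooc$counts)),
                                    n_granulosa = ncol(gene_counts(gran$counts)))
  } else if (!is.null(cfg$io$counts)) {
    ooc <- list(counts = read_count_matrix(cfg$io$counts),
                records = read_metadata(cfg$io$metadata))
  }
  if (isTRUE(cfg$stages$qc)) {
    if (is.null(ooc)) stop("qc stage requires simulated or loaded data")
    plate <- gen_ct_plate(n = scfg$ct_plate_size, base_ct = scfg$ct_base,
                          sd = scfg$ct_sd, n_failures = 4L,
                          failure_shift = scfg$ct_failure_shift,
                          seed = cfg$seed)
    gate <- gate_amplification(plate$ct, alpha = th$grubbs_alpha)
    write_tsv_stable(gate$trace, file.path(out, "ct_gate_trace.tsv"))
    qc <- filter_cells(ooc$records, ooc$counts, th)
    write_tsv_stable(qc$cells, file.path(out, "qc_cells.tsv"))
    summary$stages$qc <- list(n_wells_failed = sum(!gate$pass),
                              n_cells_failed = sum(!qc$cells$pass))
  }
  expr_ooc <- expr_gran <- NULL
  if (isTRUE(cfg$stages$quantify)) {
    if (is.null(ooc)) stop("missing upstream stage output for quantify")
    expr_ooc <- to_rpm(ooc$counts)
    cm_model <- fit_copy_model(spike_counts(ooc$counts)[, 1],
                               ercc_reference(scfg$n_spikes))
    jsonlite::write_json(unclass(cm_model)[c("slope", "intercept", "n_used")],
                         file.path(out, "copy_model.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(gran)) expr_gran <- to_rpm(gran$counts)
    summary$stages$quantify <- list(
      denominator = expr_ooc$denominator_mode,
      copy_slope = cm_model$slope,
      mean_detectable = mean(count_detectable_genes(ooc$counts)))
  }
  if (isTRUE(cfg$stages$bias)) {
    fs <- gen_fresh_vs_section(scfg)
    rep <- section_bias_report(fs$fresh, fs$section,
                               detect_alpha = th$bias_alpha,
                               bias_min_diff = th$bias_min_diff,
                               bias_alpha = th$bias_alpha)
    write_tsv_stable(rep, file.path(out, "bias_report.tsv"))
    write_tsv_stable(stratify_by_rank(rep, 10L),
                     file.path(out, "bias_by_rank.tsv"))
    summary$stages$bias <- list(n_detect_error = sum(rep$detect_error),
                                n_bias = sum(rep$bias != ""))
  }
  if (isTRUE(cfg$stages$model)) {
    if (is.null(expr_ooc)) stop("missing upstream stage output for model")
    pca <- fit_pca(expr_ooc$log2, min_log2 = th$log2_filter)
    sm <- fit_size_model(pca, ooc$records$diameter_um, grid = grid,
                         deviation_cut = th$deviation_um)
    mr <- match_oocytes(expr_ooc$log2, ooc$records$diameter_um, sm)
    write_tsv_stable(mr, file.path(out, "match_result.tsv"))
    jsonlite::write_json(list(coef = sm$coef, grid = sm$grid,
                              excluded = sm$excluded),
                         file.path(out, "size_model.json"), digits = NA)
    summary$stages$model <- list(n_analyzed = nrow(mr),
                                 n_deviant = sum(mr$deviant),
                                 n_retarded = sum(mr$retarded))
  }
  if (isTRUE(cfg$stages$deg)) {
    if (is.null(expr_gran)) stop("missing upstream stage output for deg")
    dr <- two_group_deg(expr_gran$log2, gran$records$position,
                        diff_cut = th$deg_diff, floor_log2 = th$log2_filter,
                        alpha = th$deg_alpha, q_cut = th$deg_q)
    write_tsv_stable(dr, file.path(out, "deg_result.tsv"))
    summary$stages$deg <- list(n_tested = nrow(dr), n_pass = sum(dr$pass))
  }
  if (isTRUE(cfg$stages$junctions)) {
    ex <- gen_exon_table(seed = cfg$seed)
    tmm <- tmm_factors(ex$counts)
    vals <- tmm_values(ex$counts, tmm)
    mask <- tmm_detectable(vals$values, cut = th$tmm_detect)
    rates <- exon_detection_rates(mask[ex$model$exon_id, , drop = FALSE],
                                  ex$model)
    write_tsv_stable(rates, file.path(out, "exon_rates.tsv"))
    write_tsv_stable(rate_by_exon_count(rates),
                     file.path(out, "exon_rates_by_count.tsv"))
    summary$stages$junctions <- list(mean_rate = mean(rates$rate))
  }
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Command-line entry point
#'
#' Subcommands `simulate`, `qc`, `quantify`, `bias`, `model`, `deg`,
#' `junctions` and `run-all`, each accepting `--config <yaml>`,
#' `--seed <int>` and `--out <dir>`. A subcommand enables its stage
#' plus required upstream stages.
#'
#' @param args character vector (defaults to the command line).
#' @return exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: lcmtx <simulate|qc|quantify|bias|model|deg|junctions|run-all> ",
            "[--config FILE] [--seed N] [--out DIR]")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- list(config = NULL, seed = NULL, out = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt)) stop("unknown option: ", args[i])
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  cfg <- if (!is.null(opt$config)) read_config(opt$config) else pipeline_config()
  if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
  if (!is.null(opt$out)) cfg$io$out_dir <- opt$out
  stage_sets <- list(
    simulate = "simulate",
    qc = c("simulate", "qc"),
    quantify = c("simulate", "quantify"),
    bias = c("simulate", "bias"),
    model = c("simulate", "quantify", "model"),
    deg = c("simulate", "quantify", "deg"),
    junctions = "junctions",
    `run-all` = c("simulate", "qc", "quantify", "bias", "model", "deg",
                  "junctions"))
  if (!cmd %in% names(stage_sets)) stop("unknown subcommand: ", cmd)
  for (s in names(cfg$stages)) cfg$stages[[s]] <- s %in% stage_sets[[cmd]]
  run_pipeline(cfg)
  invisible(0L)
}
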