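#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one place, with
#' the study protocol as defaults: the cohort conditions
#' ([cohort_config()]), the sweep ([sweep_config()]: six regularization
#' weights, 300 epochs, checkpoints every 10), high-weight selection
#' size `K = 2000`, differential threshold 0.3, resampling with 15
#' samples and 100 replicates, SD bins of width 0.05 on `[0, 0.5]`
#' with high-SD cut 0.10, and filter thresholds MAF 0.05 / detection p
#' 0.05.
#'
#' @param cohort A [cohort_config()].
#' @param sweep A [sweep_config()].
#' @param K High-weight selection size.
#' @param dmr_threshold Beta-difference cut for differential sites.
#' @param n_resample,reps Resampling draw size and replicate count.
#' @param sd_breaks,high_sd_threshold SD histogram bins and cut.
#' @param maf_threshold,detp_threshold Probe filter cuts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            sweep = sweep_config(),
                            K = 2000, dmr_threshold = 0.3,
                            n_resample = 15, reps = 100,
                            sd_breaks = seq(0, 0.5, by = 0.05),
                            high_sd_threshold = 0.10,
                            maf_threshold = 0.05, detp_threshold = 0.05) {
  structure(list(cohort = cohort, sweep = sweep, K = K,
                 dmr_threshold = dmr_threshold, n_resample = n_resample,
                 reps = reps, sd_breaks = sd_breaks,
                 high_sd_threshold = high_sd_threshold,
                 maf_threshold = maf_threshold,
                 detp_threshold = detp_threshold),
            class = "pipeline_config")
}

#' Run the end-to-end analysis on a synthetic cohort
#'
#' Chains simulate, filter, train (sweep), evaluate, weight mining,
#' signature extraction and variability statistics, writing every stage
#' result as tab-separated text under `outdir` together with a manifest
#' of MD5 digests; reruns with the same config and seed reproduce the
#' digests.
#'
#' @param outdir Run directory (created).
#' @param config A [pipeline_config()].
#' @param seed Integer master seed for the whole run.
#' @return Invisibly, a list with the in-memory stage results:
#'   `cohort`, `filtered`, `records`, `optimal`, `pooled_cm`,
#'   `metrics`, `selections`, `signature`, `variability`, `manifest`.
#' @export
run_pipeline <- function(outdir, config = pipeline_config(), seed = 1L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)

  ## simulate
  cohort <- generate_cohort(config$cohort, seed = derive_seed(seed, 1L))
  write_beta_matrix(cohort$beta, file.path(outdir, "beta.tsv"))
  write_sample_sheet(cohort$sheet, file.path(outdir, "sample_sheet.tsv"))
  write_annotation(cohort$annotation, file.path(outdir, "annotation.tsv"))
  utils::write.table(cohort$truth, file.path(outdir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## filter
  filtered <- filter_probes(cohort$beta, cohort$annotation, cohort$detp,
                            maf_threshold = config$maf_threshold,
                            detp_threshold = config$detp_threshold)

  ## train: the cross-validation sweep
  sweep_cfg <- config$sweep
  sweep_cfg$master_seed <- derive_seed(seed, 2L)
  records <- run_sweep(filtered, cohort$sheet, sweep_cfg,
                       checkpoint_dir = file.path(outdir, "checkpoints"))
  records_out <- records
  ## manifest digests must not depend on the run directory location
  records_out$checkpoint <- basename(records_out$checkpoint)
  utils::write.table(records_out, file.path(outdir, "sweep_records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## evaluate at the optimum
  optimal <- select_optimal(records)
  pooled_cm <- pooled_confusion(records, filtered, cohort$sheet,
                                optimal$epoch, optimal$r)
  metrics <- metrics_report(pooled_cm)
  utils::write.table(
    data.frame(key = names(metrics), value = unlist(metrics)),
    file.path(outdir, "metrics_report.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  ## weights and signature
  models <- models_at(records, optimal$epoch, optimal$r)
  selections <- lapply(seq_along(models), function(i)
    select_high_weight(extract_weight_table(models[[i]]), K = config$K,
                       series_id = i))
  signature <- common_sites(selections)
  sig_df <- rbind(
    data.frame(probe_id = signature$esc_pos_ipsc_neg,
               set = "esc_pos_ipsc_neg", stringsAsFactors = FALSE),
    data.frame(probe_id = signature$ipsc_pos_esc_neg,
               set = "ipsc_pos_esc_neg", stringsAsFactors = FALSE))
  utils::write.table(sig_df, file.path(outdir, "signature.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## variability statistics
  sheet <- cohort$sheet
  esc <- sheet$sample_id[sheet$cell_type == "ESC"]
  ipsc <- sheet$sample_id[sheet$cell_type == "iPSC"]
  n <- min(config$n_resample, length(esc), length(ipsc))
  dmr <- resampled_dmr_mean(filtered, esc, ipsc, n = n,
                            reps = config$reps,
                            threshold = config$dmr_threshold,
                            seed = derive_seed(seed, 3L))
  sd_esc <- sd_range_histogram(filtered, esc, n = n, reps = config$reps,
                               breaks = config$sd_breaks,
                               high_sd_threshold = config$high_sd_threshold,
                               seed = derive_seed(seed, 4L))
  sd_ipsc <- sd_range_histogram(filtered, ipsc, n = n, reps = config$reps,
                                breaks = config$sd_breaks,
                                high_sd_threshold = config$high_sd_threshold,
                                seed = derive_seed(seed, 5L))
  variability <- list(dmr_esc_ipsc = dmr, sd_esc = sd_esc,
                      sd_ipsc = sd_ipsc)
  utils::write.table(
    data.frame(statistic = c("resampled_dmr_mean_esc_ipsc",
                             "high_sd_mean_count_esc",
                             "high_sd_mean_count_ipsc"),
               mean = c(dmr$mean, sd_esc$high_sd_mean_count,
                        sd_ipsc$high_sd_mean_count),
               sem = c(dmr$sem, sd_esc$high_sd_sem, sd_ipsc$high_sd_sem)),
    file.path(outdir, "variability_summary.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  ## manifest
  files <- c("beta.tsv", "sample_sheet.tsv", "annotation.tsv", "truth.tsv",
             "sweep_records.tsv", "metrics_report.tsv", "signature.tsv",
             "variability_summary.tsv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(outdir, files))),
    stringsAsFactors = FALSE)
  manifest_path <- file.path(outdir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed,
         version = as.character(utils::packageVersion("methylarow")),
         K = config$K, dmr_threshold = config$dmr_threshold,
         n_resample = config$n_resample, reps = config$reps,
         reg_weights = config$sweep$reg_weights,
         epochs = config$sweep$epochs,
         checkpoint_every = config$sweep$checkpoint_every),
    file.path(outdir, "config_echo.json"), auto_unbox = TRUE)

  invisible(list(cohort = cohort, filtered = filtered, records = records,
                 optimal = optimal, pooled_cm = pooled_cm,
                 metrics = metrics, selections = selections,
                 signature = signature, variability = variability,
                 manifest = manifest))
}
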