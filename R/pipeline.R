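#' Pipeline configuration
#'
#' Bundles the stage configurations for an end-to-end simulate-and-analyse
#' run. All randomness derives from `seed` through fixed per-stage offsets,
#' so stages are individually reproducible.
#'
#' @param out_dir Output directory for the report bundle.
#' @param seed Master seed.
#' @param sim A [sim_config()]; its seed is overridden by `seed`.
#' @param metrics A [metrics_config()].
#' @param hunc A [hunc_config()].
#' @param scoring An [align_scoring()].
#' @param n_hunc,n_decoys_fpkm,n_decoys_cov,hunc_width,amplitude Truth
#'   parameters passed to [make_sim_truth()].
#' @param n_extreme Extreme-set size for the association stage (the
#'   full-scale analysis uses 100; scale to the simulated pool).
#' @param n_low_complexity Transcripts given planted low-complexity
#'   segments.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            sim = sim_config(),
                            metrics = metrics_config(),
                            hunc = hunc_config(),
                            scoring = align_scoring(),
                            n_hunc = 4L, n_decoys_fpkm = 1L,
                            n_decoys_cov = 1L, hunc_width = 150L,
                            amplitude = 5, n_extreme = 10L,
                            n_low_complexity = 5L) {
  sim$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 metrics = metrics, hunc = hunc, scoring = scoring,
                 n_hunc = n_hunc, n_decoys_fpkm = n_decoys_fpkm,
                 n_decoys_cov = n_decoys_cov, hunc_width = hunc_width,
                 amplitude = amplitude, n_extreme = n_extreme,
                 n_low_complexity = n_low_complexity),
            class = "pipeline_config")
}

# hash of the scientific configuration; the output location is excluded so
# identical analyses hash identically wherever they are written
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(rapply(cfg, unclass, how = "replace"),
                       tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

run_stage <- function(name, expr) {
  message("INFO [", name, "] start")
  out <- tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  message("INFO [", name, "] done")
  out
}

#' Run the full simulate-and-analyse pipeline
#'
#' Simulate-first mode: generates a synthetic transcriptome and replicated
#' dilution series with ground-truthed anomalies, then runs every analysis
#' stage and writes the report bundle to `config$out_dir`: per-transcript
#' metrics and fold-change summary, hunc and difference region calls (TSV
#' and BED6), sequence features, the association report, the truth record,
#' and a run manifest with the config hash, seed and per-stage counts.
#' Deterministic: identical config and seed give identical bundles.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`transcriptome`,
#'   `series`, `metrics`, `fc_summary`, `hunc`, `diff`, `features`,
#'   `association`, `recovery`, `manifest`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config$sim
  # named substreams: one fixed offset per stage off the master seed
  seeds <- list(transcriptome = config$seed,
                truth = config$seed + 1000L,
                series = config$seed + 2000L,
                refs = config$seed + 3000L)

  tr <- run_stage("simulate", {
    tx <- generate_transcriptome(cfg, n_low_complexity =
                                   config$n_low_complexity)
    truth <- make_sim_truth(tx$models, n_hunc = config$n_hunc,
                            hunc_width = config$hunc_width,
                            amplitude = config$amplitude,
                            n_decoys_fpkm = config$n_decoys_fpkm,
                            n_decoys_cov = config$n_decoys_cov,
                            seed = seeds$truth)
    series_cfg <- cfg
    series_cfg$seed <- seeds$series
    series <- simulate_dilution_experiment(tx$models, truth, series_cfg)
    list(tx = tx, truth = truth, series = series)
  })

  metrics <- run_stage("metrics", {
    lens <- vapply(tr$tx$models, `[[`, 0L, "length")
    fpkm <- compute_fpkm(tr$series$counts[[1L]], lens, cfg$n_fragments)
    coverage_metrics_table(tr$series$replicates[[1L]]$ivt_only, fpkm,
                           config$metrics)
  })
  fc_summary <- fold_change_summary(metrics$fold_change,
                                    config$metrics$fc_thresholds)

  hunc_res <- run_stage("hunc", {
    s1 <- score_dilution_replicate(tr$series, 1L, config$hunc)
    s2 <- score_dilution_replicate(tr$series, 2L, config$hunc)
    m1 <- tr$series$replicates[[1L]]$mouse_only
    m2 <- tr$series$replicates[[2L]]$mouse_only
    calls <- call_hunc_regions(s1, s2, tr$series$mouse_fpkm, m1, m2,
                               config$hunc)
    message("INFO [hunc] cutoffs: rep1=", format(calls$cutoffs[1]),
            " rep2=", format(calls$cutoffs[2]))
    diffs <- difference_regions(s1, s2, calls, tr$series$mouse_fpkm,
                                m1, m2, config$hunc)
    list(calls = calls, diffs = diffs)
  })
  recovery <- score_recovery(hunc_res$calls$regions, tr$truth)

  features <- run_stage("seqfeat", {
    set.seed(seeds$refs)
    # synthetic rRNA-like references (stand-ins for the depletion targets)
    refs <- vapply(c(500L, 120L), function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, "")
    sequence_feature_table(tr$tx$sequences, refs, config$scoring)
  })

  assoc <- run_stage("associate", {
    association_report(metrics, features, metric_cols = c("base_cv", "fpkm"),
                       fpkm_min = config$metrics$proc_min_fpkm,
                       n = config$n_extreme)
  })

  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   n_transcripts = length(tr$tx$models),
                   n_hunc_regions = nrow(hunc_res$calls$regions),
                   n_diff_regions = nrow(hunc_res$diffs$regions),
                   n_dropped = nrow(hunc_res$calls$dropped),
                   hunc_cutoffs = as.list(hunc_res$calls$cutoffs),
                   fc_summary = as.list(fc_summary),
                   recovery_sensitivity = recovery$sensitivity)

  out <- function(f) file.path(config$out_dir, f)
  write_tsv(metrics, out("metrics.tsv"))
  write_tsv(data.frame(threshold = names(fc_summary), count = fc_summary),
            out("fold_change_summary.tsv"))
  write_tsv(hunc_res$calls$regions, out("hunc_regions.tsv"))
  write_tsv(rbind(hunc_res$calls$dropped, hunc_res$diffs$dropped),
            out("dropped_regions.tsv"))
  write_regions_bed(hunc_res$calls$regions, tr$tx$models,
                    out("hunc_regions.bed"))
  write_tsv(hunc_res$diffs$regions, out("difference_regions.tsv"))
  write_tsv(features, out("features.tsv"))
  write_tsv(assoc, out("association.tsv"))
  write_sim_truth(tr$truth, out("truth_hunc.tsv"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(transcriptome = tr$tx, truth = tr$truth,
                 series = tr$series, metrics = metrics,
                 fc_summary = fc_summary, hunc = hunc_res$calls,
                 diff = hunc_res$diffs, features = features,
                 association = assoc, recovery = recovery,
                 manifest = manifest))
}
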