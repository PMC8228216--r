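## End-to-end pipeline: simulate (or read) -> kinematics -> QC -> morphology
## -> statistics -> haplotype network, with a per-island summary table in the
## style of a study's trait-by-island table.

#' Per-island summary table of sperm traits
#'
#' Mean and SD of male means per island for total length, flagellum:head
#' ratio, midpiece length and within-male CV, the among-male CV per island,
#' and (when motility data are present) mean and SD of male mean VCL and of
#' the motile proportion.
#'
#' @param morph_summary per-male morphology table from
#'   [summarize_cohort_morphology()].
#' @param male_summary optional per-male motility table from
#'   [qc_track_set()].
#' @return Data frame, one row per island plus an `All` row; among-male CV in
#'   the `cv_am` column.
#' @export
island_summary_table <- function(morph_summary, male_summary = NULL) {
  one <- function(mo, ms, label) {
    row <- data.frame(
      island = label, n_males_morphology = nrow(mo),
      total_mean = mean(mo$mean_total), total_sd = stats::sd(mo$mean_total),
      fh_mean = mean(mo$mean_fh_ratio), fh_sd = stats::sd(mo$mean_fh_ratio),
      midpiece_mean = mean(mo$mean_midpiece),
      midpiece_sd = stats::sd(mo$mean_midpiece),
      cv_wm_mean = mean(mo$cv_wm), cv_wm_sd = stats::sd(mo$cv_wm),
      cv_am = if (nrow(mo) >= 2L) cohort_cv_am(mo) else NA_real_,
      stringsAsFactors = FALSE)
    if (!is.null(ms) && nrow(ms)) {
      row$n_males_motility <- nrow(ms)
      row$vcl_mean <- mean(ms$mean_vcl, na.rm = TRUE)
      row$vcl_sd <- stats::sd(ms$mean_vcl, na.rm = TRUE)
      row$prop_motile_mean <- mean(ms$proportion_motile)
      row$prop_motile_sd <- stats::sd(ms$proportion_motile)
    } else {
      row$n_males_motility <- 0L
      row$vcl_mean <- row$vcl_sd <- NA_real_
      row$prop_motile_mean <- row$prop_motile_sd <- NA_real_
    }
    row
  }
  isl <- sort(unique(morph_summary$island))
  rows <- lapply(isl, function(i)
    one(morph_summary[morph_summary$island == i, ],
        if (is.null(male_summary)) NULL
        else male_summary[male_summary$island == i, ], i))
  rows <- c(rows, list(one(morph_summary, male_summary, "All")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Either simulates a study from a [simulation_config()] or reads track,
#' morphology and FASTA files, then runs kinematics, the QC cascade,
#' morphology summaries, the statistical models and the haplotype network,
#' and (optionally) writes all report files to `out_dir`. Deterministic
#' given the config: all randomness flows from the config seed.
#'
#' @param sim_config a [simulation_config()], or `NULL` when reading files.
#' @param tracks_csv,morphology_csv,fasta paths, used when `sim_config` is
#'   `NULL`. Any of them may be `NULL` to skip that stream.
#' @param thresholds QC thresholds, see [qc_thresholds()].
#' @param alpha selection threshold for interaction terms.
#' @param levene_center centre for Levene's test, `"median"` or `"mean"`.
#' @param fit_glmm also fit the binomial mixed model (slower); default TRUE.
#' @param out_dir optional output directory for report files.
#' @return List of class `study_report`: `island_table`, `qc` (cell table and
#'   per-male summaries), `morph_summary`, `cv_am`, `models` (speed,
#'   motility_glmm, motility_lm, levene, midpiece, sd_model), `network`,
#'   `files` (paths written).
#' @export
run_pipeline <- function(sim_config = NULL, tracks_csv = NULL,
                         morphology_csv = NULL, fasta = NULL,
                         thresholds = qc_thresholds(), alpha = 0.05,
                         levene_center = "median", fit_glmm = TRUE,
                         out_dir = NULL) {
  frame_rate <- 50
  if (!is.null(sim_config)) {
    stopifnot(inherits(sim_config, "sim_config"))
    study <- simulate_study(sim_config)
    tracks <- study$tracks
    cells <- study$cohort$cells
    measurer <- stats::setNames(study$cohort$males$measurer,
                                study$cohort$males$male_id)
    sequences <- study$haplotypes$sequences
    frame_rate <- sim_config$frame_rate
  } else {
    tracks <- if (!is.null(tracks_csv)) read_tracks(tracks_csv) else NULL
    cells <- if (!is.null(morphology_csv)) read_morphology(morphology_csv)
             else NULL
    measurer <- NULL
    sequences <- if (!is.null(fasta)) read_fasta(fasta) else NULL
  }
  ## kinematics + QC
  qc <- if (!is.null(tracks))
    qc_track_set(tracks, thresholds, frame_rate = frame_rate) else NULL
  ## morphology
  morph <- if (!is.null(cells)) summarize_cohort_morphology(cells) else NULL
  cv_am <- if (!is.null(morph) && nrow(morph) >= 2L) cohort_cv_am(morph)
           else NA_real_
  ## statistics
  models <- list()
  if (!is.null(qc) && !is.null(morph)) {
    ds <- build_analysis_dataset(qc$males, morph)
    models$speed <- tryCatch(fit_speed_model(ds, alpha = alpha),
                             error = function(e) e)
    if (fit_glmm)
      models$motility_glmm <- tryCatch(fit_motility_glmm(ds, alpha = alpha),
                                       error = function(e) e)
    models$motility_lm <- tryCatch(fit_motility_lm_weighted(ds, alpha = alpha),
                                   error = function(e) e)
  }
  if (!is.null(morph) && length(unique(morph$island)) >= 2L) {
    models$levene <- tryCatch(
      levene_among_males(morph$mean_total, morph$island,
                         center = levene_center),
      error = function(e) e)
    models$midpiece <- tryCatch(fit_midpiece_model(cells, alpha = alpha),
                                error = function(e) e)
    mo <- morph
    if (!is.null(measurer)) mo$measurer <- measurer[mo$male_id]
    models$sd_model <- tryCatch(fit_sd_model(mo), error = function(e) e)
  }
  ## haplotype network
  network <- if (!is.null(sequences)) build_haplotype_network(sequences)
             else NULL
  island_table <- if (!is.null(morph))
    island_summary_table(morph, if (is.null(qc)) NULL else qc$males)
    else NULL
  files <- character(0)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    wf <- function(obj, fn, writer) {
      p <- file.path(out_dir, fn); writer(obj, p); p
    }
    if (!is.null(island_table))
      files <- c(files, wf(island_table, "island_summary.csv",
                           function(o, p) utils::write.csv(o, p, row.names = FALSE)))
    if (!is.null(qc)) {
      files <- c(files, wf(qc$cell_table, "qc_cells.tsv",
                           function(o, p) utils::write.table(o, p, sep = "\t",
                             quote = FALSE, row.names = FALSE)))
      msum <- qc$males[, setdiff(names(qc$males), "eligible_vcls")]
      files <- c(files, wf(msum, "male_motility.csv",
                           function(o, p) utils::write.csv(o, p, row.names = FALSE)))
    }
    if (!is.null(morph))
      files <- c(files, wf(morph, "male_morphology.csv",
                           function(o, p) utils::write.csv(o, p, row.names = FALSE)))
    if (!is.null(network))
      files <- c(files, write_network_files(network, out_dir))
    ok_models <- Filter(function(m) inherits(m, "sf_model_result"), models)
    if (length(ok_models)) {
      mj <- lapply(ok_models, function(m)
        list(method = m$method, coefficients = m$coefficients,
             selection_log = m$selection_log, notes = m$notes))
      pj <- file.path(out_dir, "models.json")
      jsonlite::write_json(mj, pj, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
      files <- c(files, pj)
    }
  }
  structure(list(island_table = island_table, qc = qc, morph_summary = morph,
                 cv_am = cv_am, models = models, network = network,
                 files = files), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  if (!is.null(x$island_table)) {
    cat(sprintf("  %d male(s) morphology, among-male CV %.2f%%\n",
                sum(x$island_table$n_males_morphology[
                  x$island_table$island != "All"]), x$cv_am))
    print(x$island_table[, c("island", "n_males_morphology", "total_mean",
                             "total_sd", "vcl_mean", "prop_motile_mean")],
          digits = 4)
  }
  if (!is.null(x$network))
    cat(sprintf("  haplotype network: %d haplotypes, %d edges\n",
                x$network$n_nodes, nrow(x$network$edges)))
  fitted <- names(Filter(function(m) inherits(m, "sf_model_result"),
                         x$models))
  if (length(fitted)) cat("  models fitted:", paste(fitted, collapse = ", "),
                          "\n")
  invisible(x)
}
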