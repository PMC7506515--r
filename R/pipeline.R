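#' Run the full surveillance pipeline end to end
#'
#' simulate (development + validation cohorts) -> extract flags -> fit the
#' triage model on the development cohort's ground-truth labels -> predict
#' validation probabilities -> sample the review queue -> evaluate. Every
#' stage's outputs land under `out_dir`; inputs are never mutated. With the
#' same seed and configuration the run is fully reproducible, including
#' `report.json`.
#'
#' @param out_dir Output directory (created).
#' @param seed Integer seed driving the simulation and queue sampling.
#' @param n_procedures Procedures per cohort.
#' @param sim A [sim_config()] overriding `seed`/`n_procedures` if supplied.
#' @param config A [flag_config()] list.
#' @param threshold Review threshold (default 0.10).
#' @param above_fraction,below_fraction Review-queue sampling fractions
#'   (defaults 0.8 and 0.01).
#' @param firth Fit with Firth penalization.
#' @param write_cohorts Also write the two cohorts' flat files under
#'   `out_dir` (off by default; they are large).
#' @return Invisibly, a list with `model`, `flags_dev`, `flags_val`,
#'   `scores`, `queue`, `metrics` (reviewed-cases confusion metrics),
#'   `metrics_truth` (full-cohort metrics against ground truth), `bands`,
#'   `roc`, and `report` (the content of `report.json`).
#' @export
run_pipeline <- function(out_dir, seed = 1L, n_procedures = 10000L,
                         sim = NULL, config = flag_config(),
                         threshold = 0.10, above_fraction = 0.8,
                         below_fraction = 0.01, firth = FALSE,
                         write_cohorts = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(sim)) {
    sim <- sim_config(n_procedures = n_procedures, seed = seed)
  } else {
    sim$seed <- as.integer(seed)
  }
  message("simulating development and validation cohorts (n = ",
          sim$n_procedures, " each) ...")
  fx <- end_to_end_fixture(sim)
  dev <- fx$development
  val <- fx$validation
  if (write_cohorts) {
    write_cohort(dev$cohort, file.path(out_dir, "development"))
    write_cohort(val$cohort, file.path(out_dir, "validation"))
  }
  message("extracting flags ...")
  flags_dev <- build_flag_vectors(dev$cohort, config)
  flags_val <- build_flag_vectors(val$cohort, config)
  utils::write.csv(flags_dev, file.path(out_dir, "flags_development.csv"),
                   row.names = FALSE)
  utils::write.csv(flags_val, file.path(out_dir, "flags_validation.csv"),
                   row.names = FALSE)
  message("fitting triage model on development labels ...")
  model <- triage_fit(flags_dev, dev$truth, threshold = threshold,
                      firth = firth)
  write_model(model, file.path(out_dir, "model.json"))
  scores <- triage_predict(model, flags_val)
  queue <- triage_queue(scores, threshold = threshold,
                        above_fraction = above_fraction,
                        below_fraction = below_fraction, seed = seed)
  utils::write.csv(queue, file.path(out_dir, "triage.csv"),
                   row.names = FALSE)
  # evaluation over the sampled review queue (partial verification, as in
  # practice) and against full ground truth (the synthetic luxury)
  reviewed_labels <- val$truth
  reviewed_labels$reviewed <- queue$selected_for_review[
    match(reviewed_labels$procedure_id, queue$procedure_id)]
  metrics <- confusion_metrics(reviewed_labels, scores, threshold)
  metrics_truth <- confusion_metrics(val$truth, scores, threshold)
  bands <- band_table(scores, reviewed_labels)
  roc <- if (any(val$truth$infection) && !all(val$truth$infection)) {
    roc_auc(scores$probability, val$truth$infection)
  } else {
    # a single-class validation cohort (possible at very small n) leaves
    # the ROC undefined
    list(auc = NA_real_,
         points = data.frame(threshold = numeric(0),
                             sensitivity = numeric(0),
                             specificity = numeric(0), fpr = numeric(0)))
  }
  utils::write.csv(bands, file.path(out_dir, "band_table.csv"),
                   row.names = FALSE)
  utils::write.csv(roc$points, file.path(out_dir, "roc.csv"),
                   row.names = FALSE)
  metrics_df <- do.call(rbind, lapply(c("ppv", "sensitivity", "specificity"),
                                      function(m) {
    data.frame(metric = m, estimate = metrics[[m]][["est"]],
               ci_lo = metrics[[m]][["lo"]], ci_hi = metrics[[m]][["hi"]])
  }))
  utils::write.csv(metrics_df, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  report <- list(
    seed = seed, n_procedures = sim$n_procedures, threshold = threshold,
    development = list(
      n_infections = sum(dev$truth$infection),
      c_statistic = model$diagnostics$c_statistic,
      converged = model$diagnostics$converged),
    validation = list(
      n_infections = sum(val$truth$infection),
      n_above_threshold = sum(queue$above_threshold),
      n_reviewed = sum(queue$selected_for_review),
      auc = roc$auc,
      reviewed = list(counts = as.list(metrics$counts),
                      ppv = metrics$ppv[["est"]],
                      sensitivity = metrics$sensitivity[["est"]],
                      specificity = metrics$specificity[["est"]]),
      ground_truth = list(counts = as.list(metrics_truth$counts),
                          ppv = metrics_truth$ppv[["est"]],
                          sensitivity = metrics_truth$sensitivity[["est"]],
                          specificity = metrics_truth$specificity[["est"]]))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(model = model, flags_dev = flags_dev,
                 flags_val = flags_val, scores = scores, queue = queue,
                 metrics = metrics, metrics_truth = metrics_truth,
                 bands = bands, roc = roc, report = report))
}
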