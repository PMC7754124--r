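#' Run the whole analysis end to end
#'
#' Composes the full workflow: (optionally) simulate a cohort, preprocess
#' acquisitions into the TIC-normalized aligned feature matrix, fit the four
#' PLS-DA separation diagnostics (HCC vs non-tumour, MFCCC vs non-tumour,
#' HCC vs MFCCC, and non-tumour HCC-arm vs non-tumour MFCCC-arm), then run
#' SVM and RF under patient-grouped K-fold cross-validation for the three
#' classification tasks and derive fragment- and sample-level confusion
#' summaries with majority-vote judgements.
#'
#' @param config A [pesi_config()].
#' @param sim A [sim_config()] used when no input data are supplied.
#' @param manifest,acquisitions Optional real inputs: a [pesi_manifest()] and
#'   a list of acquisitions (objects, closures or scan-table paths) in
#'   manifest order.  When `NULL`, a cohort is simulated from `sim`.
#' @param algos Classifiers to run (default both).
#' @param tasks Tasks to run (default all three).
#' @param output_path Optional path for a machine-readable JSON report.
#' @return An object of class `pesi_report`: the resolved configuration and
#'   seed, fragment counts per task, PLS-DA fits, and per task x algorithm
#'   the prediction table, fragment confusion, judgements and sample
#'   confusion.
#' @export
run_end_to_end <- function(config = pesi_config(), sim = sim_config(),
                           manifest = NULL, acquisitions = NULL,
                           algos = c("svm", "rf"),
                           tasks = c("hcc_vs_nt", "mfccc_vs_nt",
                                     "three_class"),
                           output_path = NULL) {
  if (is.null(acquisitions)) {
    cohort <- simulate_cohort(sim, lazy = TRUE)
    manifest <- cohort$manifest
    acquisitions <- cohort$acquisitions
  } else if (is.null(manifest)) {
    stop("acquisitions supplied without a manifest")
  }
  fm <- preprocess_cohort(acquisitions, config)

  meta <- fm$meta
  panel <- function(rows, labels) plsda(fm$x[rows, , drop = FALSE],
                                        labels, ncomp = 2)
  nt <- meta$tissue_label == "NONTUMOUR"
  plsda_fits <- list(
    hcc_vs_nt = panel(task_row_index(meta, "hcc_vs_nt"),
                      meta$tissue_label[task_row_index(meta, "hcc_vs_nt")]),
    mfccc_vs_nt = panel(task_row_index(meta, "mfccc_vs_nt"),
                        meta$tissue_label[task_row_index(meta,
                                                         "mfccc_vs_nt")]),
    hcc_vs_mfccc = panel(which(!nt), meta$tissue_label[!nt]),
    nt_vs_nt = panel(which(nt), meta$cohort[nt]))

  folds <- assign_folds(manifest, config$k_folds, config$seed)
  results <- list()
  for (task in tasks) for (algo in algos) {
    preds <- crossval(fm, folds, algo, task, config)
    judgements <- majority_vote(preds, config$vote_threshold_rule)
    results[[paste(task, algo, sep = ".")]] <- list(
      task = task, algo = algo, predictions = preds,
      fragment_confusion = fragment_confusion(preds, task),
      judgements = judgements,
      sample_confusion = sample_confusion(judgements, task))
  }
  report <- structure(list(
    version = as.character(utils::packageVersion("pesiclass")),
    config = config, seed = config$seed,
    n_samples = nrow(manifest),
    n_fragments = vapply(tasks, function(t)
      length(task_row_index(meta, t)), 0L),
    n_bins = ncol(fm$x),
    features = fm, plsda = plsda_fits, results = results),
    class = "pesi_report")
  if (!is.null(output_path)) write_report_json(report, output_path)
  report
}

confusion_as_list <- function(cs) {
  list(task = cs$task, level = cs$level, n_total = cs$n_total,
       n_concordant = cs$n_concordant,
       n_false_positive = cs$n_false_positive,
       n_false_negative = cs$n_false_negative,
       n_misclassified = cs$n_misclassified,
       accuracy = cs$accuracy, sensitivity = cs$sensitivity,
       specificity = cs$specificity,
       per_class_recall = as.list(cs$per_class_recall))
}

#' Write the machine-readable report
#'
#' @param report A [run_end_to_end()] result.
#' @param path Output JSON path.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    version = report$version, seed = report$seed,
    n_samples = report$n_samples,
    n_fragments = as.list(report$n_fragments), n_bins = report$n_bins,
    plsda_explained_x_variance = lapply(report$plsda, function(m)
      m$explained_x_variance),
    results = lapply(report$results, function(r) list(
      task = r$task, algo = r$algo,
      fragment = confusion_as_list(r$fragment_confusion),
      sample = confusion_as_list(r$sample_confusion))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.pesi_report <- function(x, ...) {
  cat(sprintf("PESI-MS classification report (pesiclass %s, seed %d)\n",
              x$version, x$seed))
  cat(sprintf("  %d samples, %d aligned m/z bins; fragments per task: %s\n",
              x$n_samples, x$n_bins,
              paste(names(x$n_fragments), x$n_fragments, sep = "=",
                    collapse = " ")))
  for (r in x$results) {
    fc <- r$fragment_confusion; sc <- r$sample_confusion
    cat(sprintf("\n%s / %s\n", r$task, toupper(r$algo)))
    cat(sprintf("  fragments: %d concordant | %d FP | %d FN | %d misclassified of %d  (accuracy %.1f%%)\n",
                fc$n_concordant, fc$n_false_positive, fc$n_false_negative,
                fc$n_misclassified, fc$n_total, 100 * fc$accuracy))
    cat(sprintf("  samples:   %d concordant of %d  (concordance %.1f%%)\n",
                sc$n_concordant, sc$n_total, 100 * sc$accuracy))
  }
  invisible(x)
}
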