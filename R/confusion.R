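#' Fragment-level confusion summary
#'
#' Applies the four-way error taxonomy to fragment predictions:
#' \emph{concordant} (exact match with the pathologist label),
#' \emph{false positive} (true non-tumour predicted as any tumour class),
#' \emph{false negative} (true tumour predicted non-tumour), and
#' \emph{misclassified} (true HCC predicted MFCCC or vice versa — possible
#' only in the three-class task).  Derived metrics: accuracy (concordant /
#' total), sensitivity (concordant tumour fragments / all tumour fragments),
#' specificity (concordant non-tumour fragments / all non-tumour fragments)
#' and per-class recalls.
#'
#' @param preds A [crossval()] prediction table, or any data frame with
#'   `true_label` and `predicted_label` columns.
#' @param task The task defining the admissible label space (defaults to the
#'   table's `task` attribute).
#' @return An object of class `pesi_confusion`.
#' @export
fragment_confusion <- function(preds, task = attr(preds, "task")) {
  if (is.null(task)) stop("task must be given (or carried by the predictions)")
  space <- task_labels(task)
  bad <- setdiff(c(preds$true_label, preds$predicted_label), space)
  if (length(bad))
    stop("label(s) outside the ", task, " space: ", paste(bad, collapse = ", "))
  confusion_from_pairs(preds$true_label, preds$predicted_label, task,
                       level = "fragment")
}

confusion_from_pairs <- function(true, pred, task, level) {
  is_t <- true %in% TUMOUR_LABELS
  is_pt <- pred %in% TUMOUR_LABELS
  conc <- pred == true
  fp <- !is_t & is_pt
  fn <- is_t & !is_pt
  mis <- is_t & is_pt & !conc
  per_class <- vapply(sort(unique(true)), function(l)
    mean(conc[true == l]), 0)
  structure(list(
    task = task, level = level, n_total = length(true),
    n_concordant = sum(conc), n_false_positive = sum(fp),
    n_false_negative = sum(fn), n_misclassified = sum(mis),
    accuracy = mean(conc),
    sensitivity = if (any(is_t)) mean(conc[is_t]) else NA_real_,
    specificity = if (any(!is_t)) mean(conc[!is_t]) else NA_real_,
    per_class_recall = per_class), class = "pesi_confusion")
}

#' @export
print.pesi_confusion <- function(x, ...) {
  cat(sprintf("%s-level confusion (%s): %d units\n", x$level, x$task,
              x$n_total))
  cat(sprintf("  concordant %d | false positive %d | false negative %d | misclassified %d\n",
              x$n_concordant, x$n_false_positive, x$n_false_negative,
              x$n_misclassified))
  cat(sprintf("  accuracy %.1f%%  sensitivity %.1f%%  specificity %.1f%%\n",
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

vote_threshold <- function(n, rule) {
  if (is.numeric(rule)) as.integer(rule) else ceiling(n / 2)
}

#' Majority-vote specimen judgement
#'
#' The system's per-specimen verdict: a sample is \emph{concordant} when at
#' least `ceiling(n/2)` of its predicted fragments match the pathologist
#' label (5 or more of 10 at the defaults), otherwise \emph{non-concordant}.
#' The sample's predicted label is the modal fragment prediction; on a modal
#' tie it is flagged `indeterminate`.
#'
#' @param preds A [crossval()] prediction table (every sample must have at
#'   least one predicted fragment).
#' @param vote_threshold_rule `"majority"` for the `ceiling(n/2)` rule, or an
#'   integer threshold on the number of correct fragments.
#' @return A data frame of class `pesi_judgements`: one row per sample with
#'   `sample_id`, `patient_id`, `true_label`, `n_fragments`, `n_correct`,
#'   `verdict`, `predicted_sample_label`, `tie_flag`.
#' @export
majority_vote <- function(preds, vote_threshold_rule = "majority") {
  by_sample <- split(seq_len(nrow(preds)), preds$sample_id)
  rows <- lapply(by_sample, function(i) {
    n <- length(i)
    n_correct <- sum(preds$predicted_label[i] == preds$true_label[i])
    tab <- table(preds$predicted_label[i])
    modal <- names(tab)[tab == max(tab)]
    tie <- length(modal) > 1
    data.frame(sample_id = preds$sample_id[i[1]],
               patient_id = preds$patient_id[i[1]],
               true_label = preds$true_label[i[1]],
               n_fragments = n, n_correct = n_correct,
               verdict = if (n_correct >=
                             vote_threshold(n, vote_threshold_rule))
                 "concordant" else "non_concordant",
               predicted_sample_label = if (tie) "indeterminate" else modal,
               tie_flag = tie, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out[order(match(out$sample_id, unique(preds$sample_id))), ],
            class = c("pesi_judgements", "data.frame"),
            task = attr(preds, "task"), algo = attr(preds, "algo"))
}

#' Sample-level confusion summary
#'
#' Counts specimens by the majority-vote verdict: the concordance rate is
#' `concordant samples / total samples`, and sensitivity/specificity are the
#' verdict-concordant fractions of tumour and non-tumour specimens.
#' Non-concordant specimens are categorized by their modal predicted label
#' under the fragment taxonomy; a specimen whose modal label is tied
#' (`indeterminate`) or equal to the truth despite a failed vote is counted
#' as false negative when the truth is tumour and false positive otherwise.
#'
#' @param judgements A [majority_vote()] table.
#' @param task Task (defaults to the table's attribute).
#' @return An object of class `pesi_confusion` with `level = "sample"`.
#' @export
sample_confusion <- function(judgements, task = attr(judgements, "task")) {
  if (is.null(task)) stop("task must be given (or carried by the judgements)")
  true <- judgements$true_label
  pred <- judgements$predicted_sample_label
  conc <- judgements$verdict == "concordant"
  is_t <- true %in% TUMOUR_LABELS
  is_pt <- pred %in% TUMOUR_LABELS
  err <- !conc
  fp <- err & !is_t & is_pt
  fn <- err & is_t & pred == "NONTUMOUR"
  mis <- err & is_t & is_pt & pred != true
  other <- err & !(fp | fn | mis)   # indeterminate, or modal == truth
  fn <- fn | (other & is_t)
  fp <- fp | (other & !is_t)
  per_class <- vapply(sort(unique(true)), function(l)
    mean(conc[true == l]), 0)
  structure(list(
    task = task, level = "sample", n_total = length(true),
    n_concordant = sum(conc), n_false_positive = sum(fp),
    n_false_negative = sum(fn), n_misclassified = sum(mis),
    accuracy = mean(conc),
    sensitivity = if (any(is_t)) mean(conc[is_t]) else NA_real_,
    specificity = if (any(!is_t)) mean(conc[!is_t]) else NA_real_,
    per_class_recall = per_class), class = "pesi_confusion")
}
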