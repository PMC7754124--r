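#' Patient-grouped stratified fold assignment
#'
#' Folds are assigned at the patient level so that all fragments of a patient
#' (hence of a sample) share a fold — the leakage-prevention rule of the
#' analysis.  Patients are shuffled by a seeded RNG within strata (cohort x
#' sample profile) and dealt round-robin, so each fold's class mix
#' approximates the global patient-level mix and fold sizes differ by at most
#' one patient per stratum.
#'
#' @param manifest A [pesi_manifest()].
#' @param k Number of folds (default 10); must not exceed the number of
#'   patients.
#' @param seed Integer seed.
#' @return A named integer vector of class `pesi_folds` mapping `patient_id`
#'   to a fold in 1..k.
#' @export
assign_folds <- function(manifest, k = 10, seed = 1L) {
  validate_manifest(manifest)
  patients <- unique(manifest$patient_id)
  if (k > length(patients))
    stop("k = ", k, " exceeds the number of patients (", length(patients), ")")
  profile <- vapply(patients, function(p) {
    rows <- manifest$patient_id == p
    paste(manifest$cohort[rows][1],
          paste(sort(unique(manifest$tissue_label[rows])), collapse = "+"))
  }, "")
  set.seed(seed)
  fold <- integer(length(patients))
  names(fold) <- patients
  offset <- 0L
  for (s in unique(profile)) {
    idx <- sample(which(profile == s))
    fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
    offset <- (offset + length(idx)) %% k
  }
  structure(fold, class = "pesi_folds", k = k)
}

#' Classification tasks
#'
#' `"hcc_vs_nt"` uses the HCC-cohort rows (labels HCC vs NONTUMOUR),
#' `"mfccc_vs_nt"` the MFCCC-cohort rows, and `"three_class"` all rows with
#' the full three-label space.
#'
#' @param task Task name.
#' @return `task_labels()` returns the task's label space.
#' @export
task_labels <- function(task) {
  switch(match.arg(task, c("hcc_vs_nt", "mfccc_vs_nt", "three_class")),
         hcc_vs_nt = c("HCC", "NONTUMOUR"),
         mfccc_vs_nt = c("MFCCC", "NONTUMOUR"),
         three_class = c("HCC", "MFCCC", "NONTUMOUR"))
}

task_row_index <- function(meta, task) {
  switch(match.arg(task, c("hcc_vs_nt", "mfccc_vs_nt", "three_class")),
         hcc_vs_nt = which(meta$cohort == "HCC_cohort"),
         mfccc_vs_nt = which(meta$cohort == "MFCCC_cohort"),
         three_class = seq_len(nrow(meta)))
}

#' Train a fragment classifier
#'
#' `algo = "svm"` fits an RBF-kernel support vector machine on per-feature
#' standardized inputs (standardization parameters learned on the training
#' rows only; zero-variance features pass through unscaled); the default
#' gamma is `1 / (n_features * var(standardized X))` and cost 1.
#' `algo = "rf"` fits a random forest with 500 trees and square-root feature
#' subsampling, seeded and single-threaded so repeated fits are identical.
#'
#' @param x Numeric training matrix (fragments x bins).
#' @param y Character labels (at least two classes present).
#' @param algo `"svm"` or `"rf"`.
#' @param config A [pesi_config()] supplying hyperparameters.
#' @param seed Integer seed (random forest).
#' @param levels Full label space of the task (kept even if a level is absent
#'   from `y`'s factor coding is not allowed: 2+ classes required).
#' @return An object of class `pesi_classifier` with a `predict()` method
#'   returning character labels.
#' @export
train_classifier <- function(x, y, algo = c("svm", "rf"),
                             config = pesi_config(), seed = config$seed,
                             levels = sort(unique(y))) {
  algo <- match.arg(algo)
  x <- as.matrix(x)
  y <- as.character(y)
  if (length(unique(y)) < 2)
    stop("training data contains a single class (", unique(y),
         "); cannot fit a classifier")
  yf <- factor(y, levels = levels)
  fit <- if (algo == "svm") {
    centre <- colMeans(x)
    spread <- apply(x, 2, sd)
    spread[spread == 0] <- 1
    xs <- sweep(sweep(x, 2, centre), 2, spread, "/")
    v <- var(as.vector(xs))
    gamma <- config$svm_gamma %||% (1 / (ncol(x) * max(v, 1e-12)))
    list(model = e1071::svm(xs, yf, kernel = "radial", cost = config$svm_cost,
                            gamma = gamma, scale = FALSE),
         centre = centre, spread = spread)
  } else {
    set.seed(seed)
    xd <- as.data.frame(x)
    names(xd) <- paste0("bin", seq_len(ncol(x)))
    list(model = ranger::ranger(x = xd, y = yf,
                                num.trees = config$rf_num_trees,
                                mtry = max(1, floor(sqrt(ncol(x)))),
                                seed = seed, num.threads = 1))
  }
  structure(c(fit, list(algo = algo, levels = levels)),
            class = "pesi_classifier")
}

#' @export
predict.pesi_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$algo == "svm") {
    xs <- sweep(sweep(newdata, 2, object$centre), 2, object$spread, "/")
    as.character(predict(object$model, xs))
  } else {
    nd <- as.data.frame(newdata)
    names(nd) <- paste0("bin", seq_len(ncol(newdata)))
    as.character(predict(object$model, data = nd,
                         num.threads = 1)$predictions)
  }
}

#' @export
print.pesi_classifier <- function(x, ...) {
  cat("PESI fragment classifier:", toupper(x$algo), "over labels",
      paste(x$levels, collapse = ", "), "\n")
  invisible(x)
}

#' Patient-grouped K-fold cross-validation of fragment classification
#'
#' For each fold, a classifier is trained on all other folds' fragments and
#' predicts the held-out fold, so every selected fragment is predicted
#' exactly once.  Standardization (SVM) is learned on training rows only.
#' Train/test patient sets are asserted disjoint on every fold.
#'
#' @param fm A TIC-normalized [pesi_features()].
#' @param folds A [assign_folds()] result covering every patient in the task.
#' @param algo `"svm"` or `"rf"`.
#' @param task `"hcc_vs_nt"`, `"mfccc_vs_nt"` or `"three_class"`.
#' @param config A [pesi_config()].
#' @return A data frame of class `pesi_predictions` with one row per
#'   evaluated fragment: `sample_id`, `patient_id`, `fragment_index`,
#'   `true_label`, `predicted_label`, `fold`; attributes `task` and `algo`.
#' @export
crossval <- function(fm, folds, algo = c("svm", "rf"),
                     task = c("hcc_vs_nt", "mfccc_vs_nt", "three_class"),
                     config = pesi_config()) {
  algo <- match.arg(algo)
  task <- match.arg(task)
  validate_features(fm)
  rows <- task_row_index(fm$meta, task)
  meta <- fm$meta[rows, , drop = FALSE]
  x <- fm$x[rows, , drop = FALSE]
  labels <- meta$tissue_label
  bad <- setdiff(labels, task_labels(task))
  if (length(bad))
    stop("task ", task, " selected rows with label(s) outside its space: ",
         paste(bad, collapse = ", "))
  fold_row <- unname(folds[meta$patient_id])
  if (anyNA(fold_row))
    stop("fold assignment missing for patient(s): ",
         paste(unique(meta$patient_id[is.na(fold_row)]), collapse = ", "))
  pred <- character(length(rows))
  for (f in seq_len(attr(folds, "k"))) {
    test <- which(fold_row == f)
    train <- which(fold_row != f)
    if (!length(test))
      stop("empty test fold ", f, " for task ", task)
    if (length(intersect(meta$patient_id[test], meta$patient_id[train])))
      stop("patient leakage detected in fold ", f)
    clf <- train_classifier(x[train, , drop = FALSE], labels[train], algo,
                            config = config,
                            seed = sample_seed(config$seed, f),
                            levels = task_labels(task))
    pred[test] <- predict(clf, x[test, , drop = FALSE])
  }
  out <- data.frame(sample_id = meta$sample_id,
                    patient_id = meta$patient_id,
                    fragment_index = meta$fragment_index,
                    true_label = labels, predicted_label = pred,
                    fold = fold_row, stringsAsFactors = FALSE)
  structure(out, class = c("pesi_predictions", "data.frame"),
            task = task, algo = algo)
}
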