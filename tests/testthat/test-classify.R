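test_that("fold assignment is grouped by patient and balanced", {
  m <- pesi_manifest(paste0("S", 1:10), paste0("P", 1:10),
                     rep(c("HCC", "NONTUMOUR"), 5), "HCC_cohort")
  f <- assign_folds(m, k = 10, seed = 1)
  expect_equal(sort(unname(f)), 1:10)  # one patient per fold

  m <- random_manifest(seed = 4, n = 20)
  f <- assign_folds(m, k = 3, seed = 2)
  expect_true(all(table(f) >= 1))
  # no patient in two folds: f is a function of patient_id by construction
  expect_equal(length(f), length(unique(m$patient_id)))
  expect_error(assign_folds(m, k = 100, seed = 1), "exceeds")
})

test_that("all fragments of a sample share a fold in a simulated cohort", {
  sc <- tiny_sim(seed = 13)
  cohort <- simulate_cohort(sc)
  fm <- preprocess_cohort(cohort$acquisitions, tiny_config())
  folds <- assign_folds(cohort$manifest, k = 3, seed = 5)
  fold_of_row <- unname(folds[fm$meta$patient_id])
  per_sample <- tapply(fold_of_row, fm$meta$sample_id,
                       function(v) length(unique(v)))
  expect_true(all(per_sample == 1))
  # and paired samples of one patient share it too
  per_patient <- tapply(fold_of_row, fm$meta$patient_id,
                        function(v) length(unique(v)))
  expect_true(all(per_patient == 1))
})

test_that("both classifiers separate a linearly separable toy set", {
  set.seed(3)
  x <- rbind(matrix(rnorm(40, 0), 10, 4), matrix(rnorm(40, 6), 10, 4))
  y <- rep(c("HCC", "NONTUMOUR"), each = 10)
  for (algo in c("svm", "rf")) {
    clf <- train_classifier(x, y, algo, tiny_config())
    expect_equal(predict(clf, x), y)
  }
  expect_error(train_classifier(x, rep("HCC", 20), "svm", tiny_config()),
               "single class")
})

test_that("random forest predictions are reproducible under a fixed seed", {
  set.seed(8)
  x <- matrix(rnorm(200), 50, 4)
  y <- rep(c("HCC", "NONTUMOUR"), 25)
  p1 <- predict(train_classifier(x, y, "rf", tiny_config(), seed = 99), x)
  p2 <- predict(train_classifier(x, y, "rf", tiny_config(), seed = 99), x)
  expect_identical(p1, p2)
})

test_that("shuffled labels give chance-level held-out accuracy", {
  set.seed(21)
  accs <- replicate(5, {
    x <- matrix(rnorm(120 * 5), 120, 5)
    y <- sample(rep(c("HCC", "NONTUMOUR"), 60))
    train <- 1:80; test <- 81:120
    clf <- train_classifier(x[train, ], y[train], "rf", tiny_config())
    mean(predict(clf, x[test, ]) == y[test])
  })
  n <- 5 * 40
  half_width <- 2.576 * sqrt(0.25 / n)
  expect_gt(mean(accs), 0.5 - half_width)
  expect_lt(mean(accs), 0.5 + half_width)
})

test_that("cross-validation predicts every fragment once without leakage", {
  sc <- tiny_sim(seed = 14, delta = 2)
  cohort <- simulate_cohort(sc)
  cfg <- tiny_config(seed = 14)
  fm <- preprocess_cohort(cohort$acquisitions, cfg)
  folds <- assign_folds(cohort$manifest, cfg$k_folds, cfg$seed)
  for (task in c("hcc_vs_nt", "mfccc_vs_nt", "three_class")) {
    pr <- crossval(fm, folds, "svm", task, cfg)
    rows <- switch(task, hcc_vs_nt = 8, mfccc_vs_nt = 6, three_class = 14)
    expect_equal(nrow(pr), rows * 10)
    expect_true(all(nzchar(pr$predicted_label)))
    expect_true(all(pr$predicted_label %in% task_labels(task)))
    # every (sample, fragment) appears exactly once
    expect_false(any(duplicated(paste(pr$sample_id, pr$fragment_index))))
  }
  # strong signal: near-perfect recovery even on the tiny cohort
  pr <- crossval(fm, folds, "rf", "hcc_vs_nt", cfg)
  expect_gte(fragment_confusion(pr)$accuracy, 0.95)
  # byte-identical reruns
  pr2 <- crossval(fm, folds, "rf", "hcc_vs_nt", cfg)
  expect_identical(as.data.frame(pr), as.data.frame(pr2))
})

test_that("confusion arithmetic reproduces hand-computed rates", {
  mk <- function(n_t, n_nt, err_t, err_nt, tumour = "HCC") {
    data.frame(
      sample_id = "x", patient_id = "x", fragment_index = 0,
      true_label = c(rep(tumour, n_t), rep("NONTUMOUR", n_nt)),
      predicted_label = c(rep("NONTUMOUR", err_t),
                          rep(tumour, n_t - err_t),
                          rep(tumour, err_nt),
                          rep("NONTUMOUR", n_nt - err_nt)))
  }
  cs <- fragment_confusion(mk(1170, 1050, 262, 110), task = "hcc_vs_nt")
  expect_equal(round(100 * cs$accuracy, 1), 83.2)
  expect_equal(round(100 * cs$sensitivity, 1), 77.6)
  expect_equal(round(100 * cs$specificity, 1), 89.5)
  expect_equal(cs$n_false_negative, 262)  # tumour-side errors
  expect_equal(cs$n_false_positive, 110)
  expect_equal(cs$n_misclassified, 0)
  expect_equal(cs$n_concordant + cs$n_false_positive +
                 cs$n_false_negative + cs$n_misclassified, cs$n_total)

  cs <- fragment_confusion(mk(1170, 1050, 60, 60), task = "hcc_vs_nt")
  expect_equal(round(100 * cs$sensitivity, 1), 94.9)
  expect_equal(round(100 * cs$specificity, 1), 94.3)
  expect_equal(round(100 * cs$accuracy, 1), 94.6)

  cs <- fragment_confusion(mk(500, 460, 25, 10, tumour = "MFCCC"),
                           task = "mfccc_vs_nt")
  expect_equal(round(100 * cs$accuracy, 1), 96.4)
  expect_equal(round(100 * cs$sensitivity, 1), 95.0)
  expect_equal(round(100 * cs$specificity, 1), 97.8)

  perfect <- mk(50, 50, 0, 0)
  cs <- fragment_confusion(perfect, task = "hcc_vs_nt")
  expect_equal(cs$accuracy, 1)
  expect_equal(cs$n_false_positive + cs$n_false_negative +
                 cs$n_misclassified, 0)

  bad <- mk(5, 5, 0, 0)
  bad$predicted_label[1] <- "MFCCC"
  expect_error(fragment_confusion(bad, task = "hcc_vs_nt"), "MFCCC")
})

test_that("three-class confusion separates misclassified from FP/FN", {
  pr <- data.frame(
    sample_id = "x", patient_id = "x", fragment_index = 0,
    true_label = c("HCC", "HCC", "MFCCC", "NONTUMOUR", "NONTUMOUR"),
    predicted_label = c("MFCCC", "NONTUMOUR", "HCC", "HCC", "NONTUMOUR"))
  cs <- fragment_confusion(pr, task = "three_class")
  expect_equal(cs$n_misclassified, 2)
  expect_equal(cs$n_false_negative, 1)
  expect_equal(cs$n_false_positive, 1)
  expect_equal(cs$n_concordant, 1)
  expect_equal(unname(cs$per_class_recall["NONTUMOUR"]), 0.5)
})

test_that("majority vote applies the >= ceiling(n/2) rule", {
  mk_sample <- function(id, n_correct, n = 10, true = "HCC") {
    data.frame(sample_id = id, patient_id = id, fragment_index = 0:(n - 1),
               true_label = true,
               predicted_label = c(rep(true, n_correct),
                                   rep("NONTUMOUR", n - n_correct)))
  }
  j <- majority_vote(rbind(mk_sample("A", 5), mk_sample("B", 4),
                           mk_sample("C", 10)))
  expect_equal(j$verdict[j$sample_id == "A"], "concordant")
  expect_equal(j$verdict[j$sample_id == "B"], "non_concordant")
  expect_equal(j$verdict[j$sample_id == "C"], "concordant")
  # A is a 5/5 modal tie
  expect_true(j$tie_flag[j$sample_id == "A"])
  expect_equal(j$predicted_sample_label[j$sample_id == "A"], "indeterminate")
  expect_equal(j$predicted_sample_label[j$sample_id == "B"], "NONTUMOUR")
})

test_that("vote concordance matches the binomial tail on simulated samples", {
  set.seed(17)
  for (p_err in c(0.2, 0.4)) {
    n_samples <- 10000
    correct <- matrix(runif(n_samples * 10) > p_err, n_samples)
    preds <- data.frame(
      sample_id = rep(seq_len(n_samples), each = 10),
      patient_id = rep(seq_len(n_samples), each = 10),
      fragment_index = rep(0:9, n_samples),
      true_label = "HCC",
      predicted_label = ifelse(t(correct)[seq_len(n_samples * 10)],
                               "HCC", "NONTUMOUR"))
    j <- majority_vote(preds)
    frac <- mean(j$verdict == "concordant")
    expected <- pbinom(4, 10, 1 - p_err, lower.tail = FALSE)
    se <- sqrt(expected * (1 - expected) / n_samples)
    expect_lt(abs(frac - expected), 3 * se)
  }
})

test_that("sample-level confusion reproduces printed concordance rates", {
  mk_j <- function(n, n_bad, true = "HCC", pred_bad = "NONTUMOUR") {
    data.frame(sample_id = paste0("s", seq_len(n)),
               patient_id = paste0("s", seq_len(n)), true_label = true,
               n_fragments = 10,
               n_correct = c(rep(2, n_bad), rep(10, n - n_bad)),
               verdict = c(rep("non_concordant", n_bad),
                           rep("concordant", n - n_bad)),
               predicted_sample_label = c(rep(pred_bad, n_bad),
                                          rep(true, n - n_bad)),
               tie_flag = FALSE)
  }
  cs <- sample_confusion(mk_j(222, 25), task = "hcc_vs_nt")
  expect_equal(round(100 * cs$accuracy, 1), 88.7)
  cs <- sample_confusion(mk_j(96, 1, true = "MFCCC"), task = "mfccc_vs_nt")
  expect_equal(round(100 * cs$accuracy, 1), 99.0)
  expect_equal(cs$n_false_negative, 1)
  cs <- sample_confusion(mk_j(50, 0), task = "hcc_vs_nt")
  expect_equal(cs$accuracy, 1)
  # counts always partition the total
  cs <- sample_confusion(mk_j(30, 7), task = "hcc_vs_nt")
  expect_equal(cs$n_concordant + cs$n_false_positive + cs$n_false_negative +
                 cs$n_misclassified, cs$n_total)
})

test_that("vote concordance beats fragment accuracy when fragments exceed chance", {
  sc <- tiny_sim(seed = 15, delta = 1.2, scan_sd = 0.6)
  cohort <- simulate_cohort(sc)
  cfg <- tiny_config(seed = 15)
  fm <- preprocess_cohort(cohort$acquisitions, cfg)
  folds <- assign_folds(cohort$manifest, cfg$k_folds, cfg$seed)
  pr <- crossval(fm, folds, "svm", "hcc_vs_nt", cfg)
  fc <- fragment_confusion(pr)
  sc2 <- sample_confusion(majority_vote(pr))
  if (fc$accuracy > 0.5) expect_gte(sc2$accuracy, fc$accuracy)
})
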