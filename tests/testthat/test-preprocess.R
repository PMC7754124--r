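test_that("fragment splitting averages the right scans and drops the tail", {
  sc <- tiny_sim(seed = 6)
  acq <- simulate_cohort(sc)$acquisitions[[1]]
  frs <- split_fragments(acq)  # defaults: 12 windows formed, 10 kept
  expect_length(frs, 10)
  expect_equal(vapply(frs, `[[`, 0L, "n_scans_averaged"), rep(10L, 10))
  expect_equal(vapply(frs, `[[`, 0L, "fragment_index"), 0:9)

  # fragment 3 equals the brute-force mean of scans with 30 <= t < 40
  rows <- which(acq$times >= 30 & acq$times < 40)
  expect_equal(frs[[4]]$intensities,
               colMeans(acq$intensities[rows, ]), tolerance = 1e-12)

  # scans partition: every kept scan contributes to exactly one fragment
  counts <- table(floor(acq$times / 10))
  expect_equal(sum(vapply(frs, `[[`, 0L, "n_scans_averaged")),
               sum(counts[as.integer(names(counts)) < 10]))

  # constant acquisition: every fragment equals the constant vector
  v <- runif(length(acq$mz))
  const <- pesi_acquisition(acq$sample, acq$mz, acq$times,
                            matrix(v, length(acq$times), length(acq$mz),
                                   byrow = TRUE))
  frs <- split_fragments(const)
  for (f in frs) expect_equal(f$intensities, v, tolerance = 1e-12)

  # an empty kept window is a named failure
  sparse <- pesi_acquisition(acq$sample, acq$mz, c(5, 25),
                             acq$intensities[1:2, ])
  expect_error(split_fragments(sparse), "window 1")
})

test_that("centroiding finds symmetric peaks and honours thresholds", {
  fr <- bump_fragment(500.0, 1000)
  pl <- centroid_peaks(fr, noise_k = 0, min_rel_intensity = 0)
  expect_equal(nrow(pl), 1)
  expect_lt(abs(pl$mz - 500.0), 0.05)  # within half a grid step

  flat <- list(mz = fr$mz, intensities = rep(7, length(fr$mz)))
  expect_equal(nrow(centroid_peaks(flat)), 0)
  zero <- list(mz = fr$mz, intensities = rep(0, length(fr$mz)))
  expect_equal(nrow(centroid_peaks(zero)), 0)

  # second bump at 10% height is dropped by a 20% relative floor
  two <- bump_fragment(c(500, 505), c(1000, 100))
  expect_equal(nrow(centroid_peaks(two, noise_k = 0,
                                   min_rel_intensity = 0.2)), 1)
  expect_equal(nrow(centroid_peaks(two, noise_k = 0,
                                   min_rel_intensity = 0.05)), 2)
})

test_that("alignment merges within tolerance and splits beyond it", {
  pls <- list(pesi_peaklist(150.10, 50), pesi_peaklist(150.40, 70))
  fm <- align_peaks(pls, tol_da = 0.5)
  expect_equal(ncol(fm$x), 1)
  expect_equal(fm$bin_mz, (150.10 * 50 + 150.40 * 70) / 120)
  expect_equal(fm$x[, 1], c(50, 70))

  pls <- list(pesi_peaklist(c(100.0, 101.0), c(10, 20)))
  fm <- align_peaks(pls, tol_da = 0.5)
  expect_equal(ncol(fm$x), 2)
  expect_equal(fm$x[1, ], c(10, 20))
})

test_that("alignment equals a brute-force single-linkage oracle", {
  for (seed in 1:100) {
    k <- 2 + seed %% 4
    pls <- lapply(seq_len(k), function(i)
      random_peaklist(seed * 100 + i, n = 3 + (seed + i) %% 6))
    fm <- align_peaks(pls, tol_da = 0.5)
    mz <- sort(unlist(lapply(pls, `[[`, "mz")))
    oracle <- single_linkage_bins(mz, h = 0.5)
    expect_equal(ncol(fm$x), max(oracle))
    # identical memberships: oracle bin boundaries at the same sorted gaps
    expect_equal(cumsum(c(1L, as.integer(diff(mz) > 0.5))), oracle)
    # and the gap rule guarantee: consecutive member gaps <= tol
    split_idx <- split(mz, oracle)
    expect_true(all(vapply(split_idx, function(v)
      length(v) == 1 || max(diff(v)) <= 0.5, TRUE)))
  }
})

test_that("a fragment's within-bin peaks are summed, absent bins are zero", {
  pls <- list(pesi_peaklist(c(200.0, 200.3), c(5, 7)),
              pesi_peaklist(300.0, 11))
  fm <- align_peaks(pls, tol_da = 0.5)
  expect_equal(dim(fm$x), c(2L, 2L))
  expect_equal(fm$x[1, ], c(12, 0))
  expect_equal(fm$x[2, ], c(0, 11))
})

test_that("the optional maximum bin width splits chained bins", {
  # chain 100.0, 100.4, 100.8, ... each gap 0.4 <= tol, total width 2.0
  mz <- seq(100, 102, by = 0.4)
  pls <- list(pesi_peaklist(mz, rep(1, length(mz))))
  expect_equal(ncol(align_peaks(pls, tol_da = 0.5)$x), 1)
  fm <- align_peaks(pls, tol_da = 0.5, max_bin_width_da = 1.0)
  expect_gt(ncol(fm$x), 1)
  grp <- apply(abs(outer(mz, fm$bin_mz, `-`)), 1, which.min)
  widths <- tapply(mz, grp, function(v) max(v) - min(v))
  expect_true(all(widths <= 1.0 + 1e-9))
})

test_that("TIC normalization is exact, idempotent and scale-invariant", {
  meta <- data.frame(sample_id = "A", patient_id = "P", fragment_index = 0,
                     tissue_label = "HCC", cohort = "HCC_cohort")
  fm <- pesi_features(matrix(c(2, 2, 4), 1, 3), c(100, 200, 300), meta)
  nn <- tic_normalize(fm)
  expect_equal(nn$x[1, ], c(0.25, 0.25, 0.5))
  expect_equal(tic_normalize(nn)$x, nn$x, tolerance = 1e-12)

  set.seed(20)
  x <- matrix(rexp(60) + 0.01, 10, 6)
  meta10 <- data.frame(sample_id = paste0("S", 1:10), patient_id = "P",
                       fragment_index = 0, tissue_label = "HCC",
                       cohort = "HCC_cohort")
  fm <- pesi_features(x, sort(runif(6, 100, 900)), meta10)
  nn <- tic_normalize(fm)
  expect_true(all(abs(rowSums(nn$x) - 1) <= 1e-9))
  scaled <- fm; scaled$x <- fm$x * rexp(10)  # per-row positive scaling
  expect_equal(tic_normalize(scaled)$x, nn$x, tolerance = 1e-12)

  fm$x[3, ] <- 0
  expect_error(tic_normalize(fm), "S3")
})

test_that("cohort preprocessing yields 10 rows per sample, order-invariantly", {
  sc <- tiny_sim(seed = 8)
  cohort <- simulate_cohort(sc)
  cfg <- tiny_config()
  fm <- preprocess_cohort(cohort$acquisitions, cfg)
  expect_equal(nrow(fm$x), 10 * nrow(cohort$manifest))
  expect_equal(unname(table(fm$meta$sample_id)),
               rep(10L, nrow(cohort$manifest)), ignore_attr = TRUE)
  expect_true(fm$normalized)

  perm <- rev(seq_along(cohort$acquisitions))
  fm2 <- preprocess_cohort(cohort$acquisitions[perm], cfg)
  expect_equal(fm2$bin_mz, fm$bin_mz, tolerance = 1e-12)
  key <- function(f) paste(f$meta$sample_id, f$meta$fragment_index)
  reorder <- match(key(fm), key(fm2))
  expect_equal(fm2$x[reorder, ], fm$x, tolerance = 1e-9)

  one <- preprocess_cohort(cohort$acquisitions[1], cfg)
  expect_equal(nrow(one$x), 10)
})
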