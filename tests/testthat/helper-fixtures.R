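# Shared fixture builders: everything generated in code, desk-scale sizes.

# A small, fast simulation configuration; coarse grid keeps tests quick while
# the 0.5 Da alignment tolerance stays meaningful.
tiny_sim <- function(seed = 1, ...) {
  args <- list(n_patients_hcc = 4, paired_fraction_hcc = 1,
               n_patients_mfccc = 3, paired_fraction_mfccc = 1,
               n_background_peaks = 20, n_discriminative_peaks = 3,
               mz_spacing = 0.5, seed = seed)
  do.call(sim_config, modifyList(args, list(...)))
}

tiny_config <- function(seed = 1, ...) {
  args <- list(k_folds = 3, seed = seed)
  do.call(pesi_config, modifyList(args, list(...)))
}

# A valid random acquisition on a small axis (for I/O round-trips).
random_acquisition <- function(seed = 1, n_scans = 12, n_mz = 25) {
  set.seed(seed)
  pesi_acquisition(
    list(sample_id = "S1", patient_id = "P1", tissue_label = "HCC",
         cohort = "HCC_cohort"),
    mz = sort(runif(n_mz, 50, 1500)),
    times = sort(runif(n_scans, 0, 119.9)),
    intensities = matrix(rexp(n_scans * n_mz, 1 / 50), n_scans, n_mz))
}

random_manifest <- function(seed = 1, n = 8) {
  set.seed(seed)
  pesi_manifest(sample_id = paste0("S", seq_len(n)),
                patient_id = paste0("P", sample(ceiling(n / 2), n,
                                                replace = TRUE)),
                tissue_label = sample(c("HCC", "MFCCC", "NONTUMOUR"), n,
                                      replace = TRUE),
                cohort = sample(c("HCC_cohort", "MFCCC_cohort"), n,
                                replace = TRUE))
}

random_peaklist <- function(seed, n = 8, lo = 100, hi = 200) {
  set.seed(seed)
  mz <- sort(runif(n, lo, hi))
  mz <- mz[c(TRUE, diff(mz) > 1e-6)]
  pesi_peaklist(mz, rexp(length(mz), 1 / 100) + 1)
}

# Brute-force single-linkage binning oracle via hclust (independent of the
# gap-rule implementation).
single_linkage_bins <- function(mz, h) {
  if (length(mz) == 1) return(1L)
  cl <- stats::cutree(stats::hclust(stats::dist(mz), method = "single"),
                      h = h)
  # renumber by ascending m/z so bin ids are comparable
  as.integer(factor(cl, levels = unique(cl[order(mz)])))
}

# Gaussian-bump fragment for centroiding tests.
bump_fragment <- function(centres, heights, sigma = 0.5,
                          mz = seq(480, 520, by = 0.1)) {
  y <- numeric(length(mz))
  for (k in seq_along(centres))
    y <- y + heights[k] * exp(-(mz - centres[k])^2 / (2 * sigma^2))
  list(mz = mz, intensities = y)
}
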