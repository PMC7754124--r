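#' Simulation configuration for synthetic PESI cohorts
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: two study arms (HCC and MFCCC cohorts) in which every patient
#' contributes a tumour sample and a configurable fraction also contribute a
#' matched non-tumour sample sharing the patient random effect; a shared peak
#' library with class-dependent log-fold effects on disjoint peak subsets per
#' contrast; multiplicative log-normal patient and scan noise; an additive
#' Gaussian noise floor; and an exponential total-ion-current decay starting
#' at `t0_s` that emulates late-run needle contamination (the reason the last
#' two 10-second fragments of each acquisition are discarded).
#'
#' Defaults reproduce the study geometry: 117 HCC patients (105 with a paired
#' non-tumour sample) and 50 MFCCC patients (46 paired), i.e. 318 samples and,
#' after fragmentation, 3,180 analysed spectra.
#'
#' @param n_patients_hcc,n_patients_mfccc Patients per arm.
#' @param paired_fraction_hcc,paired_fraction_mfccc Fraction of each arm's
#'   patients contributing a matched non-tumour sample (rounded to a count).
#' @param n_background_peaks Peaks with no class effect.
#' @param n_discriminative_peaks Discriminative peaks per contrast
#'   (HCC-vs-non-tumour, MFCCC-vs-non-tumour, HCC-vs-MFCCC); the three sets
#'   are disjoint.
#' @param delta Log-fold class effect magnitude of discriminative peaks.
#' @param patient_sd Log-scale SD of the patient random effect (shared by a
#'   patient's tumour and non-tumour samples).
#' @param scan_sd Log-scale SD of per-scan multiplicative noise, drawn
#'   independently per peak and per scan (a factor shared across peaks within
#'   a scan would cancel exactly under TIC normalization).
#' @param additive_noise_sd SD of the additive Gaussian noise floor
#'   (truncated at 0), in counts.
#' @param t0_s Onset time of signal decay in seconds (within [0, 120]).
#' @param tau_s Decay time constant in seconds.
#' @param scans_per_second Scan rate; default 1 gives 120 scans per run.
#' @param mz_spacing Grid spacing of the continuum m/z axis in Da.
#' @param peak_width_sigma Gaussian peak width (SD) in Da.
#' @param base_log_range Range of `log` base peak intensities (uniform draw).
#' @param min_peak_spacing_da Minimum spacing between library peak positions.
#' @param seed Integer seed; the whole cohort is a pure function of this
#'   configuration.
#' @return An object of class `pesi_sim_config`.
#' @export
sim_config <- function(n_patients_hcc = 117,
                       paired_fraction_hcc = 105 / 117,
                       n_patients_mfccc = 50,
                       paired_fraction_mfccc = 46 / 50,
                       n_background_peaks = 100,
                       n_discriminative_peaks = 10,
                       delta = 2,
                       patient_sd = 0.5,
                       scan_sd = 0.3,
                       additive_noise_sd = 2,
                       t0_s = 100,
                       tau_s = 20,
                       scans_per_second = 1,
                       mz_spacing = 0.1,
                       peak_width_sigma = 0.2,
                       base_log_range = log(c(200, 5000)),
                       min_peak_spacing_da = 2,
                       seed = 1L) {
  sc <- as.list(environment())
  sc$seed <- as.integer(seed)
  if (any(c(sc$patient_sd, sc$scan_sd, sc$additive_noise_sd) < 0))
    stop("noise standard deviations must be >= 0")
  if (sc$t0_s < 0 || sc$t0_s > ACQ_SECONDS)
    stop("t0_s must lie in [0, ", ACQ_SECONDS, "]")
  if (sc$delta < 0) stop("delta must be >= 0")
  if (sc$tau_s <= 0) stop("tau_s must be > 0")
  if (sc$peak_width_sigma <= 0) stop("peak_width_sigma must be > 0")
  if (sc$mz_spacing <= 0) stop("mz_spacing must be > 0")
  if (min(sc$paired_fraction_hcc, sc$paired_fraction_mfccc) < 0 ||
      max(sc$paired_fraction_hcc, sc$paired_fraction_mfccc) > 1)
    stop("paired fractions must lie in [0, 1]")
  structure(sc, class = "pesi_sim_config")
}

#' Generate the shared peak library of a synthetic cohort
#'
#' Peak positions are drawn without replacement from a grid of candidate m/z
#' locations at least `min_peak_spacing_da` apart (plus a small jitter), so
#' aligned bins downstream are unambiguous.  Each discriminative peak carries
#' a single non-zero class effect of magnitude `delta` (random sign) on the
#' tumour class of its contrast; non-tumour tissue is the baseline (all
#' effects 0).  Deterministic under the configuration seed.
#'
#' @param sc A [sim_config()].
#' @return A data frame of class `pesi_peak_library` with columns `mz`,
#'   `sigma`, `base_log_intensity`, `eff_HCC`, `eff_MFCCC`, `eff_NONTUMOUR`,
#'   `contrast`.
#' @export
make_peak_library <- function(sc) {
  n_disc <- sc$n_discriminative_peaks
  n_total <- sc$n_background_peaks + 3L * n_disc
  lo <- MZ_MIN + 90
  hi <- MZ_MAX - 100
  candidates <- seq(lo, hi, by = sc$min_peak_spacing_da)
  if (n_total > length(candidates))
    stop("requested ", n_total, " peaks but the m/z range hosts at most ",
         length(candidates), " at ", sc$min_peak_spacing_da, " Da spacing")
  set.seed(sc$seed)
  jit_max <- min(0.2 * sc$min_peak_spacing_da, 0.4)
  mz <- sort(sample(candidates, n_total)) +
    runif(n_total, -jit_max, jit_max)
  base <- runif(n_total, sc$base_log_range[1], sc$base_log_range[2])
  contrast <- rep("background", n_total)
  eff_hcc <- numeric(n_total)
  eff_mfccc <- numeric(n_total)
  if (n_disc > 0) {
    disc_idx <- sample(n_total, 3L * n_disc)
    sets <- split(disc_idx, rep(c("hcc_vs_nt", "mfccc_vs_nt",
                                  "hcc_vs_mfccc"), each = n_disc))
    signs <- function(n) sample(c(-1, 1), n, replace = TRUE)
    contrast[sets$hcc_vs_nt] <- "hcc_vs_nt"
    eff_hcc[sets$hcc_vs_nt] <- signs(n_disc) * sc$delta
    contrast[sets$mfccc_vs_nt] <- "mfccc_vs_nt"
    eff_mfccc[sets$mfccc_vs_nt] <- signs(n_disc) * sc$delta
    contrast[sets$hcc_vs_mfccc] <- "hcc_vs_mfccc"
    side <- rep_len(c(TRUE, FALSE), n_disc)  # alternate affected histotype
    eff_hcc[sets$hcc_vs_mfccc[side]] <- signs(sum(side)) * sc$delta
    eff_mfccc[sets$hcc_vs_mfccc[!side]] <- signs(sum(!side)) * sc$delta
  }
  lib <- data.frame(mz = mz, sigma = sc$peak_width_sigma,
                    base_log_intensity = base, eff_HCC = eff_hcc,
                    eff_MFCCC = eff_mfccc, eff_NONTUMOUR = 0,
                    contrast = contrast, stringsAsFactors = FALSE)
  class(lib) <- c("pesi_peak_library", "data.frame")
  lib
}

#' Simulate one 2-minute acquisition
#'
#' Expected intensity of peak j at scan time t for tissue class c is
#' `exp(base_j + effect_cj + u_patient) * d(t) * e`, where `d(t) = 1` before
#' `t0_s` and `exp(-(t - t0_s)/tau_s)` afterwards, and
#' `e ~ LogNormal(0, scan_sd^2)` independently per peak and scan.  Peaks are
#' Gaussian in m/z (SD `peak_width_sigma`) rendered on the grid; an additive
#' Gaussian noise floor (truncated at 0) is applied to the whole grid.
#'
#' @param library A [make_peak_library()] result.
#' @param sample_record One-row manifest record (list with `sample_id`,
#'   `patient_id`, `tissue_label`, `cohort`).
#' @param sc A [sim_config()].
#' @param patient_effect The patient's log-scale random effect `u`.
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used (cohort simulation passes a per-sample seed).
#' @return A [pesi_acquisition()].
#' @export
simulate_acquisition <- function(library, sample_record, sc,
                                 patient_effect = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  label <- sample_record$tissue_label
  eff <- switch(label, HCC = library$eff_HCC, MFCCC = library$eff_MFCCC,
                NONTUMOUR = library$eff_NONTUMOUR,
                stop("unknown tissue_label: ", label))
  mz <- seq(MZ_MIN, MZ_MAX, by = sc$mz_spacing)
  dt <- 1 / sc$scans_per_second
  times <- seq(0, ACQ_SECONDS - dt, by = dt)
  n_scans <- length(times)
  n_peaks <- nrow(library)
  amp <- exp(library$base_log_intensity + eff + patient_effect)
  decay <- ifelse(times < sc$t0_s, 1, exp(-(times - sc$t0_s) / sc$tau_s))
  e <- if (sc$scan_sd > 0)
    matrix(rlnorm(n_scans * n_peaks, 0, sc$scan_sd), n_scans, n_peaks)
  else matrix(1, n_scans, n_peaks)
  ints <- matrix(0, n_scans, length(mz))
  half <- ceiling(4 * sc$peak_width_sigma / sc$mz_spacing)
  for (j in seq_len(n_peaks)) {
    centre <- round((library$mz[j] - MZ_MIN) / sc$mz_spacing) + 1
    idx <- max(1, centre - half):min(length(mz), centre + half)
    shape <- exp(-(mz[idx] - library$mz[j])^2 / (2 * library$sigma[j]^2))
    ints[, idx] <- ints[, idx] + (amp[j] * decay * e[, j]) %o% shape
  }
  if (sc$additive_noise_sd > 0)
    ints <- pmax(ints + matrix(rnorm(length(ints), 0, sc$additive_noise_sd),
                               n_scans), 0)
  pesi_acquisition(sample_record, mz, times, ints)
}

sample_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 10007 + 131 * i) %% 2147483629)
}

#' Simulate a full two-arm cohort
#'
#' Builds the manifest (tumour sample for every patient; matched non-tumour
#' sample, sharing the patient random effect, for the paired fraction) and
#' one acquisition per sample.  Everything is a pure function of the
#' configuration, so identical configurations yield byte-identical cohorts.
#'
#' @param sc A [sim_config()].
#' @param lazy If `TRUE`, `acquisitions` is a list of zero-argument closures
#'   that each generate their acquisition on call, so a study-scale cohort
#'   can be streamed through preprocessing one sample at a time.
#' @return A list with `manifest` (a [pesi_manifest()]), `acquisitions`,
#'   `library` and `patient_effects`.
#' @export
simulate_cohort <- function(sc, lazy = FALSE) {
  library <- make_peak_library(sc)
  arm <- function(prefix, n_pat, frac, tumour_label, cohort) {
    if (n_pat == 0) return(NULL)
    pid <- sprintf("P_%s%03d", prefix, seq_len(n_pat))
    n_paired <- round(frac * n_pat)
    rows <- data.frame(sample_id = paste0("S_", prefix,
                                          sprintf("%03d", seq_len(n_pat)),
                                          "_T"),
                       patient_id = pid, tissue_label = tumour_label,
                       cohort = cohort, stringsAsFactors = FALSE)
    if (n_paired > 0)
      rows <- rbind(rows, data.frame(
        sample_id = paste0("S_", prefix,
                           sprintf("%03d", seq_len(n_paired)), "_N"),
        patient_id = pid[seq_len(n_paired)], tissue_label = "NONTUMOUR",
        cohort = cohort, stringsAsFactors = FALSE))
    rows
  }
  manifest <- rbind(arm("H", sc$n_patients_hcc, sc$paired_fraction_hcc,
                        "HCC", "HCC_cohort"),
                    arm("M", sc$n_patients_mfccc, sc$paired_fraction_mfccc,
                        "MFCCC", "MFCCC_cohort"))
  manifest <- pesi_manifest(manifest$sample_id, manifest$patient_id,
                            manifest$tissue_label, manifest$cohort)
  patients <- unique(manifest$patient_id)
  set.seed(sample_seed(sc$seed, 0))
  u <- stats::setNames(rnorm(length(patients), 0, sc$patient_sd), patients)
  gen_one <- function(i) {
    rec <- as.list(manifest[i, ])
    force(i)
    function() simulate_acquisition(library, rec, sc,
                                    patient_effect = u[[rec$patient_id]],
                                    seed = sample_seed(sc$seed, i))
  }
  acquisitions <- lapply(seq_len(nrow(manifest)), gen_one)
  if (!lazy) acquisitions <- lapply(acquisitions, function(f) f())
  list(manifest = manifest, acquisitions = acquisitions, library = library,
       patient_effects = u)
}
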