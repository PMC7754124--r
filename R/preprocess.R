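#' Split an acquisition into averaged 10-second fragments
#'
#' Scans are assigned to windows by `floor(time_s / fragment_seconds)`; each
#' window's spectrum is the arithmetic mean of its scans.  With the defaults
#' a 120-second run yields 12 windows, of which only the first
#' `n_kept = 10` are returned: the trailing two are discarded because
#' late-run signal decay makes them inconsistent.
#'
#' @param acq A [pesi_acquisition()].
#' @param fragment_seconds Window length in seconds.
#' @param n_exported Number of windows formed.
#' @param n_kept Number of leading windows returned.
#' @return A list of `pesi_fragment` objects (fields `sample`,
#'   `fragment_index` in 0..`n_kept`-1, `mz`, `intensities`,
#'   `n_scans_averaged`).
#' @export
split_fragments <- function(acq, fragment_seconds = 10, n_exported = 12,
                            n_kept = 10) {
  validate_acquisition(acq)
  if (n_kept > n_exported) stop("n_kept must not exceed n_exported")
  window <- floor(acq$times / fragment_seconds)
  out <- vector("list", n_kept)
  for (w in seq_len(n_kept) - 1L) {
    rows <- which(window == w)
    if (!length(rows))
      stop("fragment window ", w, " of sample ", acq$sample$sample_id,
           " contains no scans")
    ints <- if (length(rows) == 1L) acq$intensities[rows, ]
            else colMeans(acq$intensities[rows, , drop = FALSE])
    out[[w + 1L]] <- structure(
      list(sample = acq$sample, fragment_index = w, mz = acq$mz,
           intensities = as.numeric(ints), n_scans_averaged = length(rows)),
      class = "pesi_fragment")
  }
  out
}

#' Peak lists
#'
#' An ordered list of centroided peaks: strictly increasing m/z in
#' [10, 2000] Da, intensities > 0.
#'
#' @param mz,intensity Numeric vectors of equal length.
#' @return A data frame of class `pesi_peaklist`.
#' @export
pesi_peaklist <- function(mz = numeric(0), intensity = numeric(0)) {
  pl <- data.frame(mz = as.numeric(mz), intensity = as.numeric(intensity))
  if (nrow(pl)) {
    if (any(diff(pl$mz) <= 0)) stop("peak m/z must be strictly increasing")
    if (any(pl$mz < MZ_MIN | pl$mz > MZ_MAX))
      stop("peak m/z outside [", MZ_MIN, ", ", MZ_MAX, "] Da")
    if (any(pl$intensity <= 0)) stop("peak intensities must be > 0")
  }
  class(pl) <- c("pesi_peaklist", "data.frame")
  pl
}

#' Centroid a fragment's continuum spectrum
#'
#' A grid point becomes a peak iff it is a strict local maximum, its
#' intensity is at least `noise_k` times the median absolute deviation of the
#' whole fragment spectrum, and at least `min_rel_intensity` times the base
#' peak.  The peak m/z is refined as the intensity-weighted centroid of the
#' three grid points around the maximum; the apex intensity is reported.
#' An all-zero (or featureless) fragment yields an empty peak list.
#'
#' @param fragment A `pesi_fragment` from [split_fragments()], or any list
#'   with numeric `mz` and `intensities`.
#' @param noise_k Noise multiplier (default 5).
#' @param min_rel_intensity Relative-intensity floor (default 0.001).
#' @return A [pesi_peaklist()].
#' @export
centroid_peaks <- function(fragment, noise_k = 5, min_rel_intensity = 0.001) {
  y <- fragment$intensities
  mz <- fragment$mz
  n <- length(y)
  if (n < 3 || max(y) <= 0) return(pesi_peaklist())
  apex <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
  thr <- max(noise_k * mad(y), min_rel_intensity * max(y))
  apex <- apex[y[apex] >= thr]
  if (!length(apex)) return(pesi_peaklist())
  w <- cbind(y[apex - 1L], y[apex], y[apex + 1L])
  m <- cbind(mz[apex - 1L], mz[apex], mz[apex + 1L])
  centroid_mz <- rowSums(w * m) / rowSums(w)
  pesi_peaklist(centroid_mz, y[apex])
}

#' Align peak lists into shared m/z bins
#'
#' All peaks of all fragments are pooled and sorted by m/z; bins are formed
#' by splitting the sorted pool wherever the gap between consecutive m/z
#' values exceeds `tol_da` (single-linkage gap rule, so consecutive member
#' gaps never exceed the tolerance, though chained bins can be wider).  Bin
#' centroids are intensity-weighted mean m/z; a fragment's value in a bin is
#' the sum of its member-peak intensities (conserving TIC), 0 where it has no
#' peak.  Deterministic and independent of input order.
#'
#' @param peaklists A list of [pesi_peaklist()] objects, at least one
#'   non-empty.
#' @param tol_da Alignment tolerance in Da (default 0.5).
#' @param meta Optional metadata data frame, one row per peak list (columns
#'   `sample_id`, `patient_id`, `fragment_index`, `tissue_label`, `cohort`);
#'   placeholders are synthesized when absent.
#' @param max_bin_width_da Optional cap on bin width: bins wider than this
#'   are split at their largest internal gap until they comply.  `Inf`
#'   (default) keeps pure single-linkage semantics.
#' @return An unnormalized [pesi_features()].
#' @export
align_peaks <- function(peaklists, tol_da = 0.5, meta = NULL,
                        max_bin_width_da = Inf) {
  n_pl <- length(peaklists)
  counts <- vapply(peaklists, nrow, 0L)
  if (!n_pl || all(counts == 0)) stop("need at least one non-empty peak list")
  if (is.null(meta))
    meta <- data.frame(sample_id = paste0("pl", seq_len(n_pl)),
                       patient_id = paste0("pl", seq_len(n_pl)),
                       fragment_index = 0L, tissue_label = "NONTUMOUR",
                       cohort = "HCC_cohort", stringsAsFactors = FALSE)
  mz <- unlist(lapply(peaklists, function(p) p$mz), use.names = FALSE)
  intensity <- unlist(lapply(peaklists, function(p) p$intensity),
                      use.names = FALSE)
  src <- rep(seq_len(n_pl), counts)
  ord <- order(mz)
  mz <- mz[ord]; intensity <- intensity[ord]; src <- src[ord]
  bin <- cumsum(c(1L, as.integer(diff(mz) > tol_da)))
  if (is.finite(max_bin_width_da)) {
    repeat {
      width <- tapply(mz, bin, function(v) max(v) - min(v))
      wide <- names(width)[width > max_bin_width_da]
      if (!length(wide)) break
      for (b in wide) {
        idx <- which(bin == as.integer(b))
        g <- which.max(diff(mz[idx]))
        bin[idx[(g + 1):length(idx)]] <- max(bin) + 1L
      }
      bin <- as.integer(factor(rank(tapply(mz, bin, min))[as.character(bin)]))
    }
  }
  bin_ids <- sort(unique(bin))
  bin_mz <- vapply(bin_ids, function(b) {
    i <- bin == b
    sum(mz[i] * intensity[i]) / sum(intensity[i])
  }, 0)
  x <- matrix(0, n_pl, length(bin_ids))
  col <- match(bin, bin_ids)
  for (k in seq_along(mz)) x[src[k], col[k]] <- x[src[k], col[k]] +
    intensity[k]
  pesi_features(x, bin_mz, meta, normalized = FALSE)
}

#' Normalize each fragment spectrum on its total ion current
#'
#' Divides every row by its own sum so rows sum to 1 within 1e-9; idempotent
#' and invariant to per-row scaling.
#'
#' @param fm A [pesi_features()] with strictly positive row sums.
#' @return The normalized `pesi_features` (flag set).
#' @export
tic_normalize <- function(fm) {
  validate_features(fm)
  rs <- rowSums(fm$x)
  bad <- which(rs <= 0)
  if (length(bad))
    stop("zero total ion current in fragment ",
         fm$meta$fragment_index[bad[1]], " of sample ",
         fm$meta$sample_id[bad[1]])
  fm$x <- fm$x / rs
  fm$normalized <- TRUE
  validate_features(fm)
  fm
}

resolve_acquisition <- function(a) {
  if (inherits(a, "pesi_acquisition")) a
  else if (is.function(a)) a()
  else if (is.character(a) && length(a) == 1) read_scan_table(a)
  else stop("cannot interpret acquisition input of class ",
            paste(class(a), collapse = "/"))
}

#' Preprocess a cohort of acquisitions into the analysis feature matrix
#'
#' Composes the full preprocessing chain: split each acquisition into
#' 10-second fragments (discarding the trailing windows), average and
#' centroid each fragment, align all fragments' peaks jointly within the m/z
#' tolerance, and normalize on the TIC.  Each sample contributes exactly
#' `n_fragments_kept` rows (10 at the defaults; a 318-sample cohort yields
#' 3,180 rows).
#'
#' @param acquisitions List whose elements are [pesi_acquisition()] objects,
#'   zero-argument closures returning one (so large cohorts stream one sample
#'   at a time), or scan-table file paths.
#' @param config A [pesi_config()].
#' @return A TIC-normalized [pesi_features()].
#' @export
preprocess_cohort <- function(acquisitions, config = pesi_config()) {
  peaklists <- list()
  meta <- list()
  for (i in seq_along(acquisitions)) {
    acq <- resolve_acquisition(acquisitions[[i]])
    frs <- tryCatch(
      split_fragments(acq, config$fragment_seconds,
                      config$n_fragments_exported, config$n_fragments_kept),
      error = function(e) stop("sample ", acq$sample$sample_id, ": ",
                               conditionMessage(e), call. = FALSE))
    for (fr in frs) {
      peaklists[[length(peaklists) + 1L]] <-
        centroid_peaks(fr, config$noise_k, config$min_rel_intensity)
      meta[[length(meta) + 1L]] <- data.frame(
        sample_id = acq$sample$sample_id, patient_id = acq$sample$patient_id,
        fragment_index = fr$fragment_index,
        tissue_label = acq$sample$tissue_label, cohort = acq$sample$cohort,
        stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta)
  fm <- align_peaks(peaklists, config$align_tol_da, meta,
                    config$max_bin_width_da)
  tic_normalize(fm)
}
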