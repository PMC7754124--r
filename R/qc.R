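#' Calibration reference tables
#'
#' The daily instrument check compares an observed peak list against a
#' reference standard (a polypropylene-glycol mixture in routine use): each
#' reference ion has an expected m/z and an expected intensity relative to
#' the base peak (exactly one entry equals 1).  The monitored ion table is
#' supplied as data, not hardcoded; a synthetic example ships with the
#' package (`system.file("extdata", "ppg_reference_synthetic.csv",
#' package = "pesiclass")`).
#'
#' @param path CSV with columns `expected_mz`, `expected_relative_intensity`.
#' @param mass_tol_da Maximum allowed |mass error| in Da (default 0.5).
#' @param ratio_tol_fraction Maximum allowed relative deviation of the
#'   observed/expected intensity ratio (default 0.3).
#' @return An object of class `pesi_calibration_reference`.
#' @export
read_calibration_reference <- function(path, mass_tol_da = 0.5,
                                       ratio_tol_fraction = 0.3) {
  ref <- read.csv(path)
  calibration_reference(ref$expected_mz, ref$expected_relative_intensity,
                        mass_tol_da, ratio_tol_fraction)
}

#' @rdname read_calibration_reference
#' @param expected_mz Ascending m/z values in Da.
#' @param expected_relative_intensity Fractions of the base peak in (0, 1],
#'   exactly one equal to 1.
#' @export
calibration_reference <- function(expected_mz, expected_relative_intensity,
                                  mass_tol_da = 0.5,
                                  ratio_tol_fraction = 0.3) {
  if (any(diff(expected_mz) <= 0))
    stop("expected_mz must be strictly ascending")
  ri <- expected_relative_intensity
  if (any(ri <= 0 | ri > 1))
    stop("expected relative intensities must lie in (0, 1]")
  if (sum(ri == 1) != 1)
    stop("exactly one reference entry must be the base peak (intensity 1)")
  structure(list(table = data.frame(expected_mz = expected_mz,
                                    expected_relative_intensity = ri),
                 mass_tol_da = mass_tol_da,
                 ratio_tol_fraction = ratio_tol_fraction),
            class = "pesi_calibration_reference")
}

#' Daily instrument calibration check
#'
#' For each reference ion the nearest observed peak is matched (ties broken
#' toward lower m/z); the check passes iff every reference ion has a match
#' within `mass_tol_da` and every matched peak's intensity ratio to the
#' observed base-peak match deviates from the expected ratio by at most
#' `ratio_tol_fraction` (relative).  A pure function of its inputs: failures
#' are report outcomes, not errors.
#'
#' @param peaklist A [pesi_peaklist()] (non-empty).
#' @param reference A [calibration_reference()].
#' @return An object of class `pesi_qc_report`: per-ion table (`matched`,
#'   `mass_error_da`, `observed_ratio`, `ratio_deviation`, `ok`) plus an
#'   overall `pass` flag.
#' @export
check_calibration <- function(peaklist, reference) {
  if (!nrow(peaklist)) stop("empty peak list")
  ref <- reference$table
  nearest <- vapply(ref$expected_mz, function(m) {
    d <- abs(peaklist$mz - m)
    which(d == min(d))[1]   # ties toward lower m/z (first index)
  }, 0L)
  mass_err <- peaklist$mz[nearest] - ref$expected_mz
  matched <- abs(mass_err) <= reference$mass_tol_da
  base_ref <- which(ref$expected_relative_intensity == 1)
  base_int <- peaklist$intensity[nearest[base_ref]]
  obs_ratio <- peaklist$intensity[nearest] / base_int
  ratio_dev <- abs(obs_ratio - ref$expected_relative_intensity) /
    ref$expected_relative_intensity
  ok <- matched & ratio_dev <= reference$ratio_tol_fraction
  # an unmatched base peak invalidates every ratio
  if (!matched[base_ref]) ok[] <- FALSE
  report <- data.frame(expected_mz = ref$expected_mz,
                       matched = matched,
                       observed_mz = ifelse(matched, peaklist$mz[nearest], NA),
                       mass_error_da = ifelse(matched, mass_err, NA),
                       expected_ratio = ref$expected_relative_intensity,
                       observed_ratio = ifelse(matched, obs_ratio, NA),
                       ratio_deviation = ifelse(matched, ratio_dev, NA),
                       ok = ok)
  structure(list(table = report, pass = all(ok),
                 mass_tol_da = reference$mass_tol_da,
                 ratio_tol_fraction = reference$ratio_tol_fraction),
            class = "pesi_qc_report")
}

#' @export
print.pesi_qc_report <- function(x, ...) {
  cat("Instrument calibration check:", if (x$pass) "PASS" else "FAIL", "\n")
  cat(sprintf("  tolerances: |mass error| <= %.3g Da, ratio deviation <= %.0f%%\n",
              x$mass_tol_da, 100 * x$ratio_tol_fraction))
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}
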