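#' Raw PESI acquisitions
#'
#' An acquisition is one sample's 2-minute positive-ion run: an ascending m/z
#' grid within [10, 2000] Da and an ordered set of full-scan continuum spectra
#' (one intensity vector per scan, time-stamped in seconds from run start).
#'
#' @param sample A one-row manifest record (list or data frame row with
#'   `sample_id`, `patient_id`, `tissue_label`, `cohort`).
#' @param mz Strictly increasing numeric m/z axis in Da, within [10, 2000].
#' @param times Strictly increasing scan times in seconds, all in [0, 120).
#' @param intensities Numeric matrix, `length(times)` rows x `length(mz)`
#'   columns, all entries >= 0.
#' @return An object of class `pesi_acquisition`.
#' @export
pesi_acquisition <- function(sample, mz, times, intensities) {
  sample <- as.list(sample)[c("sample_id", "patient_id", "tissue_label",
                              "cohort")]
  intensities <- as.matrix(intensities)
  acq <- structure(list(sample = sample, mz = as.numeric(mz),
                        times = as.numeric(times), intensities = intensities),
                   class = "pesi_acquisition")
  validate_acquisition(acq)
  acq
}

validate_acquisition <- function(acq) {
  if (any(diff(acq$mz) <= 0)) stop("m/z axis must be strictly increasing")
  if (acq$mz[1] < MZ_MIN || acq$mz[length(acq$mz)] > MZ_MAX)
    stop("m/z axis must lie within [", MZ_MIN, ", ", MZ_MAX, "] Da")
  if (length(acq$times) != nrow(acq$intensities))
    stop("scan count mismatch: ", length(acq$times), " times vs ",
         nrow(acq$intensities), " intensity rows")
  if (ncol(acq$intensities) != length(acq$mz))
    stop("axis/row length mismatch: axis has ", length(acq$mz),
         " points, scans have ", ncol(acq$intensities))
  bad <- which(diff(acq$times) <= 0)
  if (length(bad))
    stop("scan times not strictly increasing at scan index ", bad[1] + 1)
  if (any(acq$times < 0) || any(acq$times >= ACQ_SECONDS))
    stop("scan times must lie in [0, ", ACQ_SECONDS, ") seconds")
  neg <- which(rowSums(acq$intensities < 0) > 0)
  if (length(neg))
    stop("negative intensity in scan index ", neg[1])
  invisible(acq)
}

#' @export
print.pesi_acquisition <- function(x, ...) {
  cat(sprintf(
    "PESI acquisition: sample %s (patient %s, %s, %s)\n  %d scans over %.1f s, m/z %.1f-%.1f (%d grid points)\n",
    x$sample$sample_id, x$sample$patient_id, x$sample$tissue_label,
    x$sample$cohort, length(x$times), max(x$times), x$mz[1],
    x$mz[length(x$mz)], length(x$mz)))
  invisible(x)
}

fmt_num <- function(x) sprintf("%.15g", x)

#' Read and write the scan-table text format
#'
#' A plain-text stand-in for a vendor full-scan export, so that fixtures are
#' diffable.  Grammar (tab-separated header lines, then one line per scan):
#' \preformatted{
#' #PESI-SCAN-TABLE<TAB>1
#' #sample_id<TAB><id>
#' #patient_id<TAB><id>
#' #tissue_label<TAB>HCC|MFCCC|NONTUMOUR
#' #cohort<TAB>HCC_cohort|MFCCC_cohort
#' #mz<TAB><space-separated ascending m/z values, Da>
#' <time_s><TAB><space-separated intensities over the m/z axis>
#' }
#'
#' @param path File path.
#' @return `read_scan_table()` returns a [pesi_acquisition()];
#'   `write_scan_table()` invisibly returns `path` and the file round-trips
#'   losslessly within float formatting (15 significant digits).
#' @export
read_scan_table <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#PESI-SCAN-TABLE"))
    stop("not a PESI scan table: ", path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  kv <- strsplit(sub("^#", "", hdr), "\t", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "\t"), "")
  need <- c("sample_id", "patient_id", "tissue_label", "cohort", "mz")
  miss <- setdiff(need, keys)
  if (length(miss))
    stop("scan table missing header field(s): ", paste(miss, collapse = ", "))
  get <- function(k) vals[match(k, keys)]
  mz <- as.numeric(strsplit(get("mz"), " ", fixed = TRUE)[[1]])
  times <- numeric(length(body))
  ints <- matrix(0, length(body), length(mz))
  for (i in seq_along(body)) {
    parts <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("malformed scan line at scan index ", i)
    times[i] <- as.numeric(parts[1])
    row <- as.numeric(strsplit(parts[2], " ", fixed = TRUE)[[1]])
    if (length(row) != length(mz))
      stop("axis/row length mismatch at scan index ", i, ": axis ",
           length(mz), " points, scan ", length(row))
    ints[i, ] <- row
  }
  pesi_acquisition(list(sample_id = get("sample_id"),
                        patient_id = get("patient_id"),
                        tissue_label = get("tissue_label"),
                        cohort = get("cohort")),
                   mz, times, ints)
}

#' @rdname read_scan_table
#' @param acq A `pesi_acquisition`.
#' @export
write_scan_table <- function(acq, path) {
  validate_acquisition(acq)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#PESI-SCAN-TABLE\t1",
    paste0("#sample_id\t", acq$sample$sample_id),
    paste0("#patient_id\t", acq$sample$patient_id),
    paste0("#tissue_label\t", acq$sample$tissue_label),
    paste0("#cohort\t", acq$sample$cohort),
    paste0("#mz\t", paste(fmt_num(acq$mz), collapse = " "))), con)
  for (i in seq_along(acq$times))
    writeLines(paste0(fmt_num(acq$times[i]), "\t",
                      paste(fmt_num(acq$intensities[i, ]), collapse = " ")),
               con)
  invisible(path)
}
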