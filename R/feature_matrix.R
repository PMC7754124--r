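#' Fragment feature matrices
#'
#' The analysis container: one row per 10-second acquisition fragment, one
#' column per aligned m/z bin.  Row metadata carries `sample_id`,
#' `patient_id`, `fragment_index`, `tissue_label` and `cohort`.  Once
#' TIC-normalized every row sums to 1 (within 1e-9) and the `normalized` flag
#' is set.
#'
#' @param x Numeric matrix (fragments x bins), non-negative.
#' @param bin_mz Ascending numeric vector of bin-centroid m/z values.
#' @param meta Data frame with columns `sample_id`, `patient_id`,
#'   `fragment_index`, `tissue_label`, `cohort`; one row per row of `x`.
#' @param normalized Logical: rows claim to sum to 1.
#' @return An object of class `pesi_features`.
#' @export
pesi_features <- function(x, bin_mz, meta, normalized = FALSE) {
  x <- as.matrix(x)
  fm <- structure(list(x = x, bin_mz = as.numeric(bin_mz),
                       meta = as.data.frame(meta), normalized = normalized),
                  class = "pesi_features")
  validate_features(fm)
  fm
}

validate_features <- function(fm) {
  if (ncol(fm$x) != length(fm$bin_mz))
    stop("feature matrix has ", ncol(fm$x), " columns but ",
         length(fm$bin_mz), " bin m/z values")
  if (length(fm$bin_mz) > 1 && any(diff(fm$bin_mz) <= 0))
    stop("bin m/z values must be strictly ascending")
  req <- c("sample_id", "patient_id", "fragment_index", "tissue_label",
           "cohort")
  miss <- setdiff(req, names(fm$meta))
  if (length(miss))
    stop("feature-matrix metadata missing column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(fm$meta) != nrow(fm$x))
    stop("metadata has ", nrow(fm$meta), " rows, matrix has ", nrow(fm$x))
  if (isTRUE(fm$normalized) && nrow(fm$x) > 0) {
    rs <- rowSums(fm$x)
    bad <- which(abs(rs - 1) > 1e-9)
    if (length(bad))
      stop("matrix flagged normalized but row ", bad[1], " (sample ",
           fm$meta$sample_id[bad[1]], ", fragment ",
           fm$meta$fragment_index[bad[1]], ") sums to ", rs[bad[1]])
  }
  invisible(fm)
}

#' @export
print.pesi_features <- function(x, ...) {
  cat(sprintf(
    "PESI feature matrix: %d fragments x %d m/z bins (%s)\n  %d samples, %d patients; labels: %s\n",
    nrow(x$x), ncol(x$x),
    if (isTRUE(x$normalized)) "TIC-normalized" else "raw intensities",
    length(unique(x$meta$sample_id)), length(unique(x$meta$patient_id)),
    paste(names(table(x$meta$tissue_label)),
          table(x$meta$tissue_label), sep = ":", collapse = " ")))
  invisible(x)
}

#' @export
dim.pesi_features <- function(x) dim(x$x)

#' Read and write a feature matrix as TSV
#'
#' Tab-separated text with two comment header lines (`#normalized` flag and
#' `#bin_mz` values), a column header, then one line per fragment: the five
#' metadata columns followed by one intensity per bin.  Reading a file whose
#' `#normalized` flag is true re-checks the row-sum invariant and fails if a
#' row does not sum to 1 within 1e-9.
#'
#' @param fm A `pesi_features` object.
#' @param path File path.
#' @return `read_feature_matrix()` returns a `pesi_features`;
#'   round-trips are lossless within 1e-9.
#' @export
write_feature_matrix <- function(fm, path) {
  validate_features(fm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#normalized\t", if (isTRUE(fm$normalized)) "true" else "false"),
    paste0("#bin_mz\t", paste(fmt_num(fm$bin_mz), collapse = " ")),
    paste(c("sample_id", "patient_id", "fragment_index", "tissue_label",
            "cohort", paste0("bin", seq_along(fm$bin_mz))), collapse = "\t")),
    con)
  for (i in seq_len(nrow(fm$x)))
    writeLines(paste(c(fm$meta$sample_id[i], fm$meta$patient_id[i],
                       fm$meta$fragment_index[i], fm$meta$tissue_label[i],
                       fm$meta$cohort[i], fmt_num(fm$x[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || !startsWith(lines[1], "#normalized"))
    stop("not a feature-matrix TSV: ", path)
  normalized <- identical(strsplit(lines[1], "\t")[[1]][2], "true")
  bz <- strsplit(lines[2], "\t")[[1]][2]
  bin_mz <- if (is.na(bz) || !nzchar(bz)) numeric(0)
            else as.numeric(strsplit(bz, " ", fixed = TRUE)[[1]])
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  n <- length(body)
  x <- matrix(0, n, length(bin_mz))
  meta <- data.frame(sample_id = character(n), patient_id = character(n),
                     fragment_index = integer(n), tissue_label = character(n),
                     cohort = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    parts <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 5 + length(bin_mz))
      stop("malformed feature row ", i, ": expected ", 5 + length(bin_mz),
           " fields, got ", length(parts))
    meta$sample_id[i] <- parts[1]
    meta$patient_id[i] <- parts[2]
    meta$fragment_index[i] <- as.integer(parts[3])
    meta$tissue_label[i] <- parts[4]
    meta$cohort[i] <- parts[5]
    if (length(bin_mz)) x[i, ] <- as.numeric(parts[-(1:5)])
  }
  pesi_features(x, bin_mz, meta, normalized = normalized)
}
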