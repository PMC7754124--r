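#' Sample manifests
#'
#' A manifest lists the specimens of a study: one row per sample with an
#' opaque `sample_id` (unique), the `patient_id` it came from (tumour and
#' matched non-tumour samples share it), its pathologist `tissue_label`
#' (`HCC`, `MFCCC` or `NONTUMOUR`) and its `cohort` (`HCC_cohort` or
#' `MFCCC_cohort`).  The cohort is metadata used only to select rows for a
#' classification task; it is never a model feature.
#'
#' @param sample_id,patient_id Character vectors.
#' @param tissue_label Character vector over `HCC`, `MFCCC`, `NONTUMOUR`.
#' @param cohort Character vector over `HCC_cohort`, `MFCCC_cohort`.
#' @return A `data.frame` of class `pesi_manifest`.
#' @export
pesi_manifest <- function(sample_id, patient_id, tissue_label, cohort) {
  m <- data.frame(sample_id = as.character(sample_id),
                  patient_id = as.character(patient_id),
                  tissue_label = as.character(tissue_label),
                  cohort = as.character(cohort),
                  stringsAsFactors = FALSE)
  validate_manifest(m)
  class(m) <- c("pesi_manifest", "data.frame")
  m
}

validate_manifest <- function(m) {
  req <- c("sample_id", "patient_id", "tissue_label", "cohort")
  miss <- setdiff(req, names(m))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  dup <- m$sample_id[duplicated(m$sample_id)]
  if (length(dup))
    stop("duplicate sample_id in manifest: ",
         paste(unique(dup), collapse = ", "))
  bad <- !m$tissue_label %in% TISSUE_LABELS
  if (any(bad))
    stop("unknown tissue_label '", m$tissue_label[which(bad)[1]],
         "' in manifest row ", which(bad)[1],
         " (sample_id ", m$sample_id[which(bad)[1]], "); valid labels: ",
         paste(TISSUE_LABELS, collapse = ", "))
  badc <- !m$cohort %in% COHORTS
  if (any(badc))
    stop("unknown cohort '", m$cohort[which(badc)[1]], "' in manifest row ",
         which(badc)[1], "; valid cohorts: ", paste(COHORTS, collapse = ", "))
  invisible(m)
}

#' Read or write a sample manifest CSV
#'
#' The file has header columns `sample_id,patient_id,tissue_label,cohort`.
#' Duplicate sample ids and unknown labels are rejected with the offending
#' row named.
#'
#' @param path Path to a CSV file.
#' @return `read_manifest()` returns a `pesi_manifest` data frame in file
#'   order; `write_manifest()` invisibly returns `path`.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  validate_manifest(m)
  class(m) <- c("pesi_manifest", "data.frame")
  m
}

#' @rdname read_manifest
#' @param manifest A `pesi_manifest` (or compatible data frame).
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  write.csv(as.data.frame(manifest)[, c("sample_id", "patient_id",
                                        "tissue_label", "cohort")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
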