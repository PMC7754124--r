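#' Pipeline configuration
#'
#' Bundles the constants of the acquisition-processing and classification
#' pipeline: the 10-second fragmentation of each 2-minute acquisition (12
#' windows formed, the last two discarded), the 0.5 Da alignment tolerance,
#' centroiding thresholds, the number of cross-validation folds (K = 10), the
#' majority-vote rule and classifier hyperparameters.
#'
#' @param fragment_seconds Length of one acquisition fragment in seconds.
#' @param n_fragments_exported Number of fragment windows formed per
#'   acquisition (default 12 for a 120 s run).
#' @param n_fragments_kept Number of leading fragments retained for analysis;
#'   the trailing `n_fragments_exported - n_fragments_kept` windows are
#'   discarded because late-run needle contamination degrades the signal.
#' @param align_tol_da Peak-alignment m/z tolerance in Da: pooled peaks whose
#'   consecutive m/z gap exceeds this are split into separate bins.
#' @param noise_k Centroiding noise multiplier: a local maximum must exceed
#'   `noise_k` times the median absolute deviation of the fragment spectrum.
#' @param min_rel_intensity Centroiding relative-intensity floor (fraction of
#'   the fragment base peak).
#' @param max_bin_width_da Optional upper bound on aligned bin width in Da;
#'   `Inf` (default) keeps pure single-linkage semantics, where chaining can
#'   produce bins wider than the tolerance.
#' @param k_folds Number of cross-validation folds.
#' @param vote_threshold_rule `"majority"` judges a specimen concordant when
#'   at least `ceiling(n/2)` of its fragments are classified correctly (5 of
#'   10 at the defaults); alternatively an integer threshold.
#' @param svm_cost,svm_gamma RBF support-vector-machine hyperparameters;
#'   `svm_gamma = NULL` uses 1 / (n_features * var(standardized X)).
#' @param rf_num_trees Number of random-forest trees.
#' @param seed Integer seed for every stochastic step.
#'
#' @return An object of class `pesi_config` (a validated named list).
#' @seealso [load_config()]
#' @export
pesi_config <- function(fragment_seconds = 10,
                        n_fragments_exported = 12,
                        n_fragments_kept = 10,
                        align_tol_da = 0.5,
                        noise_k = 5,
                        min_rel_intensity = 0.001,
                        max_bin_width_da = Inf,
                        k_folds = 10,
                        vote_threshold_rule = "majority",
                        svm_cost = 1,
                        svm_gamma = NULL,
                        rf_num_trees = 500,
                        seed = 1L) {
  cfg <- list(
    fragment_seconds = fragment_seconds,
    n_fragments_exported = as.integer(n_fragments_exported),
    n_fragments_kept = as.integer(n_fragments_kept),
    align_tol_da = align_tol_da,
    noise_k = noise_k,
    min_rel_intensity = min_rel_intensity,
    max_bin_width_da = max_bin_width_da,
    k_folds = as.integer(k_folds),
    vote_threshold_rule = vote_threshold_rule,
    svm_cost = svm_cost,
    svm_gamma = svm_gamma,
    rf_num_trees = as.integer(rf_num_trees),
    seed = as.integer(seed)
  )
  validate_pesi_config(cfg)
  structure(cfg, class = "pesi_config")
}

validate_pesi_config <- function(cfg) {
  stopifnot(cfg$fragment_seconds > 0)
  if (cfg$n_fragments_kept > cfg$n_fragments_exported)
    stop("n_fragments_kept (", cfg$n_fragments_kept,
         ") must not exceed n_fragments_exported (",
         cfg$n_fragments_exported, ")")
  if (cfg$align_tol_da <= 0) stop("align_tol_da must be > 0")
  if (cfg$k_folds < 2) stop("k_folds must be >= 2, got ", cfg$k_folds)
  if (cfg$noise_k < 0) stop("noise_k must be >= 0")
  if (cfg$min_rel_intensity < 0 || cfg$min_rel_intensity > 1)
    stop("min_rel_intensity must be in [0, 1]")
  if (cfg$rf_num_trees < 1) stop("rf_num_trees must be >= 1")
  invisible(cfg)
}

#' Load a pipeline configuration from a YAML file
#'
#' All keys are optional; absent keys take the defaults of [pesi_config()]
#' (10 s fragments, 12 windows formed / 10 kept, 0.5 Da alignment tolerance,
#' K = 10 folds).  Unknown keys are rejected with the list of valid keys.
#'
#' @param path Path to a YAML file (an empty file yields the defaults).
#' @param quiet Suppress the log line with the fully resolved configuration.
#' @return A `pesi_config` object.
#' @export
load_config <- function(path, quiet = FALSE) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  valid <- names(formals(pesi_config))
  unknown <- setdiff(names(raw), valid)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         "; valid keys are: ", paste(valid, collapse = ", "))
  cfg <- do.call(pesi_config, raw)
  if (!quiet)
    message("resolved configuration: ",
            paste(names(cfg), vapply(cfg, function(x)
              paste(format(x %||% "auto"), collapse = ","), ""),
              sep = "=", collapse = " "))
  cfg
}

#' @export
print.pesi_config <- function(x, ...) {
  cat("PESI pipeline configuration\n")
  for (k in names(x))
    cat(sprintf("  %-22s %s\n", k,
                paste(format(x[[k]] %||% "auto"), collapse = ", ")))
  invisible(x)
}
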