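#' Pipeline run configuration
#'
#' Bundles every tunable of the inference pipeline into a validated list so a
#' run is fully described by (inputs, config). All thresholds are explicit:
#' results are never silently threshold-dependent.
#'
#' @param alpha Elastic-net mixing parameter in (0, 1]; `alpha = 1` is the
#'   lasso, small values approach ridge. Default 0.25, which keeps groups of
#'   miRNAs with heavily overlapping target sets in the model together.
#' @param consensus_fraction Fraction of patients (exclusive lower bound, in
#'   (0.5, 1]) that must share the sign of a miRNA's influence for it to be
#'   called active cohort-wide. Default 0.7.
#' @param validation_fraction Fraction of measured patients (in (0.5, 1])
#'   whose observed miRNA differential-expression sign must agree with the
#'   called influence sign for the call to count as validated. Default 0.7.
#' @param n_permutations Number of random miRNA/sign draws for the
#'   permutation p-value. Default 10000.
#' @param cv_folds Folds for the per-patient cross-validation over genes used
#'   to pick the penalty strength. Default 10.
#' @param seed Integer seed; mandatory, no wall-clock seeding.
#' @param s0 Nonnegative fudge constant added to the normalization
#'   denominator so features with near-zero healthy variance do not explode.
#'   Default 0.1 (on the log2 scale).
#' @param cancer_var_weight Nonnegative weight of the cancer-cohort standard
#'   deviation in the normalization denominator; penalizes features that are
#'   highly variable across patients. Default 1.
#'
#' @return A validated list of class `run_config`.
#' @seealso [read_run_config()], [write_run_config()]
#' @export
#' @examples
#' cfg <- run_config(seed = 7)
#' cfg$alpha
run_config <- function(alpha = 0.25,
                       consensus_fraction = 0.7,
                       validation_fraction = 0.7,
                       n_permutations = 10000L,
                       cv_folds = 10L,
                       seed = 1L,
                       s0 = 0.1,
                       cancer_var_weight = 1) {
  cfg <- list(
    alpha = as.numeric(alpha),
    consensus_fraction = as.numeric(consensus_fraction),
    validation_fraction = as.numeric(validation_fraction),
    n_permutations = as.integer(n_permutations),
    cv_folds = as.integer(cv_folds),
    seed = as.integer(seed),
    s0 = as.numeric(s0),
    cancer_var_weight = as.numeric(cancer_var_weight)
  )
  class(cfg) <- "run_config"
  validate_run_config(cfg)
}

#' Validate a run configuration
#'
#' Checks every field of a [run_config()] against its admissible range and
#' returns the config invisibly unchanged, or aborts naming the offending
#' field.
#'
#' @param cfg A `run_config` (or plain list with the same fields).
#' @return `cfg`, invisibly, with class `run_config`.
#' @export
validate_run_config <- function(cfg) {
  need <- c("alpha", "consensus_fraction", "validation_fraction",
            "n_permutations", "cv_folds", "seed", "s0", "cancer_var_weight")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    abort(paste0("run_config is missing field(s): ",
                 paste(missing, collapse = ", ")))
  }
  chk <- function(ok, what) {
    if (!isTRUE(ok)) abort(paste0("run_config: ", what))
  }
  chk(is.numeric(cfg$alpha) && cfg$alpha > 0 && cfg$alpha <= 1,
      "alpha must lie in (0, 1]")
  chk(cfg$consensus_fraction > 0.5 && cfg$consensus_fraction <= 1,
      "consensus_fraction must lie in (0.5, 1]")
  chk(cfg$validation_fraction > 0.5 && cfg$validation_fraction <= 1,
      "validation_fraction must lie in (0.5, 1]")
  chk(cfg$n_permutations >= 1, "n_permutations must be a positive integer")
  chk(cfg$cv_folds >= 2, "cv_folds must be at least 2")
  chk(is.finite(cfg$seed), "seed must be a finite integer")
  chk(is.numeric(cfg$s0) && cfg$s0 >= 0, "s0 must be nonnegative")
  chk(is.numeric(cfg$cancer_var_weight) && cfg$cancer_var_weight >= 0,
      "cancer_var_weight must be nonnegative")
  class(cfg) <- "run_config"
  invisible(cfg)
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Path to a YAML (`.yml`/`.yaml`) or JSON file holding the
#'   fields of [run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(run_config, raw)
}

#' Write a run configuration
#'
#' Serializes a `run_config` to YAML (default) or JSON; the file round-trips
#' through [read_run_config()] to an identical configuration.
#'
#' @param cfg A validated `run_config`.
#' @param path Output path; format chosen by extension (`.json` for JSON,
#'   anything else YAML).
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  cfg <- validate_run_config(cfg)
  fields <- unclass(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(fields, path)
  }
  invisible(path)
}
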