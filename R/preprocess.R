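#' Log-transform an expression matrix
#'
#' Elementwise base-2 logarithm of a strictly positive linear-scale matrix.
#' The log base only rescales the standardized differences downstream (and is
#' absorbed by `s0`), but base 2 is used throughout so values read as
#' fold-changes.
#'
#' @param expr Numeric matrix of strictly positive values.
#' @return Matrix of the same shape, log2 scale.
#' @export
log_transform <- function(expr) {
  validate_expression(expr, what = "log_transform input", positive = TRUE)
  log2(expr)
}

#' Per-patient normalized differential expression
#'
#' Standardizes each patient's log2 expression against the healthy cohort,
#' SAM-style: for patient p and feature g,
#' \deqn{Y_{gp} = \frac{\log_2 E_{gp} - \mu_H(g)}
#'   {\sigma_H(g) + w\,\sigma_C(g) + s_0}}
#' where \eqn{\mu_H, \sigma_H} are the healthy-cohort mean and standard
#' deviation of log2 expression, \eqn{\sigma_C} the cancer-cohort standard
#' deviation (weight `w` penalizes features that vary wildly between
#' patients), and `s0` a small constant guarding against near-zero
#' denominators. The same transform is applied to gene and to miRNA
#' expression (the latter only for validation).
#'
#' Tumour matrices contaminated by healthy tissue should be purified (e.g.
#' with an external deconvolution tool) before this step; the function
#' consumes whatever tumour matrix it is given.
#'
#' @param tumour,healthy Linear-scale expression matrices with identical
#'   feature id vectors; `healthy` needs at least 2 samples, `tumour` at
#'   least 2 patients (standard deviations use the n-1 denominator).
#' @param s0 Nonnegative constant added to the denominator (log2 units).
#'   Default 0.1.
#' @param cancer_var_weight Nonnegative weight `w` on the cancer-cohort SD.
#'   Default 1.
#' @return An object of class `normalized_de`: list with `values` (features
#'   x patients matrix of standardized differences) and `stats` (tibble of
#'   per-feature `healthy_mean`, `healthy_sd`, `cancer_sd`, plus cohort sizes
#'   `n_healthy`, `n_cancer` as attributes of the object).
#' @export
#' @examples
#' h <- matrix(2, 3, 3, dimnames = list(c("g1", "g2", "g3"), paste0("h", 1:3)))
#' t <- matrix(c(4, 2, 1, 4, 2, 1), 3, 2,
#'             dimnames = list(c("g1", "g2", "g3"), c("p1", "p2")))
#' nd <- normalize_differential(t, h)
#' nd$values
normalize_differential <- function(tumour, healthy, s0 = 0.1,
                                   cancer_var_weight = 1) {
  validate_expression(tumour, "tumour", positive = TRUE)
  validate_expression(healthy, "healthy", positive = TRUE)
  if (!identical(rownames(tumour), rownames(healthy))) {
    abort("normalize_differential: tumour and healthy feature ids differ")
  }
  if (ncol(healthy) < 2) abort("normalize_differential: need >= 2 healthy samples")
  if (ncol(tumour) < 2) abort("normalize_differential: need >= 2 tumour samples")
  if (s0 < 0 || cancer_var_weight < 0) {
    abort("normalize_differential: s0 and cancer_var_weight must be nonnegative")
  }
  lt <- log2(tumour)
  lh <- log2(healthy)
  mu_h <- rowMeans(lh)
  sd_h <- apply(lh, 1, sd)
  sd_c <- apply(lt, 1, sd)
  denom <- sd_h + cancer_var_weight * sd_c + s0
  if (any(denom == 0)) {
    bad <- rownames(tumour)[denom == 0]
    abort(paste0("normalize_differential: zero denominator for feature(s) ",
                 paste(utils::head(bad, 5), collapse = ", "),
                 "; set s0 > 0"))
  }
  y <- (lt - mu_h) / denom
  structure(
    list(
      values = y,
      stats = tibble(feature_id = rownames(tumour), healthy_mean = mu_h,
                     healthy_sd = sd_h, cancer_sd = sd_c)
    ),
    n_healthy = ncol(healthy), n_cancer = ncol(tumour),
    s0 = s0, cancer_var_weight = cancer_var_weight,
    class = "normalized_de"
  )
}

#' @exportS3Method base::print
print.normalized_de <- function(x, ...) {
  cat(sprintf(
    "normalized differential expression: %d features x %d patients\n",
    nrow(x$values), ncol(x$values)))
  cat(sprintf("  healthy n = %d, cancer m = %d, s0 = %g, cancer SD weight = %g\n",
              attr(x, "n_healthy"), attr(x, "n_cancer"),
              attr(x, "s0"), attr(x, "cancer_var_weight")))
  invisible(x)
}

#' @exportS3Method base::as.matrix
as.matrix.normalized_de <- function(x, ...) x$values

#' Tidy a normalized differential-expression object
#'
#' @param x A [normalize_differential()] result.
#' @param ... Unused.
#' @return Long tibble with columns `feature_id`, `patient_id`, `de`.
#' @export
tidy.normalized_de <- function(x, ...) {
  as_tibble(x$values, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "patient_id",
                        values_to = "de")
}

# Accept either a plain features x patients matrix or a normalized_de object.
de_values <- function(x, what = "differential expression") {
  if (inherits(x, "normalized_de")) x <- x$values
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(paste0(what, ": expected a numeric matrix or normalized_de object"))
  }
  if (any(!is.finite(x))) abort(paste0(what, ": non-finite values"))
  x
}
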