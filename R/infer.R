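# Per-patient elastic-net regression of normalized gene differential
# expression on the signed miRNA target matrix. Objective convention (fixed,
# so lambda is comparable across gene-set sizes):
#   1/(2 n_genes) * RSS + lambda * (alpha*||beta||_1 + (1-alpha)/2*||beta||_2^2)
# No intercept (Y is already centered on the healthy cohort) and no column
# standardization (all predictors are -1/0 indicators on a shared scale).

ENET_TOL <- 1e-12
ENET_MAX_IT <- 100000L

#' Elastic-net specification
#'
#' @param alpha Mixing parameter in (0, 1]; 1 = lasso.
#' @param lambda Nonnegative penalty scale.
#' @return List of class `enet_spec`.
#' @export
enet_spec <- function(alpha = 0.25, lambda = 0) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    abort("enet_spec: alpha must lie in (0, 1]")
  }
  if (!is.numeric(lambda) || lambda < 0) {
    abort("enet_spec: lambda must be nonnegative")
  }
  structure(list(alpha = as.numeric(alpha), lambda = as.numeric(lambda)),
            class = "enet_spec")
}

# Gram form of the design: G = N'N (dense p x p), b = N'y, n = n_genes.
gram_parts <- function(n_mat, y = NULL) {
  g <- as.matrix(Matrix::crossprod(n_mat))
  b <- if (is.null(y)) NULL else as.numeric(Matrix::crossprod(n_mat, y))
  list(g = g, b = b, n = nrow(n_mat))
}

# Smallest lambda that zeroes every coefficient under the stated objective.
lambda_max_value <- function(b, n, alpha) {
  max(abs(b)) / (n * alpha)
}

# Standard log-spaced path: n_lambda values from lambda_max down to
# ratio * lambda_max.
lambda_path <- function(lmax, n_lambda = 100L, ratio = 1e-3) {
  exp(seq(log(lmax), log(lmax * ratio), length.out = n_lambda))
}

enet_solve <- function(g, b, n, lambda, alpha,
                       tol = ENET_TOL, max_iter = ENET_MAX_IT) {
  .enet_path_gram(g, b, as.numeric(n), as.numeric(lambda), alpha,
                  tol, as.integer(max_iter))
}

#' Fit one patient's miRNA influences
#'
#' Minimizes
#' \deqn{\frac{1}{2n}\|y - N\beta\|_2^2 +
#'   \lambda\left(\alpha\|\beta\|_1 + \frac{1-\alpha}{2}\|\beta\|_2^2\right)}
#' by coordinate descent on the Gram form, where `y` is the patient's
#' normalized gene differential expression and `N` the signed target matrix
#' (n = number of genes). A positive coefficient means the miRNA's targets
#' are over-expressed in the tumour (miRNA depleted); a negative coefficient
#' means targets are under-expressed (miRNA over-expressed). There is no
#' intercept and predictors are not re-standardized.
#'
#' @param y Numeric vector of one patient's normalized differential
#'   expression, in the same gene order as the rows of `n_mat`.
#' @param n_mat Signed target matrix from [build_influence_matrix()].
#' @param spec An [enet_spec()] (alpha and lambda).
#' @param patient_id Optional label stored on the result.
#' @return Object of class `influence_vector`: tibble with columns
#'   `mirna_id`, `beta`, and attributes `patient_id`, `lambda`, `alpha`.
#' @export
fit_patient <- function(y, n_mat, spec, patient_id = NA_character_) {
  if (length(y) != nrow(n_mat)) {
    abort(sprintf("fit_patient: length(y) = %d but N has %d gene rows",
                  length(y), nrow(n_mat)))
  }
  if (!inherits(spec, "enet_spec")) spec <- do.call(enet_spec, spec)
  gp <- gram_parts(n_mat, y)
  beta <- enet_solve(gp$g, gp$b, gp$n, spec$lambda, spec$alpha)[, 1]
  structure(
    tibble(mirna_id = colnames(n_mat), beta = as.numeric(beta)),
    patient_id = patient_id, lambda = spec$lambda, alpha = spec$alpha,
    class = c("influence_vector", class(tibble()))
  )
}

# Deterministic seeded partition of 1..n into k folds of near-equal size.
fold_assignments <- function(n, k, seed) {
  withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Select the penalty strength by cross-validation over genes
#'
#' Genes are the observations of the per-patient regression, so folds
#' partition genes: a seeded random split into `n_folds` groups, the model is
#' fit on the remaining genes at every lambda of a 100-point log-spaced path
#' (from the smallest all-zero lambda down to 1/1000 of it), and the held-out
#' mean squared error is averaged over folds. The default rule returns the
#' lambda with minimal mean error; `rule = "1se"` returns the largest lambda
#' within one standard error of the minimum, which is sparser but can be
#' unstable when the error curve is noisy.
#'
#' @inheritParams fit_patient
#' @param alpha Elastic-net mixing parameter.
#' @param n_folds Number of folds (>= 2, <= number of genes).
#' @param seed Integer seed for the fold split.
#' @param rule `"min"` (default) or `"1se"`.
#' @param n_lambda,lambda_ratio Path construction controls.
#' @return The selected lambda, with the full CV curve attached as attribute
#'   `cv` (tibble: `lambda`, `mean_error`, `se_error`) and the fold ids as
#'   attribute `folds`.
#' @export
select_lambda_cv <- function(y, n_mat, alpha = 0.25, n_folds = 10L,
                             seed = 1L, rule = c("min", "1se"),
                             n_lambda = 100L, lambda_ratio = 1e-3) {
  rule <- match.arg(rule)
  n_genes <- nrow(n_mat)
  if (length(y) != n_genes) abort("select_lambda_cv: y/N dimension mismatch")
  if (n_folds < 2) abort("select_lambda_cv: n_folds must be >= 2")
  if (n_folds > n_genes) {
    abort("select_lambda_cv: more folds than genes")
  }
  gp <- gram_parts(n_mat, y)
  lmax <- lambda_max_value(gp$b, gp$n, alpha)
  if (lmax == 0) lmax <- .Machine$double.eps # y orthogonal to all columns
  path <- lambda_path(lmax, n_lambda, lambda_ratio)
  folds <- fold_assignments(n_genes, n_folds, seed)

  fold_err <- matrix(NA_real_, n_folds, length(path))
  for (f in seq_len(n_folds)) {
    test <- folds == f
    n_test <- n_mat[test, , drop = FALSE]
    y_test <- y[test]
    g_test <- as.matrix(Matrix::crossprod(n_test))
    b_test <- as.numeric(Matrix::crossprod(n_test, y_test))
    g_train <- gp$g - g_test
    b_train <- gp$b - b_test
    beta <- enet_solve(g_train, b_train, sum(!test), path, alpha)
    # held-out MSE via Gram identities:
    #   ||y_t - X_t b||^2 = y_t'y_t - 2 b_t'b + b' G_t b
    quad <- colSums(beta * (g_test %*% beta))
    rss <- sum(y_test^2) - 2 * as.numeric(crossprod(b_test, beta)) + quad
    fold_err[f, ] <- rss / sum(test)
  }
  mean_err <- colMeans(fold_err)
  se_err <- apply(fold_err, 2, sd) / sqrt(n_folds)
  i_min <- which.min(mean_err)
  sel <- if (rule == "min") {
    path[i_min]
  } else {
    candidates <- which(mean_err <= mean_err[i_min] + se_err[i_min])
    path[min(candidates)] # path is decreasing: smallest index = largest lambda
  }
  structure(sel,
            cv = tibble(lambda = path, mean_error = mean_err,
                        se_error = se_err),
            folds = folds)
}

#' Fit a whole cohort at a shared penalty
#'
#' Runs per-patient cross-validation to pick each patient's lambda, fixes the
#' cohort-wide penalty at the arithmetic mean of those per-patient values,
#' and refits every patient at that shared lambda. A shared penalty makes the
#' per-patient supports comparable, which the consensus step relies on.
#'
#' @param y_mat Normalized differential expression, genes x patients (matrix
#'   or [normalize_differential()] object); gene order must match `n_mat`
#'   rows.
#' @param n_mat Signed target matrix.
#' @param config A [run_config()]; uses `alpha`, `cv_folds` and `seed`
#'   (per-patient fold seeds are derived deterministically from it).
#' @return Object of class `mirna_influence_fit`: list with `beta` (miRNA x
#'   patient matrix of refit coefficients), `lambda_per_patient` (tibble),
#'   `lambda_bar`, `alpha`, and the pruned-miRNA record carried over from
#'   `n_mat`.
#' @export
fit_cohort <- function(y_mat, n_mat, config = run_config()) {
  y_mat <- de_values(y_mat)
  config <- validate_run_config(config)
  if (nrow(y_mat) != nrow(n_mat)) {
    abort("fit_cohort: gene rows of Y and N differ")
  }
  if (!is.null(rownames(y_mat)) &&
      !identical(rownames(y_mat), rownames(n_mat))) {
    abort("fit_cohort: gene id order of Y and N differ")
  }
  patients <- colnames(y_mat) %||% paste0("patient_", seq_len(ncol(y_mat)))
  fold_seeds <- withr::with_seed(config$seed,
                                 sample.int(.Machine$integer.max - 1L,
                                            ncol(y_mat)))
  lam <- vapply(seq_len(ncol(y_mat)), function(p) {
    as.numeric(select_lambda_cv(y_mat[, p], n_mat, alpha = config$alpha,
                                n_folds = config$cv_folds,
                                seed = fold_seeds[p]))
  }, numeric(1))
  lambda_bar <- mean(lam)
  gp <- gram_parts(n_mat)
  beta <- vapply(seq_len(ncol(y_mat)), function(p) {
    b <- as.numeric(Matrix::crossprod(n_mat, y_mat[, p]))
    enet_solve(gp$g, b, gp$n, lambda_bar, config$alpha)[, 1]
  }, numeric(ncol(n_mat)))
  beta <- matrix(beta, nrow = ncol(n_mat),
                 dimnames = list(colnames(n_mat), patients))
  structure(
    list(beta = beta,
         lambda_per_patient = tibble(patient_id = patients, lambda = lam),
         lambda_bar = lambda_bar,
         alpha = config$alpha,
         pruned_mirnas = attr(n_mat, "pruned_mirnas") %||% character(0)),
    class = "mirna_influence_fit"
  )
}

#' @exportS3Method base::print
print.mirna_influence_fit <- function(x, ...) {
  cat(sprintf("miRNA influence fit: %d miRNAs x %d patients\n",
              nrow(x$beta), ncol(x$beta)))
  cat(sprintf("  alpha = %g, cohort lambda = %g (mean of per-patient CV)\n",
              x$alpha, x$lambda_bar))
  cat(sprintf("  mean support size = %.1f miRNAs/patient\n",
              mean(colSums(x$beta != 0))))
  if (length(x$pruned_mirnas)) {
    cat(sprintf("  %d miRNA(s) not assessable (no targets in gene set)\n",
                length(x$pruned_mirnas)))
  }
  invisible(x)
}

#' Tidy a cohort influence fit
#'
#' @param x A [fit_cohort()] result.
#' @param ... Unused.
#' @return Long tibble: `mirna_id`, `patient_id`, `beta`.
#' @export
tidy.mirna_influence_fit <- function(x, ...) {
  as_tibble(x$beta, rownames = "mirna_id") |>
    tidyr::pivot_longer(-"mirna_id", names_to = "patient_id",
                        values_to = "beta")
}

#' One-row summary of a cohort influence fit
#'
#' @inheritParams tidy.mirna_influence_fit
#' @return Tibble with `n_mirnas`, `n_patients`, `alpha`, `lambda_bar`,
#'   `mean_support`, `n_pruned`.
#' @export
glance.mirna_influence_fit <- function(x, ...) {
  tibble(
    n_mirnas = nrow(x$beta),
    n_patients = ncol(x$beta),
    alpha = x$alpha,
    lambda_bar = x$lambda_bar,
    mean_support = mean(colSums(x$beta != 0)),
    n_pruned = length(x$pruned_mirnas)
  )
}

#' Export per-patient influences as TSV
#'
#' Writes the miRNA x patient coefficient grid in the shared matrix schema.
#'
#' @param fit A [fit_cohort()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_influences <- function(fit, path) {
  write_de_matrix(fit$beta, path, id_column = "mirna_id")
}
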