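test_that("penalties at or above the path maximum kill every coefficient", {
  for (s in 1:25) {
    n_mat <- random_design(20, 5, seed = s)
    y <- withr::with_seed(1000 + s, rnorm(20))
    b <- as.numeric(Matrix::crossprod(n_mat, y))
    alpha <- 0.25
    lmax <- max(abs(b)) / (20 * alpha)
    fit <- fit_patient(y, n_mat, enet_spec(alpha, lmax * 1.000001))
    expect_identical(fit$beta, rep(0, 5))
  }
  # zero response gives zero coefficients at any positive penalty
  n_mat <- random_design(20, 5, seed = 99)
  expect_identical(fit_patient(rep(0, 20), n_mat, enet_spec(0.5, 0.01))$beta,
                   rep(0, 5))
})

test_that("single-predictor fits match the analytic soft-threshold formula", {
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  for (s in 1:5) {
    x <- random_design(30, 1, density = 0.5, seed = 40 + s)
    y <- withr::with_seed(50 + s, rnorm(30, sd = 2))
    xv <- as.numeric(x[, 1])
    n <- length(y)
    for (alpha in c(0.1, 0.25, 1)) {
      for (lambda in c(0.001, 0.05, 0.5)) {
        beta_hat <- fit_patient(y, x, enet_spec(alpha, lambda))$beta
        analytic <- soft(sum(xv * y) / n, lambda * alpha) /
          (sum(xv^2) / n + lambda * (1 - alpha))
        expect_equal(beta_hat, analytic, tolerance = 1e-10)
      }
    }
  }
})

test_that("near-ridge fits match the closed-form ridge estimate", {
  for (s in 1:10) {
    n_mat <- random_design(20, 5, seed = 60 + s)
    y <- withr::with_seed(70 + s, rnorm(20))
    lambda <- 0.2
    fit <- fit_patient(y, n_mat, enet_spec(1e-6, lambda))
    x <- as.matrix(n_mat)
    ridge <- solve(crossprod(x) / 20 + lambda * diag(5),
                   crossprod(x, y) / 20)
    expect_equal(fit$beta, as.numeric(ridge), tolerance = 1e-5)
  }
})

test_that("solver agrees with glmnet as an independent reference", {
  skip_if_not_installed("glmnet")
  n_mat <- random_design(100, 8, density = 0.25, seed = 81)
  y <- withr::with_seed(82, rnorm(100))
  x <- as.matrix(n_mat)

  # lasso: identical conventions
  lam <- 0.05
  ours <- fit_patient(y, n_mat, enet_spec(1, lam))$beta
  ref <- as.numeric(glmnet::glmnet(x, y, alpha = 1, lambda = lam,
                                   standardize = FALSE, intercept = FALSE,
                                   thresh = 1e-16, maxit = 1e7)$beta)
  expect_equal(ours, ref, tolerance = 1e-7)

  # elastic net: glmnet's gaussian path standardizes the response, scaling
  # its ridge term by sd(y); map (lambda, alpha) onto glmnet's convention
  alpha <- 0.25
  sy <- sqrt(mean(y^2)) # glmnet's intercept-free response scale
  l1 <- lam * alpha
  l2 <- lam * (1 - alpha) * sy
  lam_g <- l1 + l2
  alpha_g <- l1 / lam_g
  ours2 <- fit_patient(y, n_mat, enet_spec(alpha, lam))$beta
  ref2 <- as.numeric(glmnet::glmnet(x, y, alpha = alpha_g, lambda = lam_g,
                                    standardize = FALSE, intercept = FALSE,
                                    thresh = 1e-16, maxit = 1e7)$beta)
  expect_equal(ours2, ref2, tolerance = 1e-6)
})

test_that("fits satisfy basic optimizer sanity and path monotonicity", {
  n_mat <- random_design(60, 6, seed = 91)
  y <- withr::with_seed(92, rnorm(60))
  lambdas <- sort(10^seq(-3, 0, length.out = 12), decreasing = TRUE)
  l1_norms <- vapply(lambdas, function(l) {
    fit <- fit_patient(y, n_mat, enet_spec(0.25, l))
    expect_lte(enet_objective(y, n_mat, fit$beta, l, 0.25),
               enet_objective(y, n_mat, rep(0, 6), l, 0.25))
    sum(abs(fit$beta))
  }, numeric(1))
  expect_true(all(diff(l1_norms) >= -1e-10)) # larger lambda, smaller L1 norm
})

test_that("a duplicated relevant predictor keeps both copies under the elastic net", {
  withr::with_seed(101, {
    base <- matrix(-(runif(200 * 4) < 0.3), 200, 4)
    x <- cbind(base, base[, 1]) # duplicate the first column
    dimnames(x) <- list(sprintf("g%03d", 1:200), sprintf("m%d", 1:5))
    beta_true <- c(2, -1, 0, 0, 0)
    y <- as.numeric(x %*% beta_true)
  })
  xs <- Matrix::Matrix(x, sparse = TRUE)
  fit <- fit_patient(y, xs, enet_spec(0.25, 0.1))
  expect_true(fit$beta[1] > 0 && fit$beta[5] > 0) # both copies retained
  expect_equal(fit$beta[1], fit$beta[5], tolerance = 1e-6)
})

test_that("cross-validation errors equal an independent fold-by-fold refit loop", {
  n_mat <- random_design(30, 5, density = 0.4, seed = 111)
  y <- withr::with_seed(112, as.numeric(as.matrix(n_mat) %*%
                                          c(1.5, -1, 0, 0, 0) + rnorm(30)))
  alpha <- 0.25
  sel <- select_lambda_cv(y, n_mat, alpha = alpha, n_folds = 5, seed = 7)
  cv <- attr(sel, "cv")
  folds <- attr(sel, "folds")

  # oracle: cold refit per (fold, lambda) through the public single-fit API
  oracle <- vapply(cv$lambda, function(lam) {
    errs <- vapply(1:5, function(f) {
      train <- folds != f
      fit <- fit_patient(y[train], n_mat[train, , drop = FALSE],
                         enet_spec(alpha, lam))
      pred <- as.numeric(n_mat[!train, , drop = FALSE] %*% fit$beta)
      mean((y[!train] - pred)^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_equal(cv$mean_error, oracle, tolerance = 1e-10)
  expect_equal(as.numeric(sel), cv$lambda[which.min(cv$mean_error)])
})

test_that("lambda selection is deterministic given the seed", {
  n_mat <- random_design(40, 5, seed = 121)
  y <- withr::with_seed(122, rnorm(40))
  s1 <- select_lambda_cv(y, n_mat, seed = 5)
  s2 <- select_lambda_cv(y, n_mat, seed = 5)
  expect_identical(as.numeric(s1), as.numeric(s2))
  expect_identical(attr(s1, "cv"), attr(s2, "cv"))
  expect_error(select_lambda_cv(y, n_mat, n_folds = 41), "more folds")
})

test_that("pure-noise responses select heavy penalties", {
  n_mat <- random_design(100, 10, density = 0.2, seed = 131)
  upper <- 0
  for (s in 1:50) {
    y <- withr::with_seed(500 + s, rnorm(100))
    sel <- select_lambda_cv(y, n_mat, n_folds = 5, seed = s)
    cv <- attr(sel, "cv")
    # upper half of the (decreasing) path = first 50 entries
    upper <- upper + (which(cv$lambda == as.numeric(sel)) <= 50)
  }
  expect_gte(upper, 40) # >= 80% of seeds
})

test_that("cohort fits share the mean cross-validated penalty", {
  n_mat <- random_design(80, 6, density = 0.3, seed = 141)
  y_mat <- withr::with_seed(142, {
    beta <- matrix(rnorm(6 * 3), 6, 3)
    as.matrix(n_mat) %*% beta + matrix(rnorm(80 * 3, sd = 0.1), 80, 3)
  })
  colnames(y_mat) <- paste0("p", 1:3)
  cfg <- run_config(seed = 9, cv_folds = 5)
  fit <- fit_cohort(y_mat, n_mat, cfg)
  expect_equal(fit$lambda_bar, mean(fit$lambda_per_patient$lambda))
  # refit coefficients reproduce single fits at the shared penalty
  for (p in 1:3) {
    single <- fit_patient(y_mat[, p], n_mat,
                          enet_spec(cfg$alpha, fit$lambda_bar))
    expect_equal(unname(fit$beta[, p]), single$beta, tolerance = 1e-10)
  }
  expect_equal(dim(fit$beta), c(6L, 3L))
  g <- glance(fit)
  expect_equal(g$n_patients, 3L)
  td <- tidy(fit)
  expect_equal(nrow(td), 18L)
})

test_that("a one-patient cohort reduces to a single fit at its CV penalty", {
  n_mat <- random_design(50, 4, seed = 151)
  y <- withr::with_seed(152, as.numeric(as.matrix(n_mat) %*%
                                          c(2, 0, -1, 0) + rnorm(50, sd = 0.2)))
  y_mat <- matrix(y, ncol = 1, dimnames = list(rownames(n_mat), "p1"))
  cfg <- run_config(seed = 33, cv_folds = 5)
  fit <- fit_cohort(y_mat, n_mat, cfg)
  fold_seed <- withr::with_seed(cfg$seed,
                                sample.int(.Machine$integer.max - 1L, 1))
  lam <- select_lambda_cv(y, n_mat, alpha = cfg$alpha, n_folds = 5,
                          seed = fold_seed)
  expect_equal(fit$lambda_bar, as.numeric(lam))
  expect_equal(unname(fit$beta[, 1]),
               fit_patient(y, n_mat, enet_spec(cfg$alpha, fit$lambda_bar))$beta)
})

test_that("dimension and argument errors are caught early", {
  n_mat <- random_design(10, 3, seed = 161)
  expect_error(fit_patient(rnorm(9), n_mat, enet_spec(0.25, 0.1)),
               "length\\(y\\)")
  expect_error(enet_spec(0.25, -1), "lambda")
  expect_error(enet_spec(2, 0.1), "alpha")
  expect_error(fit_cohort(matrix(rnorm(8), 4, 2), n_mat, run_config()),
               "gene rows")
})
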