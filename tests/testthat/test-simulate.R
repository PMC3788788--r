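test_that("degenerate patient spread reproduces the planted means exactly", {
  n_mat <- random_design(30, 6, density = 0.3, seed = 201)
  cfg <- sim_config(n_active = 2, n_patients = 5, patient_sd = 0, seed = 7)
  sim <- simulate_cohort(n_mat, cfg)
  means <- setNames(rep(0, 6), colnames(n_mat))
  means[names(sim$truth$planted_means)] <- sim$truth$planted_means
  for (p in 1:5) expect_equal(unname(sim$mirna_de[, p]), unname(means))
  expect_equal(sim$gene_de, as.matrix(n_mat %*% sim$mirna_de))
})

test_that("gene DE means follow N x planted means, with sign flip via -1 entries", {
  # custom design: g1 targeted only by m1, g2 only by m2, g3 by both
  n_mat <- Matrix::sparseMatrix(i = c(1, 2, 3, 3), j = c(1, 2, 1, 2),
                                x = -1, dims = c(3, 2),
                                dimnames = list(c("g1", "g2", "g3"),
                                                c("m1", "m2")))
  cfg <- sim_config(n_active = 1, n_patients = 400, patient_sd = 0.5,
                    mean_magnitude_range = c(2, 2), seed = 11)
  sim <- simulate_cohort(n_mat, cfg)
  active <- sim$truth$active_mirna_ids
  mu <- sim$truth$planted_means[[1]]
  expect_equal(abs(mu), 2)

  means <- setNames(rep(0, 2), c("m1", "m2")); means[active] <- mu
  expected <- as.numeric(n_mat %*% means)
  emp <- rowMeans(sim$gene_de)
  in_deg <- Matrix::rowSums(n_mat != 0)
  se <- 0.5 * sqrt(in_deg) / sqrt(400)
  expect_true(all(abs(emp - expected) <= 3.5 * se))
  # the gene driven only by the active miRNA has flipped-sign expectation
  driven <- which(c("m1", "m2") == active)
  expect_equal(expected[driven], -mu)
  # a gene targeted only by the inactive miRNA is centred at zero
  expect_equal(expected[setdiff(1:2, driven)], 0)
  expect_error(simulate_cohort(n_mat, sim_config(n_active = 5)), "n_active")
})

test_that("network perturbation counts, set semantics and determinism hold", {
  el <- simulate_network(10, 60, median_targets = 6, seed = 21)
  expect_identical(perturb_network(el, 0, 0, seed = 1), el)

  rem <- perturb_network(el, 0, 0.5, seed = 2)
  expect_equal(nrow(rem), nrow(el) - floor(0.5 * nrow(el)))
  expect_true(all(paste(rem$mirna_id, rem$gene_id) %in%
                    paste(el$mirna_id, el$gene_id)))

  add <- perturb_network(el, 0.3, 0, seed = 3)
  expect_equal(nrow(add), nrow(el) + floor(0.3 * nrow(el)))
  new_pairs <- setdiff(paste(add$mirna_id, add$gene_id),
                       paste(el$mirna_id, el$gene_id))
  expect_equal(length(new_pairs), floor(0.3 * nrow(el)))

  expect_identical(perturb_network(el, 0.3, 0.2, seed = 9),
                   perturb_network(el, 0.3, 0.2, seed = 9))
  expect_error(perturb_network(el, 0, 1), "remove_fraction")
})

test_that("diffusion matches the hand-computed two-gene example and spares isolated genes", {
  ids <- c("g1", "g2", "g3") # g1-g2 path, g3 isolated
  adj <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 1,
                              dims = c(3, 3), dimnames = list(ids, ids))
  gn <- gene_network(ids, adj)
  y <- matrix(c(1, 0, 5), 3, 1, dimnames = list(ids, "p1"))
  out <- apply_diffusion(y, gn, gamma = 0.1)
  expect_equal(unname(out[, 1]), c(1.01, 0.1, 5))
  expect_identical(apply_diffusion(y, gn, 0), y)
  expect_error(apply_diffusion(y, gn, 1), "gamma")
  expect_error(gene_network(ids, Matrix::Diagonal(3) * 1), "self-loops")
})

test_that("expression noise has the stated mean and level-proportional variance", {
  y <- matrix(2, 1000, 1000)
  rownames(y) <- sprintf("g%04d", 1:1000); colnames(y) <- sprintf("p%04d", 1:1000)
  nu <- 0.5
  noisy <- add_expression_noise(y, nu, seed = 31)
  eps <- noisy - y
  expect_lt(abs(mean(eps)), 3 * sqrt(nu * 2 / length(eps)))
  expect_lt(abs(var(as.numeric(eps)) - nu * 2) / (nu * 2), 0.05)
  expect_identical(add_expression_noise(y, 0, seed = 1), y)
  # zero entries still receive noise anchored at the cohort mean level
  y0 <- matrix(c(0, 4), 2, 500)
  dimnames(y0) <- list(c("gz", "gn"), sprintf("p%03d", 1:500))
  n0 <- add_expression_noise(y0, 1, seed = 5)
  expect_gt(sd(n0[1, ]), 0.5)
})

test_that("recovery metrics agree with direct set arithmetic", {
  truth <- structure(list(active_mirna_ids = c("a", "b", "c"),
                          planted_means = c(a = 2, b = -1.5, c = 1)),
                     class = "simulation_truth")
  exact <- manual_calls(c("a", "b", "c"), c(1L, -1L, 1L))
  m <- evaluate_recovery(exact, truth)
  expect_equal(unlist(m[1, 1:3]), c(sensitivity = 1, precision = 1,
                                    sign_accuracy = 1))
  partial <- manual_calls(c("a", "b", "d"), c(1L, 1L, -1L))
  m2 <- evaluate_recovery(partial, truth)
  expect_equal(m2$sensitivity, 2 / 3)
  expect_equal(m2$precision, 2 / 3)
  expect_equal(m2$sign_accuracy, 0.5) # a correct, b flipped

  none <- manual_calls(character(0), integer(0))
  m3 <- evaluate_recovery(none, truth)
  expect_equal(m3$sensitivity, 0)
  expect_equal(m3$precision, 1)
  expect_true(is.na(m3$sign_accuracy))

  # brute-force check on random sets
  universe <- sprintf("m%d", 1:10)
  for (s in 1:25) {
    withr::with_seed(s, {
      t_ids <- sample(universe, sample(0:5, 1))
      p_ids <- sample(universe, sample(0:5, 1))
    })
    tr <- structure(list(active_mirna_ids = t_ids,
                         planted_means = setNames(rep(1, length(t_ids)),
                                                  t_ids)),
                    class = "simulation_truth")
    pr <- manual_calls(p_ids, rep(1L, length(p_ids)))
    mm <- evaluate_recovery(pr, tr)
    tp <- length(intersect(t_ids, p_ids))
    expect_equal(mm$sensitivity,
                 if (length(t_ids) == 0) 1 else tp / length(t_ids))
    expect_equal(mm$precision,
                 if (length(p_ids) == 0) 1 else tp / length(p_ids))
  }
})

test_that("synthetic bipartite networks hit the requested scale and median degree", {
  el <- simulate_network(40, 1000, median_targets = 40, seed = 41)
  n <- build_influence_matrix(el, sort(unique(el$gene_id)),
                              sort(unique(el$mirna_id)), quiet = TRUE)
  deg <- target_degree_summary(n)
  expect_equal(ncol(n), 40)
  med <- attr(deg, "median_targets")
  expect_gt(med, 20); expect_lt(med, 80) # heavy-tailed but centred near 40
  # determinism
  expect_identical(simulate_network(40, 1000, median_targets = 40, seed = 41),
                   el)
  sub <- subsample_network(el, 10, 200, seed = 42)
  expect_lte(dplyr::n_distinct(sub$mirna_id), 10)
  expect_lte(dplyr::n_distinct(sub$gene_id), 200)
})

test_that("robustness sweeps are tidy, aggregated and seed-deterministic", {
  n_small <- {
    el <- simulate_network(20, 300, median_targets = 12, seed = 62)
    build_influence_matrix(el, sort(unique(el$gene_id)),
                           sort(unique(el$mirna_id)), quiet = TRUE)
  }
  grid <- tidyr::expand_grid(edge_remove_fraction = c(0, 0.25),
                             expression_noise_nu = c(0, 0.5))
  sw <- robustness_sweep(n_small, grid, n_replicates = 2, seed = 71,
                         base_config = sim_config(n_active = 3,
                                                  n_patients = 10),
                         infer_config = run_config(seed = 1, cv_folds = 5))
  expect_equal(nrow(sw), 4L)
  expect_true(all(sw$n_replicates == 2))
  expect_true(all(sw$mean_sensitivity >= 0 & sw$mean_sensitivity <= 1))
  expect_true(all(sw$mean_precision >= 0 & sw$mean_precision <= 1))
  reps <- attr(sw, "replicates")
  expect_equal(nrow(reps), 8L)

  sw2 <- robustness_sweep(n_small, grid, n_replicates = 2, seed = 71,
                          base_config = sim_config(n_active = 3,
                                                   n_patients = 10),
                          infer_config = run_config(seed = 1, cv_folds = 5))
  expect_identical(as.data.frame(sw), as.data.frame(sw2))
  expect_error(robustness_sweep(n_small, grid[0, ], 2, 1), "empty grid")
  expect_error(robustness_sweep(n_small, data.frame(bogus = 1), 2, 1),
               "unknown grid")
})
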