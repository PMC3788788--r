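# Synthetic-cohort generator: plants a small set of active miRNAs, draws
# per-patient miRNA differential expression around their signed means, and
# propagates it through the signed target matrix to gene differential
# expression. Four noise models emulate what real data adds on top: spurious
# network edges, missing network edges, gene-gene diffusion, and
# expression-level noise.

#' Simulation configuration
#'
#' Defaults reproduce the reference study conditions: 30 planted active
#' miRNAs among the network's miRNAs, 100 patients, per-patient miRNA
#' differential expression drawn from a Gaussian with standard deviation 0.5
#' around the planted mean (0 for inactive miRNAs), planted mean magnitudes
#' uniform on \[1, 3\] with a fair-coin sign. All noise channels default to
#' off.
#'
#' @param n_active Number of planted active miRNAs.
#' @param n_patients Cohort size.
#' @param mean_magnitude_range Length-2 positive vector (lo, hi): planted
#'   mean magnitudes are Uniform(lo, hi).
#' @param patient_sd Per-patient Gaussian spread of miRNA differential
#'   expression around its mean.
#' @param edge_add_fraction,edge_remove_fraction Fractions (in \[0, 1)) of
#'   the edge count to add/remove before simulating gene expression; the
#'   original network is still used at inference.
#' @param diffusion_gamma Gene-gene diffusion strength in \[0, 1).
#' @param expression_noise_nu Nonnegative scale of the expression-level
#'   noise variance (`nu = 1` gives Poisson-type variance).
#' @param seed Integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_active = 30L, n_patients = 100L,
                       mean_magnitude_range = c(1, 3), patient_sd = 0.5,
                       edge_add_fraction = 0, edge_remove_fraction = 0,
                       diffusion_gamma = 0, expression_noise_nu = 0,
                       seed = 1L) {
  cfg <- list(
    n_active = as.integer(n_active), n_patients = as.integer(n_patients),
    mean_magnitude_range = as.numeric(mean_magnitude_range),
    patient_sd = as.numeric(patient_sd),
    edge_add_fraction = as.numeric(edge_add_fraction),
    edge_remove_fraction = as.numeric(edge_remove_fraction),
    diffusion_gamma = as.numeric(diffusion_gamma),
    expression_noise_nu = as.numeric(expression_noise_nu),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_active >= 1, cfg$n_patients >= 1,
    length(cfg$mean_magnitude_range) == 2,
    all(cfg$mean_magnitude_range > 0),
    cfg$mean_magnitude_range[1] <= cfg$mean_magnitude_range[2],
    cfg$patient_sd >= 0,
    cfg$edge_add_fraction >= 0, cfg$edge_add_fraction < 1,
    cfg$edge_remove_fraction >= 0, cfg$edge_remove_fraction < 1,
    cfg$diffusion_gamma >= 0, cfg$diffusion_gamma < 1,
    cfg$expression_noise_nu >= 0
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic scale-free bipartite miRNA-target network
#'
#' miRNA out-degrees follow a (rounded, truncated) Pareto law whose median is
#' `median_targets`; target genes are drawn without replacement with
#' Zipf-like popularity weights, so some genes are shared hubs - the regime
#' that makes miRNA influences hard to disentangle and motivates the
#' grouped-selection penalty. Matching the microarray-scale reference
#' network's density, the default median degree is 4% of the gene set.
#'
#' @param n_mirna,n_gene Vocabulary sizes.
#' @param median_targets Target median out-degree (default
#'   `round(0.04 * n_gene)`).
#' @param degree_exponent Pareto tail exponent (default 3; larger = lighter
#'   tail).
#' @param gene_zipf Zipf exponent for gene popularity (default 0.8).
#' @param seed Integer seed.
#' @return An [edge_list()] tibble over ids `mir001...`/`g00001...`.
#' @export
simulate_network <- function(n_mirna, n_gene,
                             median_targets = max(1L, round(0.04 * n_gene)),
                             degree_exponent = 3, gene_zipf = 0.8,
                             seed = 1L) {
  stopifnot(n_mirna >= 1, n_gene >= 1, median_targets >= 1,
            median_targets <= n_gene, degree_exponent > 1)
  mirna_ids <- sprintf("mir%03d", seq_len(n_mirna))
  gene_ids <- sprintf("g%05d", seq_len(n_gene))
  withr::with_seed(seed, {
    # Pareto(xm, a) has median xm * 2^(1/a); pick xm to hit median_targets
    xm <- median_targets / 2^(1 / degree_exponent)
    deg <- pmin(n_gene,
                pmax(1L, round(xm * runif(n_mirna)^(-1 / degree_exponent))))
    pop <- sample(seq_len(n_gene)^(-gene_zipf)) # shuffled Zipf weights
    m <- rep(mirna_ids, deg)
    g <- unlist(lapply(deg, function(d) {
      gene_ids[sample.int(n_gene, d, prob = pop)]
    }), use.names = FALSE)
    edge_list(m, g)
  })
}

#' Random induced subnetwork
#'
#' Samples `n_mirna` miRNAs uniformly, keeps their edges, then (if needed)
#' downsamples the induced gene set to `n_gene` genes. Used to carve reduced
#' working scales out of a larger network while preserving its degree
#' structure.
#'
#' @param edges An [edge_list()].
#' @param n_mirna,n_gene Desired vocabulary sizes (`n_gene = Inf` keeps all
#'   induced genes).
#' @param seed Integer seed.
#' @return An [edge_list()].
#' @export
subsample_network <- function(edges, n_mirna, n_gene = Inf, seed = 1L) {
  mirnas <- unique(edges$mirna_id)
  stopifnot(n_mirna <= length(mirnas))
  withr::with_seed(seed, {
    keep_m <- sample(mirnas, n_mirna)
    sub <- dplyr::filter(edges, .data$mirna_id %in% keep_m)
    genes <- unique(sub$gene_id)
    if (is.finite(n_gene) && n_gene < length(genes)) {
      keep_g <- sample(genes, n_gene)
      sub <- dplyr::filter(sub, .data$gene_id %in% keep_g)
    }
    new_edge_list(sub$mirna_id, sub$gene_id)
  })
}

#' Construct a gene-gene interaction network
#'
#' @param gene_ids Character vector of gene ids.
#' @param adjacency Sparse symmetric 0/1 adjacency over `gene_ids` with an
#'   empty diagonal.
#' @return Object of class `gene_network`.
#' @export
gene_network <- function(gene_ids, adjacency) {
  stopifnot(nrow(adjacency) == length(gene_ids),
            ncol(adjacency) == length(gene_ids))
  if (any(Matrix::diag(adjacency) != 0)) {
    abort("gene_network: self-loops are not allowed")
  }
  if (!Matrix::isSymmetric(adjacency)) {
    abort("gene_network: adjacency must be symmetric")
  }
  structure(list(gene_ids = as.character(gene_ids),
                 adjacency = methods::as(adjacency, "CsparseMatrix")),
            class = "gene_network")
}

#' Simulate an Erdos-Renyi gene-gene interaction network
#'
#' Uniform random undirected edges, no self-loops. The default mean degree
#' of 10 matches the density of the protein-protein interaction subnetwork
#' used as the reference diffusion substrate (85,590 edges over 16,799
#' genes).
#'
#' @param gene_ids Character vector of gene ids.
#' @param mean_degree Expected edges per gene (default 10).
#' @param seed Integer seed.
#' @return A [gene_network()].
#' @export
simulate_gene_network <- function(gene_ids, mean_degree = 10, seed = 1L) {
  n <- length(gene_ids)
  stopifnot(n >= 2, mean_degree > 0)
  n_edges <- min(round(mean_degree * n / 2), n * (n - 1) / 2)
  withr::with_seed(seed, {
    # sample unordered pairs by index, reject duplicates
    got <- integer(0)
    while (length(got) < n_edges) {
      i <- sample.int(n, 2 * (n_edges - length(got)), replace = TRUE)
      j <- sample.int(n, 2 * (n_edges - length(got)), replace = TRUE)
      ok <- i != j
      a <- pmin(i[ok], j[ok])
      b <- pmax(i[ok], j[ok])
      key <- (a - 1) * n + b
      got <- unique(c(got, key))
    }
    got <- got[seq_len(n_edges)]
    a <- (got - 1) %/% n + 1
    b <- (got - 1) %% n + 1
    adj <- Matrix::sparseMatrix(i = c(a, b), j = c(b, a), x = 1,
                                dims = c(n, n),
                                dimnames = list(gene_ids, gene_ids))
    gene_network(gene_ids, adj)
  })
}

#' Simulate a cohort with planted active miRNAs
#'
#' Chooses `n_active` miRNAs uniformly without replacement, assigns each a
#' planted mean with magnitude Uniform(lo, hi) and a fair-coin sign (all
#' other miRNAs get mean 0), draws every patient's miRNA differential
#' expression independently as Normal(mean, `patient_sd`), and sets each
#' patient's gene differential expression to `N %*% mirna_de` - so a gene
#' targeted only by a miRNA with planted mean +2 has expected gene DE -2
#' via the -1 entries of N.
#'
#' @param n_mat Signed target matrix used for the simulation step (which may
#'   deliberately differ from the inference network; see
#'   [perturb_network()]).
#' @param config A [sim_config()].
#' @return List: `mirna_de` (miRNA x patient matrix), `gene_de` (gene x
#'   patient matrix), `truth` (list of class `simulation_truth` with
#'   `active_mirna_ids`, `planted_means` (named, signed), `config`).
#' @export
simulate_cohort <- function(n_mat, config = sim_config()) {
  mirnas <- colnames(n_mat)
  if (config$n_active > length(mirnas)) {
    abort(sprintf("simulate_cohort: n_active = %d exceeds the %d miRNAs in N",
                  config$n_active, length(mirnas)))
  }
  lo <- config$mean_magnitude_range[1]
  hi <- config$mean_magnitude_range[2]
  withr::with_seed(config$seed, {
    active <- sample(mirnas, config$n_active)
    magnitude <- runif(config$n_active, lo, hi)
    signs <- sample(c(1, -1), config$n_active, replace = TRUE)
    means <- setNames(rep(0, length(mirnas)), mirnas)
    means[active] <- magnitude * signs
    mirna_de <- matrix(
      rnorm(length(mirnas) * config$n_patients, mean = means,
            sd = config$patient_sd),
      nrow = length(mirnas),
      dimnames = list(mirnas,
                      sprintf("patient_%03d", seq_len(config$n_patients)))
    )
    gene_de <- as.matrix(n_mat %*% mirna_de)
    truth <- structure(list(active_mirna_ids = active,
                            planted_means = means[active],
                            config = config),
                       class = "simulation_truth")
    list(mirna_de = mirna_de, gene_de = gene_de, truth = truth)
  })
}

#' Perturb a network's edge set
#'
#' Removes `floor(remove_fraction * n_edges)` edges uniformly at random and
#' adds `floor(add_fraction * n_edges)` new edges drawn uniformly from the
#' absent (miRNA, gene) pairs over the list's own vocabularies. The
#' perturbed list is meant to generate the data while the *original* network
#' is used for inference: adding edges before simulation makes the inference
#' network miss true interactions (false negatives); removing them before
#' simulation leaves the inference network with spurious ones (false
#' positives).
#'
#' @param edges An [edge_list()].
#' @param add_fraction,remove_fraction Fractions in \[0, 1).
#' @param seed Integer seed.
#' @return A perturbed [edge_list()].
#' @export
perturb_network <- function(edges, add_fraction = 0, remove_fraction = 0,
                            seed = 1L) {
  stopifnot(add_fraction >= 0, remove_fraction >= 0, add_fraction < 1)
  if (remove_fraction >= 1) {
    abort("perturb_network: remove_fraction must be < 1")
  }
  if (add_fraction == 0 && remove_fraction == 0) return(edges)
  n_edges <- nrow(edges)
  mirnas <- unique(edges$mirna_id)
  genes <- unique(edges$gene_id)
  nm <- length(mirnas)
  ng <- length(genes)
  withr::with_seed(seed, {
    keep <- edges
    if (remove_fraction > 0) {
      n_remove <- floor(remove_fraction * n_edges)
      keep <- edges[-sample.int(n_edges, n_remove), , drop = FALSE]
    }
    if (add_fraction > 0) {
      n_add <- floor(add_fraction * n_edges)
      if (n_add > nm * ng - n_edges) {
        abort("perturb_network: not enough absent pairs to add")
      }
      existing <- (match(edges$mirna_id, mirnas) - 1) * ng +
        match(edges$gene_id, genes)
      new_keys <- integer(0)
      while (length(new_keys) < n_add) {
        cand <- sample.int(nm * ng, min(nm * ng, 2 * (n_add - length(new_keys))))
        cand <- setdiff(cand, c(existing, new_keys))
        new_keys <- c(new_keys, cand)
      }
      new_keys <- new_keys[seq_len(n_add)]
      added <- tibble(
        mirna_id = mirnas[(new_keys - 1) %/% ng + 1],
        gene_id = genes[(new_keys - 1) %% ng + 1]
      )
      keep <- dplyr::bind_rows(keep, added)
    }
    new_edge_list(keep$mirna_id, keep$gene_id)
  })
}

#' Diffuse gene differential expression over a gene-gene network
#'
#' Leaks each gene's differential expression to its neighbours and, more
#' weakly, to its second-order neighbours:
#' \deqn{Y' = Y + \gamma \hat A Y + \gamma^2 \hat A^2 Y}
#' where \eqn{\hat A} is the row-normalized adjacency (rows of isolated
#' genes map to zero, so isolated genes are unchanged). This emulates
#' gene-gene interaction effects the regression model does not account for.
#'
#' @param gene_de Gene x patient differential-expression matrix.
#' @param g_net A [gene_network()] covering the matrix's genes (genes absent
#'   from the network are treated as isolated).
#' @param gamma Diffusion strength in \[0, 1).
#' @return Matrix of the same shape.
#' @export
apply_diffusion <- function(gene_de, g_net, gamma) {
  gene_de <- de_values(gene_de, "gene differential expression")
  if (gamma < 0 || gamma >= 1) {
    abort("apply_diffusion: gamma must lie in [0, 1)")
  }
  if (gamma == 0) return(gene_de)
  ids <- rownames(gene_de)
  if (is.null(ids)) abort("apply_diffusion: gene_de needs rownames")
  pos <- match(ids, g_net$gene_ids)
  if (all(is.na(pos))) abort("apply_diffusion: no genes shared with network")
  # restrict adjacency to the DE gene order; missing genes become isolated
  n <- length(ids)
  present <- !is.na(pos)
  inv <- rep(NA_integer_, length(g_net$gene_ids))
  inv[pos[present]] <- which(present)
  trip <- Matrix::summary(methods::as(g_net$adjacency, "TsparseMatrix"))
  ii <- inv[trip$i]
  jj <- inv[trip$j]
  ok <- !is.na(ii) & !is.na(jj)
  adj <- Matrix::sparseMatrix(i = ii[ok], j = jj[ok], x = 1,
                              dims = c(n, n), dimnames = list(ids, ids))
  deg <- Matrix::rowSums(adj)
  inv_deg <- ifelse(deg > 0, 1 / deg, 0)
  a_hat <- Matrix::Diagonal(x = inv_deg) %*% adj
  step1 <- as.matrix(a_hat %*% gene_de)
  step2 <- as.matrix(a_hat %*% step1)
  gene_de + gamma * step1 + gamma^2 * step2
}

#' Add expression-level noise
#'
#' Adds zero-mean Gaussian noise whose *variance* is proportional to the
#' absolute differential-expression level: `var = nu * |y|` (Poisson-type
#' variance at `nu = 1`), emulating count-like measurement noise and
#' unmodelled expression-altering mechanisms. Entries that are exactly zero
#' receive variance `nu * mean(|Y|)` so zero-signal genes stay noisy as they
#' would be in real data.
#'
#' @param gene_de Gene x patient matrix.
#' @param nu Nonnegative variance scale.
#' @param seed Integer seed.
#' @return Matrix of the same shape.
#' @export
add_expression_noise <- function(gene_de, nu, seed = 1L) {
  gene_de <- de_values(gene_de, "gene differential expression")
  stopifnot(nu >= 0)
  if (nu == 0) return(gene_de)
  v <- nu * abs(gene_de)
  v[gene_de == 0] <- nu * mean(abs(gene_de))
  noise <- withr::with_seed(seed, {
    matrix(rnorm(length(gene_de), mean = 0, sd = sqrt(v)),
           nrow = nrow(gene_de))
  })
  gene_de + noise
}

#' Recovery metrics against the planted truth
#'
#' @param predicted A [call_active()] tibble (rows = called miRNAs).
#' @param truth A `simulation_truth` from [simulate_cohort()].
#' @return One-row tibble: `sensitivity` (planted miRNAs recovered / planted;
#'   1 when nothing was planted), `precision` (recovered planted / called; 1
#'   when nothing was called - vacuously no false positives - and 0 when
#'   calls exist but none is planted), `sign_accuracy` (fraction of correctly
#'   recovered miRNAs whose called sign matches the planted sign; `NA` when
#'   there are no true positives), plus the counts `n_called`, `n_true`.
#' @export
evaluate_recovery <- function(predicted, truth) {
  true_ids <- truth$active_mirna_ids
  called_ids <- predicted$mirna_id
  tp <- intersect(called_ids, true_ids)
  sensitivity <- if (length(true_ids) == 0) 1 else length(tp) / length(true_ids)
  precision <- if (length(called_ids) == 0) 1 else length(tp) / length(called_ids)
  sign_accuracy <- if (length(tp) == 0) NA_real_ else {
    called_sign <- predicted$sign[match(tp, predicted$mirna_id)]
    mean(called_sign == sign(truth$planted_means[tp]))
  }
  tibble(sensitivity = sensitivity, precision = precision,
         sign_accuracy = sign_accuracy,
         n_called = length(called_ids), n_true = length(true_ids))
}

# Perturb the edge set (simulation side only), simulate the cohort, then
# apply diffusion and expression-level noise per the config. The returned
# gene_de already carries all configured noise; truth and mirna_de are
# untouched by it.
simulate_noisy_cohort <- function(n_mat, config, g_net = NULL) {
  n_sim <- n_mat
  if (config$edge_add_fraction > 0 || config$edge_remove_fraction > 0) {
    edges <- influence_matrix_edges(n_mat)
    perturbed <- perturb_network(edges,
                                 add_fraction = config$edge_add_fraction,
                                 remove_fraction = config$edge_remove_fraction,
                                 seed = config$seed + 1L)
    n_sim <- build_influence_matrix(perturbed, rownames(n_mat),
                                    colnames(n_mat), drop_empty = FALSE,
                                    quiet = TRUE)
  }
  cohort <- simulate_cohort(n_sim, config)
  if (config$diffusion_gamma > 0) {
    if (is.null(g_net)) {
      g_net <- simulate_gene_network(rownames(n_mat), mean_degree = 10,
                                     seed = config$seed + 2L)
    }
    cohort$gene_de <- apply_diffusion(cohort$gene_de, g_net,
                                      config$diffusion_gamma)
  }
  if (config$expression_noise_nu > 0) {
    cohort$gene_de <- add_expression_noise(cohort$gene_de,
                                           config$expression_noise_nu,
                                           seed = config$seed + 3L)
  }
  cohort
}

#' Simulate, infer and score one cohort
#'
#' Convenience wrapper running the full pipeline once: perturb the edge set
#' (simulation side only), simulate the cohort, optionally diffuse and add
#' expression noise, then infer on the *original* network, call the
#' consensus set and score recovery.
#'
#' @param n_mat Signed target matrix used for inference.
#' @param config A [sim_config()] (noise fields drive the perturbations).
#' @param infer_config A [run_config()] for the inference side.
#' @param g_net Optional [gene_network()] for diffusion; generated
#'   (mean degree 10, seeded) when `NULL` and `diffusion_gamma > 0`.
#' @return List: `metrics` (one-row tibble from [evaluate_recovery()]),
#'   `calls`, `fit`, `truth`, `cohort`.
#' @export
run_recovery <- function(n_mat, config = sim_config(),
                         infer_config = run_config(), g_net = NULL) {
  cohort <- simulate_noisy_cohort(n_mat, config, g_net)
  gene_de <- cohort$gene_de
  fit <- fit_cohort(gene_de, n_mat, infer_config)
  calls <- call_active(fit, infer_config$consensus_fraction)
  list(metrics = evaluate_recovery(calls, cohort$truth),
       calls = calls, fit = fit, truth = cohort$truth, cohort = cohort)
}

#' Robustness sweep over noise settings
#'
#' Runs the full simulate-infer-call-score pipeline for every row of a noise
#' grid, `n_replicates` times each with derived seeds, and aggregates the
#' recovery metrics per cell - the experiment shape behind
#' sensitivity/precision-vs-noise robustness figures, at configurable scale.
#'
#' @param n_mat Signed target matrix used for inference.
#' @param grid Data frame whose columns are any subset of
#'   `edge_add_fraction`, `edge_remove_fraction`, `diffusion_gamma`,
#'   `expression_noise_nu`; one row per noise setting.
#' @param n_replicates Replicate cohorts per cell.
#' @param seed Master seed; per-run seeds are derived deterministically.
#' @param base_config A [sim_config()] supplying the non-noise fields.
#' @param infer_config A [run_config()] for the inference side.
#' @param g_net Optional shared [gene_network()] for diffusion cells.
#' @return Tidy tibble: the grid columns plus `n_replicates`,
#'   `mean_sensitivity`, `mean_precision`, `mean_sign_accuracy` (sign
#'   accuracy averaged over replicates with true positives). Per-replicate
#'   rows are attached as attribute `replicates`.
#' @export
robustness_sweep <- function(n_mat, grid, n_replicates = 3L, seed = 1L,
                             base_config = sim_config(),
                             infer_config = run_config(),
                             g_net = NULL) {
  grid <- as_tibble(grid)
  if (nrow(grid) == 0) abort("robustness_sweep: empty grid")
  noise_fields <- c("edge_add_fraction", "edge_remove_fraction",
                    "diffusion_gamma", "expression_noise_nu")
  unknown <- setdiff(names(grid), noise_fields)
  if (length(unknown)) {
    abort(paste0("robustness_sweep: unknown grid column(s): ",
                 paste(unknown, collapse = ", ")))
  }
  n_runs <- nrow(grid) * n_replicates
  run_seeds <- withr::with_seed(seed,
                                sample.int(.Machine$integer.max - 10L, n_runs))
  reps <- purrr::map_dfr(seq_len(n_runs), function(r) {
    cell <- (r - 1) %/% n_replicates + 1
    cfg <- base_config
    for (f in names(grid)) cfg[[f]] <- grid[[f]][cell]
    cfg$seed <- run_seeds[r]
    cfg <- do.call(sim_config, unclass(cfg))
    res <- run_recovery(n_mat, cfg, infer_config, g_net = g_net)
    dplyr::bind_cols(grid[cell, , drop = FALSE],
                     tibble(cell = cell, replicate = (r - 1) %% n_replicates + 1),
                     res$metrics)
  })
  out <- reps |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(names(grid), "cell")))) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      mean_sensitivity = mean(.data$sensitivity),
      mean_precision = mean(.data$precision),
      mean_sign_accuracy = mean(.data$sign_accuracy, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$cell) |>
    dplyr::select(-"cell")
  attr(out, "replicates") <- reps
  out
}
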