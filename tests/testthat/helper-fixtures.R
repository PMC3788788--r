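# Fixtures are built in code at test time; nothing binary ships with the
# package.

# Small strictly positive expression matrix with ids.
toy_expression <- function(n_genes = 5, n_samples = 4, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(2^rnorm(n_genes * n_samples, mean = 6, sd = 1),
                n_genes, n_samples,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n_samples))))
    m
  })
}

# Random sparse -1/0 design in the shape of a signed target matrix.
random_design <- function(n_genes, n_mirnas, density = 0.3, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(-(runif(n_genes * n_mirnas) < density), n_genes, n_mirnas)
    # ensure no empty column (unidentifiable predictor)
    for (j in which(colSums(m != 0) == 0)) m[sample.int(n_genes, 1), j] <- -1
    dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                        sprintf("m%02d", seq_len(n_mirnas)))
    Matrix::Matrix(m, sparse = TRUE)
  })
}

# Elastic-net objective under the package's stated convention.
enet_objective <- function(y, x, beta, lambda, alpha) {
  n <- length(y)
  sum((y - as.numeric(x %*% beta))^2) / (2 * n) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

# The reduced working scale: a 50-miRNA / 2000-gene random subnetwork of a
# synthetic scale-free bipartite graph, generated so its median target count
# is ~4% of the gene set (the full-scale reference network's density).
reduced_scale_network <- function(seed) {
  parent <- simulate_network(150, 6000, median_targets = 120, seed = seed)
  sub <- subsample_network(parent, 50, 2000, seed = seed + 1L)
  build_influence_matrix(sub, sort(unique(sub$gene_id)),
                         sort(unique(sub$mirna_id)), quiet = TRUE)
}

# A consensus_calls tibble built directly (bypassing call_active) for
# validation-layer tests.
manual_calls <- function(mirna_id, sign, fraction_active = 1) {
  calls <- tibble::tibble(mirna_id = mirna_id, sign = as.integer(sign),
                          fraction_active = fraction_active)
  class(calls) <- c("consensus_calls", class(tibble::tibble()))
  calls
}

# miRNA DE matrix with prescribed per-patient sign patterns.
# signs: list of +1/-1 vectors (length n_patients) per miRNA id.
de_from_signs <- function(signs, magnitude = 1) {
  m <- do.call(rbind, lapply(signs, function(s) s * magnitude))
  rownames(m) <- names(signs)
  colnames(m) <- sprintf("p%02d", seq_len(ncol(m)))
  m
}
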