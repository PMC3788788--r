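# End-to-end workflows behind the command-line wrapper: real-data inference,
# validation against miRNA measurements, and the simulation study. Every run
# writes a JSON run record (config snapshot, input digests, stage timings,
# outputs, package version) sufficient to re-execute it.

stage_timer <- function() {
  timings <- list()
  last <- Sys.time()
  list(
    lap = function(stage) {
      now <- Sys.time()
      timings[[stage]] <<- round(as.numeric(now - last, units = "secs"), 3)
      last <<- now
    },
    get = function() timings
  )
}

run_record <- function(command, config, inputs, outputs, timings, out_dir) {
  rec <- list(
    command = command,
    version = as.character(utils::packageVersion("activemir")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = if (inherits(config, "run_config") ||
                 inherits(config, "sim_config")) unclass(config) else config,
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    outputs = outputs,
    timings_sec = timings
  )
  path <- file.path(out_dir, paste0("run_record_", command, ".json"))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Run the inference workflow
#'
#' Reads tumour and healthy gene expression plus the miRNA-target network,
#' computes per-patient normalized differential expression, intersects the
#' network with the measured genes, builds the signed target matrix, fits
#' the cohort at the shared cross-validated penalty, and calls the consensus
#' active set. Writes the coefficient grid (`influences.tsv`), the call
#' table (`calls.tsv`) and a JSON run record under `out_dir`.
#'
#' Alternatively, with `normalized = TRUE`, `gene_tumour` is read as an
#' already-normalized gene x patient differential-expression matrix (the
#' schema [run_simulate()] writes) and `gene_healthy` is ignored - this is
#' how simulated cohorts feed the same workflow unchanged.
#'
#' @param gene_tumour,gene_healthy Paths to linear-scale expression TSVs
#'   (features x samples).
#' @param network Path to the miRNA-target edge list (TSV or GMT).
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param normalized Treat `gene_tumour` as pre-normalized DE (default
#'   `FALSE`).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `fit`, `calls`, and the output paths.
#' @export
run_infer <- function(gene_tumour, gene_healthy = NULL, network,
                      config = run_config(), out_dir = ".",
                      normalized = FALSE, quiet = FALSE) {
  config <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tm <- stage_timer()
  say <- function(...) if (!quiet) inform(sprintf(...))

  edges <- read_network(network, quiet = quiet)
  if (normalized) {
    y <- read_de_matrix(gene_tumour)
    inputs <- c(gene_tumour, network)
  } else {
    if (is.null(gene_healthy)) {
      abort("run_infer: gene_healthy is required unless normalized = TRUE")
    }
    tumour <- read_expression(gene_tumour)
    healthy <- read_expression(gene_healthy)
    nd <- normalize_differential(tumour, healthy, s0 = config$s0,
                                 cancer_var_weight = config$cancer_var_weight)
    y <- nd$values
    inputs <- c(gene_tumour, gene_healthy, network)
  }
  tm$lap("preprocess")

  genes <- intersect(rownames(y), unique(edges$gene_id))
  if (length(genes) == 0) {
    abort("run_infer: no genes shared between expression and network ",
          "(ids must match exactly)")
  }
  say("matched %d of %d expression genes to the network",
      length(genes), nrow(y))
  y <- y[genes, , drop = FALSE]
  n_mat <- build_influence_matrix(edges, gene_order = genes,
                                  mirna_order = unique(edges$mirna_id),
                                  quiet = quiet)
  tm$lap("network")

  fit <- fit_cohort(y, n_mat, config)
  say("cohort lambda = %g (alpha = %g)", fit$lambda_bar, config$alpha)
  tm$lap("fit")

  calls <- call_active(fit, config$consensus_fraction)
  say("%d miRNA(s) called active at consensus fraction %g",
      nrow(calls), config$consensus_fraction)
  beta_path <- file.path(out_dir, "influences.tsv")
  calls_path <- file.path(out_dir, "calls.tsv")
  lambda_path <- file.path(out_dir, "lambda_trace.tsv")
  write_influences(fit, beta_path)
  write_results(calls, calls_path)
  readr::write_tsv(fit$lambda_per_patient, lambda_path)
  tm$lap("write")

  rec <- run_record("infer", config, inputs,
                    list(influences = beta_path, calls = calls_path,
                         lambda_trace = lambda_path),
                    tm$get(), out_dir)
  invisible(list(fit = fit, calls = calls,
                 paths = list(influences = beta_path, calls = calls_path,
                              lambda_trace = lambda_path, record = rec)))
}

#' Run the validation workflow
#'
#' Reads a call table produced by [run_infer()], normalizes the observed
#' miRNA expression through the identical transform used for genes, checks
#' sign concordance per call, and computes the permutation p-value. Writes
#' `calls_validated.tsv`, `validation.json` and a run record.
#'
#' @param calls Path to a `calls.tsv` from [run_infer()].
#' @param mirna_tumour,mirna_healthy Paths to miRNA expression TSVs;
#'   alternatively set `normalized = TRUE` and pass a pre-normalized miRNA
#'   DE matrix as `mirna_tumour`.
#' @inheritParams run_infer
#' @return Invisibly, a list with `calls` (validated tibble), `p_value`, and
#'   output paths.
#' @export
run_validate <- function(calls, mirna_tumour, mirna_healthy = NULL,
                         config = run_config(), out_dir = ".",
                         normalized = FALSE, quiet = FALSE) {
  config <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tm <- stage_timer()
  call_set <- read_results(calls)
  if (nrow(call_set) == 0) abort("run_validate: nothing to validate")
  if (normalized) {
    mirna_de <- read_de_matrix(mirna_tumour)
    inputs <- c(calls, mirna_tumour)
  } else {
    if (is.null(mirna_healthy)) {
      abort("run_validate: mirna_healthy is required unless normalized = TRUE")
    }
    tumour <- read_expression(mirna_tumour)
    healthy <- read_expression(mirna_healthy)
    mirna_de <- normalize_differential(
      tumour, healthy, s0 = config$s0,
      cancer_var_weight = config$cancer_var_weight)$values
    inputs <- c(calls, mirna_tumour, mirna_healthy)
  }
  tm$lap("preprocess")
  validated <- validate_calls(call_set, mirna_de,
                              config$validation_fraction)
  p <- permutation_pvalue(validated, mirna_de,
                          validation_fraction = config$validation_fraction,
                          n_permutations = config$n_permutations,
                          seed = config$seed)
  tm$lap("validate")
  if (!quiet) {
    inform(sprintf(
      "%d/%d measured call(s) validated (rate %.3f); permutation p = %.4g",
      sum(validated$validated_flag, na.rm = TRUE), sum(validated$measured),
      attr(p, "observed_rate"), as.numeric(p)))
  }
  out_calls <- file.path(out_dir, "calls_validated.tsv")
  write_results(validated, out_calls)
  report_path <- file.path(out_dir, "validation.json")
  jsonlite::write_json(
    list(p_value = as.numeric(p),
         observed_validation_rate = attr(p, "observed_rate"),
         n_calls_measured = attr(p, "n_calls"),
         n_permutations = config$n_permutations,
         validation_fraction = config$validation_fraction,
         seed = config$seed),
    report_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tm$lap("write")
  rec <- run_record("validate", config, inputs,
                    list(calls_validated = out_calls, report = report_path),
                    tm$get(), out_dir)
  invisible(list(calls = validated, p_value = as.numeric(p),
                 paths = list(calls = out_calls, report = report_path,
                              record = rec)))
}

#' Run the simulation workflow
#'
#' Simulates a cohort with planted active miRNAs from a network file (with
#' any configured noise), writes the synthetic miRNA and gene
#' differential-expression matrices in the standard TSV schemas (so they
#' feed [run_infer()]/[run_validate()] unchanged), the planted truth as
#' JSON, and optionally evaluates end-to-end recovery or runs a robustness
#' sweep.
#'
#' @param network Path to a miRNA-target edge list.
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param evaluate Also run inference on the synthetic cohort and report
#'   recovery metrics (default `FALSE`).
#' @param sweep Optional noise grid (data frame) triggering
#'   [robustness_sweep()]; written as `sweep.tsv`.
#' @param n_replicates Replicates per sweep cell.
#' @param infer_config A [run_config()] used when `evaluate` or `sweep` is
#'   requested.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the cohort, truth, optional `metrics` /
#'   `sweep`, and output paths.
#' @export
run_simulate <- function(network, config = sim_config(), out_dir = ".",
                         evaluate = FALSE, sweep = NULL, n_replicates = 3L,
                         infer_config = run_config(), quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tm <- stage_timer()
  edges <- read_network(network, quiet = quiet)
  genes <- unique(edges$gene_id)
  n_mat <- build_influence_matrix(edges, gene_order = genes,
                                  mirna_order = unique(edges$mirna_id),
                                  quiet = quiet)
  tm$lap("network")
  if (evaluate) {
    res <- run_recovery(n_mat, config, infer_config)
    cohort <- res$cohort
  } else {
    cohort <- simulate_noisy_cohort(n_mat, config)
  }
  tm$lap("simulate")

  mirna_path <- file.path(out_dir, "mirna_de.tsv")
  gene_path <- file.path(out_dir, "gene_de.tsv")
  truth_path <- file.path(out_dir, "truth.json")
  write_de_matrix(cohort$mirna_de, mirna_path, id_column = "mirna_id")
  write_de_matrix(cohort$gene_de, gene_path, id_column = "gene_id")
  jsonlite::write_json(
    list(active_mirna_ids = cohort$truth$active_mirna_ids,
         planted_means = as.list(cohort$truth$planted_means),
         config = unclass(config)),
    truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  outputs <- list(mirna_de = mirna_path, gene_de = gene_path,
                  truth = truth_path)
  out <- list(cohort = cohort, truth = cohort$truth)

  if (evaluate) {
    out$metrics <- res$metrics
    if (!quiet) {
      inform(sprintf(
        "recovery: sensitivity %.3f, precision %.3f, sign accuracy %s",
        res$metrics$sensitivity, res$metrics$precision,
        format(res$metrics$sign_accuracy)))
    }
    metrics_path <- file.path(out_dir, "recovery.tsv")
    readr::write_tsv(res$metrics, metrics_path)
    outputs$recovery <- metrics_path
  }
  if (!is.null(sweep)) {
    sw <- robustness_sweep(n_mat, sweep, n_replicates = n_replicates,
                           seed = config$seed, base_config = config,
                           infer_config = infer_config)
    sweep_path <- file.path(out_dir, "sweep.tsv")
    readr::write_tsv(sw, sweep_path)
    outputs$sweep <- sweep_path
    out$sweep <- sw
  }
  tm$lap("write")
  rec <- run_record("simulate", config, list(network), outputs, tm$get(),
                    out_dir)
  out$paths <- c(outputs, record = rec)
  invisible(out)
}
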