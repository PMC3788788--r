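#' Validate an expression matrix
#'
#' An expression matrix is a numeric matrix of linear-scale, strictly positive
#' intensities with unique feature ids as rownames and unique sample ids as
#' colnames. The positivity requirement exists because the pipeline takes
#' logs downstream; zeros or negatives must be dealt with before import
#' (missing values are not permitted either - pre-impute).
#'
#' @param x Numeric matrix with dimnames.
#' @param what Label used in error messages (e.g. `"tumour"`).
#' @param positive Require all values strictly positive (default `TRUE`).
#'   Differential-expression matrices set this to `FALSE` and only require
#'   finite values.
#' @return `x`, invisibly, if valid; otherwise aborts with a message naming
#'   the offending ids.
#' @export
validate_expression <- function(x, what = "expression", positive = TRUE) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(paste0(what, ": expected a numeric matrix"))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort(paste0(what, ": feature and sample ids (dimnames) are required"))
  }
  if (anyDuplicated(rownames(x))) {
    dup <- unique(rownames(x)[duplicated(rownames(x))])
    abort(paste0(what, ": duplicate feature id(s): ",
                 paste(utils::head(dup, 5), collapse = ", ")))
  }
  if (anyDuplicated(colnames(x))) {
    dup <- unique(colnames(x)[duplicated(colnames(x))])
    abort(paste0(what, ": duplicate sample id(s): ",
                 paste(utils::head(dup, 5), collapse = ", ")))
  }
  if (any(!is.finite(x))) {
    bad <- rownames(x)[unique(which(!is.finite(x), arr.ind = TRUE)[, 1])]
    abort(paste0(what, ": non-finite values in feature(s): ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (positive && any(x <= 0)) {
    bad <- rownames(x)[unique(which(x <= 0, arr.ind = TRUE)[, 1])]
    abort(paste0(what, ": nonpositive values (log is taken downstream) in ",
                 "feature(s): ", paste(utils::head(bad, 5), collapse = ", ")))
  }
  invisible(x)
}

read_matrix_tsv <- function(path, what, positive) {
  if (!file.exists(path)) abort(paste0(what, " file not found: ", path))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (ncol(tab) < 2) abort(paste0(what, ": expected feature id column plus ",
                                  "at least one sample column in ", path))
  features <- tab[[1]]
  samples <- colnames(tab)[-1]
  body <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(num)) {
    idx <- which(is.na(num) & !(body %in% c("NA", "")), arr.ind = TRUE)
    if (nrow(idx) == 0) idx <- which(is.na(num), arr.ind = TRUE)
    abort(sprintf(
      "%s: non-numeric value %s at feature '%s', sample '%s' in %s",
      what, dQuote(body[idx[1, 1], idx[1, 2]]), features[idx[1, 1]],
      samples[idx[1, 2]], path))
  }
  dimnames(num) <- list(features, samples)
  validate_expression(num, what = what, positive = positive)
  num
}

#' Read an expression matrix
#'
#' Reads a tab-separated features-by-samples matrix: first row sample ids,
#' first column feature ids, numeric body on the linear scale. The only
#' accepted dialect is TSV with a header; no CSV/Excel sniffing, so parsing
#' is deterministic. Row and column order is preserved as on disk.
#'
#' @param path Path to the TSV file.
#' @return A validated numeric matrix (features x samples).
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "g1\t1.5\t2", "g2\t3\t4.25"), f)
#' read_expression(f)
read_expression <- function(path) {
  read_matrix_tsv(path, what = "expression", positive = TRUE)
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]: values are printed with enough digits
#' (`%.17g`) that the write/read round trip reproduces the matrix exactly.
#'
#' @param x Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_column Name printed over the feature-id column (default
#'   `"feature"`).
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, id_column = "feature") {
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort("write_expression: matrix must carry feature and sample ids")
  }
  body <- apply(x, 2, function(col) sprintf("%.17g", col))
  if (!is.matrix(body)) body <- matrix(body, nrow = nrow(x))
  lines <- c(
    paste(c(id_column, colnames(x)), collapse = "\t"),
    vapply(seq_len(nrow(x)), function(i) {
      paste(c(rownames(x)[i], body[i, ]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression matrix
#'
#' Same TSV schema as [read_expression()] but values are unitless normalized
#' differences and may be negative; only finiteness is enforced. Simulated
#' cohorts are written in this schema so synthetic and real inputs flow
#' through the same pipeline.
#'
#' @inheritParams read_expression
#' @return A numeric matrix (features x patients).
#' @export
read_de_matrix <- function(path) {
  read_matrix_tsv(path, what = "differential expression", positive = FALSE)
}

#' @rdname read_de_matrix
#' @inheritParams write_expression
#' @export
write_de_matrix <- function(x, path, id_column = "feature") {
  write_expression(x, path, id_column = id_column)
}

new_edge_list <- function(mirna_id, gene_id) {
  edges <- tibble(mirna_id = as.character(mirna_id),
                  gene_id = as.character(gene_id))
  edges <- dplyr::distinct(edges)
  if (any(!nzchar(edges$mirna_id)) || any(!nzchar(edges$gene_id))) {
    abort("edge list: empty miRNA or gene id")
  }
  class(edges) <- c("edge_list", class(tibble()))
  edges
}

#' Construct a miRNA-to-gene edge list
#'
#' @param mirna_id,gene_id Character vectors of equal length; duplicate
#'   (miRNA, gene) pairs are collapsed (set semantics).
#' @return A tibble of class `edge_list` with columns `mirna_id`, `gene_id`.
#' @export
edge_list <- function(mirna_id = character(), gene_id = character()) {
  stopifnot(length(mirna_id) == length(gene_id))
  new_edge_list(mirna_id, gene_id)
}

#' Read a miRNA-to-gene interaction network
#'
#' Accepts either a two-column tab-separated edge list (miRNA id, gene id per
#' line; an optional header is detected by a literal first token `mirna`) or
#' a GMT file (`.gmt`) where each set name is a miRNA and the members are its
#' target genes. Duplicate pairs are collapsed; distinct miRNA, gene and edge
#' counts are reported via `message()`.
#'
#' @param path Path to the network file.
#' @param quiet Suppress the count message (default `FALSE`).
#' @return An [edge_list()] tibble.
#' @export
read_network <- function(path, quiet = FALSE) {
  if (!file.exists(path)) abort(paste0("network file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 3)
    if (length(bad)) {
      abort(sprintf("network: GMT line %d has fewer than 3 fields", bad[1]))
    }
    mirna <- rep(vapply(parts, `[[`, character(1), 1),
                 lengths(parts) - 2L)
    gene <- unlist(lapply(parts, function(p) p[-(1:2)]), use.names = FALSE)
    edges <- new_edge_list(mirna, gene)
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 2)
    if (length(bad)) {
      abort(sprintf("network: line %d has %d field(s), expected 2 (%s)",
                    bad[1], lengths(parts)[bad[1]], path))
    }
    m <- vapply(parts, `[[`, character(1), 1)
    g <- vapply(parts, `[[`, character(1), 2)
    if (tolower(m[1]) == "mirna") {
      m <- m[-1]
      g <- g[-1]
    }
    edges <- new_edge_list(m, g)
  }
  if (!quiet) {
    inform(sprintf("network: %d miRNAs, %d genes, %d edges",
                   dplyr::n_distinct(edges$mirna_id),
                   dplyr::n_distinct(edges$gene_id), nrow(edges)))
  }
  edges
}

#' Write consensus calls to a tab-separated table
#'
#' Columns: `mirna_id`, `sign`, `fraction_active`, `fraction_validated`
#' (empty when no miRNA measurements were supplied), `validated_flag`. Rows
#' are ordered by descending `fraction_active`, ties broken by id, so output
#' is deterministic.
#'
#' @param calls A [call_active()] / [validate_calls()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(calls, path) {
  cols <- c("mirna_id", "sign", "fraction_active")
  if (!all(cols %in% names(calls))) {
    abort("write_results: calls must have mirna_id, sign, fraction_active")
  }
  out <- tibble(
    mirna_id = as.character(calls$mirna_id),
    sign = as.integer(calls$sign),
    fraction_active = calls$fraction_active,
    fraction_validated = if ("fraction_validated" %in% names(calls)) {
      calls$fraction_validated
    } else NA_real_,
    validated_flag = if ("validated_flag" %in% names(calls)) {
      calls$validated_flag
    } else NA
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$fraction_active),
                        .data$mirna_id)
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  lines <- c(
    "mirna_id\tsign\tfraction_active\tfraction_validated\tvalidated_flag",
    sprintf("%s\t%d\t%s\t%s\t%s", out$mirna_id, out$sign,
            fmt(out$fraction_active), fmt(out$fraction_validated),
            ifelse(is.na(out$validated_flag), "",
                   ifelse(out$validated_flag, "TRUE", "FALSE")))
  )
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) abort(paste0("write_results: cannot write to ", path))
  invisible(path)
}

#' Read back a consensus-call table
#'
#' Inverse of [write_results()].
#'
#' @param path Path to a results TSV.
#' @return A tibble of class `consensus_calls`.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) abort(paste0("results file not found: ", path))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  calls <- tibble(
    mirna_id = as.character(tab$mirna_id),
    sign = as.integer(tab$sign),
    fraction_active = as.numeric(tab$fraction_active),
    fraction_validated = suppressWarnings(as.numeric(tab$fraction_validated)),
    validated_flag = ifelse(tab$validated_flag == "", NA,
                            tab$validated_flag == "TRUE")
  )
  class(calls) <- c("consensus_calls", class(tibble()))
  calls
}
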