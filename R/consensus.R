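#' Call cohort-level active miRNAs by sign consensus
#'
#' A miRNA is called active with sign s when the fraction of patients whose
#' influence coefficient is nonzero with sign s exceeds `consensus_fraction`.
#' Because the threshold is above 0.5, at most one sign can qualify. Patients
#' with a zero coefficient count against the fraction (they do not support
#' either sign).
#'
#' @param fit A [fit_cohort()] result (or a plain miRNA x patient coefficient
#'   matrix).
#' @param consensus_fraction Exclusive threshold in (0.5, 1]. Default 0.7.
#' @return Tibble of class `consensus_calls` with one row per called miRNA:
#'   `mirna_id`, `sign` (+1/-1), `fraction_active`, `fraction_validated`
#'   (`NA` until [validate_calls()]), `measured` (`NA`), `validated_flag`
#'   (`NA`); ordered by descending `fraction_active` then id. Attributes:
#'   `n_patients`, `consensus_fraction`, `not_assessable` (pruned miRNAs).
#' @export
call_active <- function(fit, consensus_fraction = 0.7) {
  beta <- if (inherits(fit, "mirna_influence_fit")) fit$beta else fit
  if (!is.matrix(beta)) abort("call_active: expected a fit or a beta matrix")
  if (ncol(beta) == 0) abort("call_active: empty cohort")
  if (consensus_fraction <= 0.5 || consensus_fraction > 1) {
    abort("call_active: consensus_fraction must lie in (0.5, 1]")
  }
  n_pat <- ncol(beta)
  frac_pos <- rowMeans(beta > 0)
  frac_neg <- rowMeans(beta < 0)
  called_pos <- frac_pos > consensus_fraction
  called_neg <- frac_neg > consensus_fraction
  calls <- tibble(
    mirna_id = c(rownames(beta)[called_pos], rownames(beta)[called_neg]),
    sign = c(rep(1L, sum(called_pos)), rep(-1L, sum(called_neg))),
    fraction_active = unname(c(frac_pos[called_pos], frac_neg[called_neg])),
    fraction_validated = NA_real_,
    measured = NA,
    validated_flag = NA
  )
  calls <- dplyr::arrange(calls, dplyr::desc(.data$fraction_active),
                          .data$mirna_id)
  structure(calls,
            n_patients = n_pat,
            patient_ids = colnames(beta),
            consensus_fraction = consensus_fraction,
            not_assessable = if (inherits(fit, "mirna_influence_fit")) {
              fit$pruned_mirnas
            } else character(0),
            class = c("consensus_calls", class(tibble())))
}

# Per-miRNA sign-concordance fractions against observed miRNA DE.
# Returns, for each row of mirna_de, the fraction of patients whose DE is
# strictly positive / strictly negative (zeros are non-concordant for both).
concordance_fractions <- function(mirna_de) {
  de <- de_values(mirna_de, "miRNA differential expression")
  list(pos = rowMeans(de > 0), neg = rowMeans(de < 0),
       ids = rownames(de), n_patients = ncol(de))
}

#' Validate consensus calls against observed miRNA expression
#'
#' For each called miRNA that was measured, computes the fraction of patients
#' whose observed miRNA differential-expression sign equals the called
#' influence sign; the call is validated when that fraction exceeds
#' `validation_fraction`. A zero DE value counts as non-concordant (strict
#' sign match). Calls absent from the measurement matrix are retained and
#' marked unmeasured. miRNA expression enters the method only here - never in
#' the inference itself.
#'
#' @param calls A [call_active()] tibble.
#' @param mirna_de Observed miRNA normalized differential expression (miRNA x
#'   patient matrix or [normalize_differential()] object). Patient ids must
#'   overlap the cohort used for calling (when both carry ids).
#' @param validation_fraction Exclusive threshold in (0.5, 1]. Default 0.7.
#' @return The calls tibble with `fraction_validated`, `measured` and
#'   `validated_flag` filled in; attribute `validation_fraction` added.
#' @export
validate_calls <- function(calls, mirna_de, validation_fraction = 0.7) {
  if (validation_fraction <= 0.5 || validation_fraction > 1) {
    abort("validate_calls: validation_fraction must lie in (0.5, 1]")
  }
  de <- de_values(mirna_de, "miRNA differential expression")
  if (ncol(de) == 0) abort("validate_calls: no patients in miRNA data")
  n_pat <- attr(calls, "n_patients")
  if (!is.null(n_pat) && !is.null(colnames(de))) {
    # patient universes must overlap when both are labelled
    cohort <- attr(calls, "patient_ids")
    if (!is.null(cohort) && !any(colnames(de) %in% cohort)) {
      abort("validate_calls: no overlapping patients between calls and miRNA data")
    }
  }
  cf <- concordance_fractions(de)
  idx <- match(calls$mirna_id, cf$ids)
  measured <- !is.na(idx)
  frac <- rep(NA_real_, nrow(calls))
  frac[measured] <- ifelse(calls$sign[measured] > 0,
                           cf$pos[idx[measured]], cf$neg[idx[measured]])
  calls$fraction_validated <- frac
  calls$measured <- measured
  calls$validated_flag <- ifelse(measured, frac > validation_fraction, NA)
  attr(calls, "validation_fraction") <- validation_fraction
  calls
}

#' Permutation p-value for the validation rate
#'
#' Judges whether the consensus call set's validation rate could arise by
#' chance: each permutation draws, uniformly without replacement from the
#' *measured* miRNA universe, a random set the size of the (measured) call
#' set, assigns each member a fair random sign, and applies the identical
#' validation rule. The p-value is the fraction of permutations whose
#' validation rate strictly exceeds the method's, with a +1/(n+1) correction
#' so the report is never exactly zero (`plus_one = FALSE` gives the raw
#' proportion).
#'
#' @inheritParams validate_calls
#' @param n_permutations Number of random draws. Default 10000.
#' @param seed Integer seed; the result is bit-for-bit reproducible.
#' @param plus_one Apply the (count + 1)/(n + 1) correction (default `TRUE`).
#' @return Scalar p-value in (0, 1], with attributes `observed_rate` (the
#'   method's validation rate), `null_rates` (the permutation rates) and
#'   `n_calls` (measured call-set size).
#' @export
permutation_pvalue <- function(calls, mirna_de, validation_fraction = 0.7,
                               n_permutations = 10000L, seed = 1L,
                               plus_one = TRUE) {
  if (nrow(calls) < 1) abort("permutation_pvalue: empty call set")
  de <- de_values(mirna_de, "miRNA differential expression")
  cf <- concordance_fractions(de)
  idx <- match(calls$mirna_id, cf$ids)
  measured <- !is.na(idx)
  k <- sum(measured)
  if (k < 1) abort("permutation_pvalue: no called miRNA was measured")
  if (length(cf$ids) < k) {
    abort("permutation_pvalue: fewer measured miRNAs than calls")
  }
  pass <- function(sign_vec, which_idx) {
    frac <- ifelse(sign_vec > 0, cf$pos[which_idx], cf$neg[which_idx])
    mean(frac > validation_fraction)
  }
  observed <- pass(calls$sign[measured], idx[measured])
  m <- length(cf$ids)
  null_rates <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      draw <- sample.int(m, k)
      signs <- sample(c(1L, -1L), k, replace = TRUE)
      pass(signs, draw)
    }, numeric(1))
  })
  greater <- sum(null_rates > observed)
  p <- if (plus_one) (greater + 1) / (n_permutations + 1) else {
    greater / n_permutations
  }
  structure(p, observed_rate = observed, null_rates = null_rates,
            n_calls = k)
}
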