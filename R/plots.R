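# ggplot2 views of the result objects. Each returns a ggplot the caller can
# restyle; nothing is printed as a side effect.

#' Plot a cohort influence fit as a signed heatmap
#'
#' One tile per (miRNA, patient): pink for positive influence (targets
#' over-expressed, miRNA depleted), blue for negative, white for zero.
#' miRNAs are ordered by how consistently they are active.
#'
#' @param object A [fit_cohort()] result.
#' @param max_mirnas Show at most this many miRNAs (the most consistently
#'   active ones). Default 40.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mirna_influence_fit <- function(object, max_mirnas = 40, ...) {
  consistency <- pmax(rowMeans(object$beta > 0), rowMeans(object$beta < 0))
  keep <- names(sort(consistency, decreasing = TRUE))
  keep <- utils::head(keep, max_mirnas)
  df <- tidy(object) |>
    dplyr::filter(.data$mirna_id %in% keep) |>
    dplyr::mutate(mirna_id = factor(.data$mirna_id, levels = rev(keep)))
  ggplot2::ggplot(df, ggplot2::aes(.data$patient_id, .data$mirna_id,
                                   fill = sign(.data$beta))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#d6604d", limits = c(-1, 1),
                                  name = "influence sign") +
    ggplot2::labs(x = "patient", y = "miRNA") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot consensus calls
#'
#' Bar chart of the per-call consensus fraction, signed by influence
#' direction and annotated with validation status when available.
#'
#' @param object A [call_active()] / [validate_calls()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.consensus_calls <- function(object, ...) {
  df <- as_tibble(object) |>
    dplyr::mutate(
      direction = ifelse(.data$sign > 0, "targets up (miRNA depleted)",
                         "targets down (miRNA over-expressed)"),
      status = dplyr::case_when(
        is.na(.data$measured) | !.data$measured ~ "not measured",
        .data$validated_flag ~ "validated",
        .default = "not validated"
      ),
      mirna_id = stats::reorder(.data$mirna_id, .data$fraction_active)
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$fraction_active, .data$mirna_id,
                                   fill = .data$direction,
                                   alpha = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::scale_alpha_manual(
      values = c(validated = 1, `not validated` = 0.55,
                 `not measured` = 0.3), name = NULL) +
    ggplot2::scale_fill_manual(
      values = c(`targets up (miRNA depleted)` = "#d6604d",
                 `targets down (miRNA over-expressed)` = "#2166ac"),
      name = NULL) +
    ggplot2::labs(x = "fraction of patients with consistent sign",
                  y = NULL) +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a cross-validation curve
#'
#' Mean held-out squared error against the penalty path (log scale), with
#' one-standard-error ribbon and the selected lambda marked.
#'
#' @param lambda_sel A [select_lambda_cv()] result (carries the curve as an
#'   attribute).
#' @return A ggplot.
#' @export
plot_cv_curve <- function(lambda_sel) {
  cv <- attr(lambda_sel, "cv")
  if (is.null(cv)) abort("plot_cv_curve: no CV curve attached")
  ggplot2::ggplot(cv, ggplot2::aes(.data$lambda, .data$mean_error)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_error - .data$se_error,
                   ymax = .data$mean_error + .data$se_error),
      fill = "grey85") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = as.numeric(lambda_sel),
                        linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda), y = "mean held-out MSE") +
    ggplot2::theme_minimal()
}

#' Plot a robustness sweep
#'
#' Recovery metrics against the varied noise parameter(s); one line per
#' metric, faceted over any second grid dimension.
#'
#' @param sweep A [robustness_sweep()] result.
#' @return A ggplot.
#' @export
plot_sweep <- function(sweep) {
  noise_cols <- intersect(
    c("edge_add_fraction", "edge_remove_fraction", "diffusion_gamma",
      "expression_noise_nu"), names(sweep))
  varied <- noise_cols[vapply(sweep[noise_cols], dplyr::n_distinct,
                              integer(1)) > 1]
  if (length(varied) == 0) varied <- noise_cols[1]
  x_col <- varied[1]
  df <- sweep |>
    tidyr::pivot_longer(dplyr::all_of(c("mean_sensitivity", "mean_precision",
                                        "mean_sign_accuracy")),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(metric = sub("^mean_", "", .data$metric))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data[[x_col]], .data$value,
                                        colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = x_col, y = "mean over replicates") +
    ggplot2::theme_minimal()
  if (length(varied) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data[[varied[2]]]),
                                 labeller = "label_both")
  }
  p
}
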