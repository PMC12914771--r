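#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Diagnostic plot of an enrichment table
#'
#' Histogram of per-variant log2 enrichment ratios, coloured by mutation
#' number when a scheme is supplied.
#'
#' @param records Output of [enrichment_ratios()].
#' @param scheme Optional [reference_scheme()] for mutation-number fill.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(records, scheme = NULL) {
  d <- tibble::as_tibble(records)
  if (!is.null(scheme)) {
    d$n_mutations <- factor(n_mutations(d$signature, scheme))
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_er,
                                         fill = .data$n_mutations))
  } else {
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_er))
  }
  p + ggplot2::geom_histogram(bins = 60) +
    ggplot2::labs(x = "log2 enrichment ratio", y = "variants",
                  fill = "mutations")
}

#' Predicted-versus-observed plot for an ensemble
#'
#' Scatter of ensemble predictions against observed labels, annotated with
#' the Pearson correlation.
#'
#' @param object An `mlp_ensemble`.
#' @param data Tibble with `signature` and `label` columns (e.g. one split
#'   of [split_by_depth()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mlp_ensemble
#' @export
autoplot.mlp_ensemble <- function(object, data, ...) {
  d <- tibble::tibble(
    observed = data$label,
    predicted = predict(object, data$signature)
  )
  r <- pearson_r(d$predicted, d$observed)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::labs(
      x = "observed log2 ER", y = "predicted log2 ER",
      title = sprintf("ensemble fit, Pearson r = %.3f (n = %d)", r, nrow(d))
    )
}

#' Dose-response plot of a Morrison fit
#'
#' Measured relative velocities with the fitted tight-binding curve
#' overlaid on a log-scaled inhibitor axis.
#'
#' @param object A `ki_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ki_fit
#' @export
autoplot.ki_fit <- function(object, ...) {
  d <- object$data
  ii <- d$inhibitor_nM[d$inhibitor_nM > 0]
  grid <- exp(seq(log(min(ii)) - 1, log(max(ii)) + 0.5, length.out = 120))
  fit <- tibble::tibble(
    inhibitor_nM = grid,
    velocity = morrison_relative_velocity(object$E, grid, object$kiapp)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$inhibitor_nM,
                                  y = .data$velocity)) +
    ggplot2::geom_line(data = fit, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$replicate))) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "inhibitor (nM)", y = "relative velocity Vi/V0",
      colour = "replicate",
      title = sprintf("Ki = %.3g nM (Kiapp = %.3g nM)", object$ki,
                      object$kiapp)
    )
}

#' Selectivity panel of a candidate report
#'
#' Bar panel of each candidate's percentile of the variant space with a
#' higher predicted log2 ER, one facet per off-target model: short bars
#' mean strong predicted off-target binding.
#'
#' @param report Output of [rank_candidates()] / [run_design()].
#' @return A ggplot object.
#' @export
plot_candidate_report <- function(report) {
  pct_cols <- grep("^pct_", names(report), value = TRUE)
  if (length(pct_cols) == 0) stop("report has no percentile columns",
                                  call. = FALSE)
  long <- tidyr::pivot_longer(report[c("signature", pct_cols)],
                              dplyr::all_of(pct_cols),
                              names_to = "model", values_to = "percentile",
                              names_prefix = "pct_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$signature,
                                     y = .data$percentile)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = NULL,
                  y = "% of space with higher predicted log2 ER") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
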