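# Diagnostic figures for fitted objects.

#' Plot estimated configuration weights
#'
#' Bar chart of the hierarchical-model configuration weights `eta`,
#' annotated with the estimated null fraction `pi0`.
#'
#' @param object A `mtqtl_hm` fit from [em_fit()].
#' @param top Show at most this many configurations (largest weights).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mtqtl_hm
#' @export
autoplot.mtqtl_hm <- function(object, top = 16L, ...) {
  df <- dplyr::slice_max(object$eta, .data$eta, n = top)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$config, -.data$eta),
                                   y = .data$eta)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "configuration (active tissues)",
                  y = expression(hat(eta)),
                  title = sprintf("eQTL sharing (pi0 = %.2f, %d genes)",
                                  object$pi0, object$n_genes)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot configuration and tissue-activity posteriors
#'
#' @param object A `config_posterior` (see [config_posterior()] and
#'   [gene_config_posterior()]).
#' @param ... Unused.
#' @return A ggplot object (configuration posteriors with tissue-activity
#'   probabilities as a second facet).
#' @method autoplot config_posterior
#' @export
autoplot.config_posterior <- function(object, ...) {
  cfg <- dplyr::mutate(object$configs, panel = "configuration",
                       lab = .data$config, val = .data$posterior)
  tis <- dplyr::mutate(object$tissues, panel = "tissue activity",
                       lab = .data$tissue, val = .data$prob)
  df <- dplyr::bind_rows(cfg[, c("panel", "lab", "val")],
                         tis[, c("panel", "lab", "val")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lab, y = .data$val)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "posterior probability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' EM log-likelihood trace
#'
#' @param fit A `mtqtl_hm` fit.
#' @return A ggplot object showing the (non-decreasing) log-likelihood per
#'   EM iteration.
#' @export
plot_loglik_trace <- function(fit) {
  df <- tibble::tibble(iteration = seq_along(fit$loglik_trace),
                       loglik = fit$loglik_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$loglik)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(y = "relative log-likelihood") +
    ggplot2::theme_minimal()
}
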