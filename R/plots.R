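#' Plot fitted transition probabilities
#'
#' Bar plot of each component's per-edge transition probabilities, faceted
#' by component — the standard way of reading off which dominant path a
#' component has captured.
#'
#' @param object A fitted `hme3m` model.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.hme3m <- function(object, ...) {
  d <- tidy(object, what = "gate")
  d$component <- sprintf("m = %d (pi = %.2f)", d$component, d$pi)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$theta)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~component, ncol = 1) +
    ggplot2::labs(x = "network edge (gene)", y = "transition probability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Plot the EM log-likelihood trace
#'
#' @param model A fitted `hme3m` model (or `markov_mix_fit`).
#' @return A ggplot object.
#' @export
plot_likelihood_trace <- function(model) {
  d <- tibble::tibble(
    iteration = seq_along(model$trace),
    trace = "penalized EM objective",
    value = model$trace
  )
  if (!is.null(model$ll_trace)) {
    d <- dplyr::bind_rows(d, tibble::tibble(
      iteration = seq_along(model$ll_trace),
      trace = "log-likelihood",
      value = model$ll_trace
    ))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$value,
                                  colour = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "EM iteration", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object A [roc_auc()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("AUC = %.3f", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation rates
#'
#' @param object A [cross_validate()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  d <- object$results
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$run), y = .data$ccr)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "cross-validation run", y = "test CCR (%)",
                  title = object$label) +
    ggplot2::theme_minimal()
}
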