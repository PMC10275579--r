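#' Plot a comparison report
#'
#' One row per metric: the generative posterior-mean test-retest correlation
#' with its 95% HDI, and the two-step point estimate with its BCa interval.
#'
#' @param object a `comparison_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.comparison_report <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(metric = object$metric, method = "two-step",
                   r = object$two_step_r, lo = object$two_step_lo,
                   hi = object$two_step_hi),
    tibble::tibble(metric = object$metric, method = "generative",
                   r = object$generative_r, lo = object$generative_lo,
                   hi = object$generative_hi))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$r, y = .data$metric,
                                     colour = .data$method)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "test-retest correlation", y = NULL,
                  colour = NULL) +
    ggplot2::xlim(-1, 1) +
    ggplot2::theme_minimal()
}

#' Plot posterior test-retest distributions of a joint fit
#'
#' Histograms of the posterior draws of each test-retest correlation, with
#' posterior means marked.
#'
#' @param object an `hb_fit` from [fit_model2()] or [fit_model4()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.hb_fit <- function(object, ...) {
  if (!object$model %in% c("m2", "m4"))
    abort("plotting test-retest posteriors requires a joint fit (m2, m4)")
  pooled <- as_draws_matrix(object)
  cols <- grep("^r\\[", colnames(pooled), value = TRUE)
  long <- purrr::map_dfr(cols, function(cl) {
    tibble::tibble(parameter = sub("^r\\[(.*)\\]$", "\\1", cl),
                   r = pooled[, cl])
  })
  means <- long |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(m = mean(.data$r), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70") +
    ggplot2::geom_vline(data = means,
                        ggplot2::aes(xintercept = .data$m), colour = "red") +
    ggplot2::facet_wrap(~parameter) +
    ggplot2::xlim(-1, 1) +
    ggplot2::labs(x = "test-retest correlation", y = "draws") +
    ggplot2::theme_minimal()
}

#' Plot a posterior predictive check
#'
#' Observed block-wise good-deck proportions over the posterior predictive
#' mean and interval, per session.
#'
#' @param object a `ppc_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ppc_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$block)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$pred_mean), colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::facet_wrap(~session, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "trial block", y = "good-deck proportion") +
    ggplot2::theme_minimal()
}
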