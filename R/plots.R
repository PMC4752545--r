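#' Plot a figure-of-merit matrix
#'
#' Per-reader figures of merit by factor-1 level, one panel per factor-2
#' level, with the reader-averaged mean overlaid.
#'
#' @param object A [fom_matrix()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.crossfroc_fom <- function(object, ...) {
  means <- object %>%
    group_by(.data$factor1, .data$factor2) %>%
    summarise(fom = mean(.data$fom), .groups = "drop")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$factor1, y = .data$fom)) +
    ggplot2::geom_point(alpha = 0.45, position = ggplot2::position_jitter(
      width = 0.08, height = 0, seed = 1)) +
    ggplot2::geom_point(data = means, colour = "red3", size = 3, shape = 18) +
    ggplot2::geom_line(data = means, ggplot2::aes(group = 1),
                       colour = "red3") +
    ggplot2::facet_wrap(~factor2) +
    ggplot2::labs(x = "factor 1 level", y = paste0(
      attr(object, "fom_type") %||% "", " figure of merit"))
}

#' Plot pairwise treatment differences with confidence intervals
#'
#' One point per treatment pair with its two-sided CI; a difference is
#' significant (filled point) when its interval excludes zero *and* the
#' overall F-test passes the protected rule.
#'
#' @param object An `orh_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.orh_result <- function(object, ...) {
  d <- mutate(object$pairwise,
              pair = paste(.data$treatment1, "-", .data$treatment2))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pair, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high,
                                          shape = .data$significant)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16)) +
    ggplot2::labs(x = NULL, y = "FOM difference",
                  title = sprintf("%s: F(%g, %.3g) = %.3g, p = %.3g",
                                  toupper(object$analysis), object$ndf,
                                  object$ddf, object$F, object$p))
}

#' @rdname autoplot.orh_result
#' @exportS3Method ggplot2::autoplot
autoplot.crossed_result <- function(object, ...) {
  d <- tidy(object) %>%
    mutate(pair = paste(.data$treatment1, "-", .data$treatment2))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pair, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high,
                                          shape = .data$significant)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16)) +
    ggplot2::facet_wrap(~analysis, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "FOM difference",
                  title = sprintf(
                    "Crossed-modality %s analysis (threshold %.3g)",
                    object$fom_type, object$bonferroni_alpha))
}
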