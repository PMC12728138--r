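#' Plot an ERP waveform
#'
#' @param object An [erp_signal()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.erp_signal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70", linetype = 2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (ms)", y = "Amplitude (µV)")
}

#' Plot a template fit
#'
#' Overlays the subject waveform, the untransformed template and the
#' optimally transformed template.
#'
#' @param fit A `template_fit`.
#' @param signal,template The signals that produced it.
#' @return A ggplot.
#' @export
plot_template_fit <- function(fit, signal, template) {
  stopifnot(inherits(fit, "template_fit"))
  signal <- as_erp_signal(signal)
  template <- as_erp_signal(template)
  fitted <- scale_amplitude(stretch_signal(template, fit$b_opt),
                            max(fit$a_opt, .Machine$double.eps))
  d <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(signal), series = "subject ERP"),
    dplyr::mutate(tibble::as_tibble(template), series = "template"),
    dplyr::mutate(tibble::as_tibble(fitted), series = "transformed template")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$amplitude,
                                  colour = .data$series)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = fit$latency_ms, linetype = 3,
                        na.rm = TRUE) +
    ggplot2::labs(
      x = "Time (ms)", y = "Amplitude (µV)", colour = NULL,
      subtitle = sprintf("a = %.2f, b = %.2f, fit r = %.2f, latency = %.0f ms",
                         fit$a_opt, fit$b_opt, fit$fit_r, fit$latency_ms)
    )
}

#' Plot shift-recovery agreement
#'
#' True versus mean recovered shift per subject, with the identity line;
#' dropped subjects are hollow.
#'
#' @param object A `shift_recovery`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.shift_recovery <- function(object, ...) {
  ggplot2::ggplot(object$subjects,
                  ggplot2::aes(x = .data$lambda_true, y = .data$lambda_hat,
                               shape = .data$kept)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::labs(
      x = expression("True shift" ~ lambda),
      y = expression("Recovered shift" ~ hat(lambda)),
      subtitle = sprintf("ICC(A,1) = %.3f", object$icc)
    )
}

#' Plot a weight vector
#'
#' @param weights Tibble from [make_weights()].
#' @return A ggplot.
#' @export
plot_weights <- function(weights) {
  ggplot2::ggplot(weights, ggplot2::aes(x = .data$time, y = .data$weight)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (ms)", y = "Weight")
}
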