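#' Plot the cumulative recall curve of one screening run
#'
#' @param object A `screening_trace`.
#' @param ... Unused.
#' @return A ggplot: recall against articles read, with the random-order
#'   diagonal for reference.
#' @export
autoplot.screening_trace <- function(object, ...) {
  rc <- recall_curve(object)
  ggplot2::ggplot(rc, ggplot2::aes(x = .data$reads, y = .data$recall)) +
    ggplot2::geom_step(colour = "#2166ac") +
    ggplot2::geom_abline(slope = 1 / object$m, intercept = 0,
                         linetype = "dashed", colour = "grey50") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "articles read", y = "recall",
                  title = "Cumulative recall",
                  subtitle = "dashed: expected under random-order reading") +
    ggplot2::theme_minimal()
}

#' Plot the mean recall curve of a seed-pair sweep
#'
#' @param object A `screening_sweep`.
#' @param what `"recall"` for the across-pair mean cumulative recall curve,
#'   `"auroc"` for the per-step AUROC trajectory (mean and SD band across
#'   seed pairs).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.screening_sweep <- function(object, what = c("recall", "auroc"),
                                     ...) {
  what <- match.arg(what)
  if (what == "recall") {
    ggplot2::ggplot(object$recall,
                    ggplot2::aes(x = .data$reads, y = .data$mean_recall)) +
      ggplot2::geom_ribbon(ggplot2::aes(
        ymin = pmax(0, .data$mean_recall - .data$sd_recall),
        ymax = pmin(1, .data$mean_recall + .data$sd_recall)),
        fill = "#2166ac", alpha = 0.2) +
      ggplot2::geom_line(colour = "#2166ac") +
      ggplot2::geom_abline(slope = 1 / object$m, intercept = 0,
                           linetype = "dashed", colour = "grey50") +
      ggplot2::labs(x = "articles read", y = "mean recall",
                    title = sprintf("Mean cumulative recall over %d seed pairs",
                                    object$pair_count)) +
      ggplot2::theme_minimal()
  } else {
    if (is.null(object$auroc_steps)) {
      abort("sweep was run with keep_auroc = FALSE",
            class = "citescreen_validation_error")
    }
    ggplot2::ggplot(object$auroc_steps,
                    ggplot2::aes(x = .data$step, y = .data$mean_auroc)) +
      ggplot2::geom_ribbon(ggplot2::aes(
        ymin = pmax(0, .data$mean_auroc - .data$sd_auroc),
        ymax = pmin(1, .data$mean_auroc + .data$sd_auroc)),
        fill = "#b2182b", alpha = 0.2) +
      ggplot2::geom_line(colour = "#b2182b") +
      ggplot2::coord_cartesian(ylim = c(0, 1)) +
      ggplot2::labs(x = "prioritisation step", y = "AUROC",
                    title = "Per-step discrimination across seed pairs") +
      ggplot2::theme_minimal()
  }
}
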