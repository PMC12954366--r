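#' Plot an accuracy timecourse
#'
#' Unit-mean accuracy with a ±SEM ribbon and the chance level; an
#' optional cluster result shades significant windows.
#'
#' @param object an [accuracy_timecourse()].
#' @param clusters optional `cluster_result` from [cluster_perm_1d()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.accuracy_timecourse <- function(object, clusters = NULL, ...) {
  df <- tidy(object) |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(mean = mean(.data$accuracy),
                     sem = sd(.data$accuracy) /
                       sqrt(dplyr::n()), .groups = "drop")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mean)) +
    ggplot2::geom_hline(yintercept = object$chance, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, fill = "#2166ac") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "time (s)", y = "decoding accuracy",
                  title = sprintf("%s decoding (%s)",
                                  paste(object$classes, collapse = "/"),
                                  object$scheme)) +
    ggplot2::theme_minimal()
  if (!is.null(clusters) && any(clusters$mask)) {
    sig <- tibble::tibble(time = object$times[clusters$mask],
                          y = object$chance - 0.02)
    p <- p + ggplot2::geom_point(data = sig,
                                 ggplot2::aes(x = .data$time, y = .data$y),
                                 inherit.aes = FALSE, shape = 15,
                                 colour = "#b2182b", size = 1)
  }
  p
}

#' Plot a Bayes-factor timecourse
#'
#' log10 BF10 over time with the evidence threshold.
#'
#' @param object a `bf_timecourse` from [bf_timecourse()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.bf_timecourse <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time, y = log10(.data$bf10))) +
    ggplot2::geom_hline(yintercept = log10(thr), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_line(colour = "#762a83") +
    ggplot2::geom_point(data = dplyr::filter(object, .data$exceeds),
                        colour = "#b2182b", size = 0.8) +
    ggplot2::labs(x = "time (s)", y = expression(log[10] ~ BF[10])) +
    ggplot2::theme_minimal()
}

#' Scalp map of time-averaged searchlight accuracy
#'
#' Channels plotted at their projected scalp positions, coloured by the
#' unit-mean accuracy averaged over a time window.
#'
#' @param object a [searchlight_result()].
#' @param mon the montage the result was computed on.
#' @param window time window to average, seconds; default the whole
#'   epoch.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.searchlight_result <- function(object, mon = biosemi64_montage(),
                                        window = NULL, ...) {
  sel <- if (is.null(window)) {
    rep(TRUE, length(object$times))
  } else {
    object$times >= window[1] & object$times < window[2]
  }
  acc <- apply(object$accuracy[, , sel, drop = FALSE], 2, mean)
  xy <- project_scalp(mon)[object$channels, , drop = FALSE]
  df <- tibble::tibble(channel = object$channels, u = xy[, 1], v = xy[, 2],
                       accuracy = acc)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                   fill = .data$accuracy)) +
    ggplot2::geom_point(shape = 21, size = 6, colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$channel), size = 1.8,
                       vjust = -1.6) +
    ggplot2::scale_fill_gradient2(midpoint = object$chance,
                                  low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "accuracy")
}
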