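#' Average a searchlight result across sensors
#'
#' Collapses the channel axis of a searchlight accuracy array by
#' averaging, yielding a spatially agnostic per-participant timecourse
#' used for whole-scalp onset estimation.
#'
#' @param sl a [searchlight_result()].
#' @return An [accuracy_timecourse()] (units x samples), chance
#'   preserved, scope `"sensor_mean"`.
#' @export
average_over_sensors <- function(sl) {
  stopifnot(inherits(sl, "searchlight_result"))
  acc <- apply(sl$accuracy, c(1, 3), mean)
  if (is.null(dim(acc))) acc <- matrix(acc, nrow = 1)
  rownames(acc) <- dimnames(sl$accuracy)[[1]]
  accuracy_timecourse(acc, sl$times, sl$sfreq, sl$chance,
                      scope = "sensor_mean", classes = sl$classes,
                      scheme = sl$scheme)
}

#' Estimate decoding onset and peak latency
#'
#' Computes the Bayes-factor timecourse of a (smoothed, sensor-averaged)
#' accuracy timecourse and reports the onset — the first post-stimulus
#' timepoint whose BF10 exceeds the evidence threshold (optionally
#' requiring `min_run` consecutive such timepoints) — and the peak, the
#' post-stimulus timepoint with the largest BF10, together with the
#' Bayes factor and mean accuracy at the peak. When no timepoint
#' crosses the threshold both latencies are reported as undefined
#' (`NA`), which is a valid outcome, not an error.
#'
#' @param tc an [accuracy_timecourse()], normally from
#'   [average_over_sensors()] after [moving_average()].
#' @param threshold BF10 evidence threshold.
#' @param min_run consecutive supra-threshold timepoints required for
#'   the onset (1 = a single timepoint suffices).
#' @param contrast label recorded in the report.
#' @inheritParams bf_interval_ttest
#' @return An `onset_report`: one-row tibble with `contrast`, `onset_s`,
#'   `peak_s`, `peak_bf`, `peak_accuracy`, `defined`; the Bayes-factor
#'   timecourse is attached as attribute `bf`.
#' @export
estimate_onset_peak <- function(tc, threshold = 10, min_run = 1,
                                contrast = NULL, r = 0.707,
                                null_excl = c(-0.5, 0.5)) {
  stopifnot(inherits(tc, "accuracy_timecourse"))
  bf <- bf_timecourse(tc, threshold = threshold, r = r,
                      null_excl = null_excl)
  post <- bf$time > 0
  onset <- NA_real_
  peak <- NA_real_
  peak_bf <- NA_real_
  peak_acc <- NA_real_
  hit <- post & bf$exceeds
  if (any(hit)) {
    if (min_run > 1) {
      rl <- rle(hit)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      ok <- rl$values & rl$lengths >= min_run
      onset_idx <- if (any(ok)) starts[which(ok)[1]] else NA_integer_
    } else {
      onset_idx <- which(hit)[1]
    }
    if (!is.na(onset_idx)) {
      onset <- bf$time[onset_idx]
      post_bf <- ifelse(post, bf$bf10, -Inf)
      peak_idx <- which.max(post_bf)
      peak <- bf$time[peak_idx]
      peak_bf <- bf$bf10[peak_idx]
      peak_acc <- bf$mean_accuracy[peak_idx]
    }
  }
  contrast <- contrast %||%
    if (length(tc$classes) == 4L) "4class" else
      paste(tc$classes, collapse = "_vs_")
  out <- tibble::tibble(
    contrast = contrast, scheme = tc$scheme,
    onset_s = onset, peak_s = peak, peak_bf = peak_bf,
    peak_accuracy = peak_acc, defined = !is.na(onset))
  structure(out, bf = bf, threshold = threshold,
            class = c("onset_report", class(out)))
}
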