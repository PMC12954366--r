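#' EEG epochs container
#'
#' The universal currency of the pipeline: a trials x channels x samples
#' amplitude array (microvolts) with a uniform timebase and a per-trial
#' metadata table.
#'
#' @param data numeric array `[n_trials, n_channels, n_samples]`, µV.
#' @param times numeric vector of sample times in seconds relative to
#'   stimulus onset; must be uniform at `1/sfreq` to within 1e-9 s.
#' @param channels character vector of channel names.
#' @param trials data frame with one row per trial and at least the
#'   columns `participant_id`, `dataset_id`, `expression` (one of happy,
#'   angry, sad, neutral), `stimulus_id`, `correct` (logical) and
#'   `is_pseudotrial` (logical).
#' @param sfreq sampling frequency in Hz.
#' @return An object of class `eeg_epochs`.
#' @export
epoch_set <- function(data, times, channels, trials, sfreq) {
  data <- unclass(data)
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3D array [trials x channels x samples].")
  }
  trials <- tibble::as_tibble(trials)
  required <- c("participant_id", "dataset_id", "expression", "stimulus_id",
                "correct", "is_pseudotrial")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Trial table is missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!all(trials$expression %in% EXPRESSIONS)) {
    bad <- unique(setdiff(trials$expression, EXPRESSIONS))
    abort(sprintf("Unknown expression label(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  if (dim(data)[1] != nrow(trials)) {
    abort("First data dimension must match the number of trial rows.")
  }
  if (dim(data)[2] != length(channels)) {
    abort("Second data dimension must match the number of channels.")
  }
  if (dim(data)[3] != length(times)) {
    abort("Third data dimension must match the number of samples.")
  }
  assert_scalar_number(sfreq, "sfreq", lower = 1e-9)
  if (length(times) > 1L) {
    dt <- diff(times)
    if (any(dt <= 0)) abort("`times` must be strictly increasing.")
    if (max(abs(dt - 1 / sfreq)) > 1e-9) {
      abort("`times` must be uniform at 1/sfreq to within 1e-9 s.")
    }
  }
  structure(
    list(data = data, times = as.numeric(times),
         channels = as.character(channels), trials = trials,
         sfreq = as.numeric(sfreq)),
    class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf(
    "<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$sfreq))
  cat(sprintf("  window: [%g, %g] s; datasets: %s; participants: %d\n",
              min(x$times), max(x$times),
              paste(unique(x$trials$dataset_id), collapse = ", "),
              length(unique(x$trials$participant_id))))
  invisible(x)
}

#' @export
dim.eeg_epochs <- function(x) dim(x$data)

n_trials <- function(x) dim(x$data)[1]

#' Subset epochs by trial index
#'
#' @param epochs an `eeg_epochs`.
#' @param idx integer or logical trial index.
#' @return An `eeg_epochs` containing the selected trials.
#' @export
subset_trials <- function(epochs, idx) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$times,
            epochs$channels, epochs$trials[idx, , drop = FALSE],
            epochs$sfreq)
}

#' Trial metadata as a tibble
#' @param x an `eeg_epochs`.
#' @param ... unused.
#' @return The trial table.
#' @export
as_tibble.eeg_epochs <- function(x, ...) x$trials

# sample index of the epoch start for a half-open [t0, t1) window
window_samples <- function(t0, t1, sfreq) round((t1 - t0) * sfreq)
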