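#' Write epochs as a portable bundle directory
#'
#' The bundle is the package's canonical on-disk format: a directory with
#' `header.json` (sampling rate, timebase, channel names, array
#' dimensions, provenance fields), `data.bin.gz` (the amplitude array as
#' little-endian doubles, trial index varying slowest) and `trials.tsv`
#' (the trial metadata table). Round trips are lossless to floating-point
#' precision.
#'
#' @param epochs an `eeg_epochs`.
#' @param path bundle directory (created if needed).
#' @param extra named list merged into the JSON header, e.g. applied
#'   preprocessing parameters or generator seeds.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path, extra = list()) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  header <- c(list(
    format = "emodecode-bundle",
    format_version = 1L,
    sfreq = epochs$sfreq,
    tmin = epochs$times[1],
    n_trials = dim(epochs$data)[1],
    n_channels = dim(epochs$data)[2],
    n_samples = dim(epochs$data)[3],
    channels = epochs$channels,
    unit = "uV"), extra)
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- gzfile(file.path(path, "data.bin.gz"), "wb")
  on.exit(close(con), add = TRUE)
  # write trial-major: [samples within channel within trial]
  writeBin(as.numeric(aperm(epochs$data, c(3, 2, 1))), con,
           size = 8, endian = "little")
  readr::write_tsv(epochs$trials, file.path(path, "trials.tsv"),
                   progress = FALSE)
  invisible(path)
}

#' Read epochs from a portable bundle directory
#'
#' @param path bundle directory written by [write_epochs()].
#' @return An `eeg_epochs`.
#' @export
read_epochs <- function(path) {
  header_path <- file.path(path, "header.json")
  data_path <- file.path(path, "data.bin.gz")
  trials_path <- file.path(path, "trials.tsv")
  for (f in c(header_path, data_path, trials_path)) {
    if (!file.exists(f)) {
      abort(sprintf("Bundle is missing required file '%s'.", basename(f)))
    }
  }
  hd <- jsonlite::read_json(header_path, simplifyVector = TRUE)
  needed <- c("sfreq", "tmin", "n_trials", "n_channels", "n_samples",
              "channels")
  miss <- setdiff(needed, names(hd))
  if (length(miss) > 0L) {
    abort(sprintf("Bundle header is missing field(s): %s.",
                  paste(miss, collapse = ", ")))
  }
  trials <- readr::read_tsv(trials_path, show_col_types = FALSE,
                            progress = FALSE)
  required <- c("participant_id", "dataset_id", "expression", "stimulus_id",
                "correct", "is_pseudotrial")
  miss <- setdiff(required, names(trials))
  if (length(miss) > 0L) {
    abort(sprintf("Bundle trial table is missing column(s): %s.",
                  paste(miss, collapse = ", ")))
  }
  n <- hd$n_trials * hd$n_channels * hd$n_samples
  con <- gzfile(data_path, "rb")
  on.exit(close(con), add = TRUE)
  raw <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  if (length(raw) != n) abort("Bundle data array is truncated.")
  data <- aperm(array(raw, c(hd$n_samples, hd$n_channels, hd$n_trials)),
                c(3, 2, 1))
  times <- hd$tmin + seq(0, hd$n_samples - 1) / hd$sfreq
  epoch_set(data, times, hd$channels, trials, hd$sfreq)
}
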