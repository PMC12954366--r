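#' Tidy an accuracy timecourse into long format
#'
#' @param x an [accuracy_timecourse()].
#' @param ... unused.
#' @return A tibble with `unit`, `time`, `accuracy` plus constant
#'   `chance`, `scope`, `scheme` columns.
#' @export
tidy.accuracy_timecourse <- function(x, ...) {
  tibble::tibble(
    unit = rep(rownames(x$accuracy) %||%
                 as.character(seq_len(nrow(x$accuracy))),
               times = ncol(x$accuracy)),
    time = rep(x$times, each = nrow(x$accuracy)),
    accuracy = as.numeric(x$accuracy),
    chance = x$chance, scope = x$scope, scheme = x$scheme)
}

#' One-row summary of an accuracy timecourse
#'
#' @param x an [accuracy_timecourse()].
#' @param ... unused.
#' @return A tibble with unit/timepoint counts, chance, the time-mean
#'   accuracy and the peak of the unit-mean accuracy with its latency.
#' @export
glance.accuracy_timecourse <- function(x, ...) {
  gm <- colMeans(x$accuracy)
  tibble::tibble(
    n_units = nrow(x$accuracy), n_timepoints = ncol(x$accuracy),
    chance = x$chance, mean_accuracy = mean(x$accuracy),
    peak_accuracy = max(gm), peak_time = x$times[which.max(gm)],
    scheme = x$scheme, scope = x$scope)
}

#' Tidy a cluster permutation result
#'
#' @param x a `cluster_result`.
#' @param ... unused.
#' @return The cluster table (without index list-columns).
#' @export
tidy.cluster_result <- function(x, ...) {
  x$clusters[, setdiff(names(x$clusters), c("timepoints", "members"))]
}

#' One-row summary of a cluster permutation result
#'
#' @param x a `cluster_result`.
#' @param ... unused.
#' @return A tibble with cluster counts and the smallest p-value.
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$p < x$alpha),
    min_p = if (nrow(x$clusters) > 0) min(x$clusters$p) else NA_real_,
    alpha = x$alpha, n_perm = x$n_perm,
    cluster_threshold = x$cluster_threshold)
}

#' Tidy a searchlight result
#'
#' @param x a [searchlight_result()].
#' @param ... unused.
#' @return A long tibble with `unit`, `channel`, `time`, `accuracy`.
#' @export
tidy.searchlight_result <- function(x, ...) {
  d <- dim(x$accuracy)
  units <- dimnames(x$accuracy)[[1]] %||% as.character(seq_len(d[1]))
  tibble::tibble(
    unit = rep(units, times = d[2] * d[3]),
    channel = rep(rep(x$channels, each = d[1]), times = d[3]),
    time = rep(x$times, each = d[1] * d[2]),
    accuracy = as.numeric(x$accuracy))
}
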