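#' Accuracy timecourse container
#'
#' Per-test-unit (participant) decoding accuracy over time, the input to
#' all downstream statistics. Stored as a units x samples matrix plus
#' timebase and metadata; [tidy()] returns the long tibble form.
#'
#' @param accuracy numeric matrix units x samples in `[0, 1]`, rownames
#'   are unit labels.
#' @param times sample times, seconds.
#' @param sfreq sampling frequency, Hz.
#' @param chance chance level (0.25 four-class, 0.5 pairwise).
#' @param scope character scope tag (`"all"`, an ROI label, or a
#'   channel-neighbourhood description).
#' @param classes the decoded class labels.
#' @param scheme fold scheme tag.
#' @return An object of class `accuracy_timecourse`.
#' @export
accuracy_timecourse <- function(accuracy, times, sfreq, chance,
                                scope = "all", classes = EXPRESSIONS,
                                scheme = "within_loso") {
  accuracy <- as.matrix(accuracy)
  if (ncol(accuracy) != length(times)) {
    abort("`accuracy` must have one column per timepoint.")
  }
  if (any(accuracy < -1e-9 | accuracy > 1 + 1e-9, na.rm = TRUE)) {
    abort("Accuracies must lie in [0, 1].")
  }
  if (!chance %in% c(0.25, 0.5)) {
    abort("`chance` must be 0.25 (four-class) or 0.5 (pairwise).")
  }
  structure(list(accuracy = accuracy, times = as.numeric(times),
                 sfreq = sfreq, chance = chance, scope = scope,
                 classes = classes, scheme = scheme),
            class = "accuracy_timecourse")
}

#' @export
print.accuracy_timecourse <- function(x, ...) {
  cat(sprintf(
    "<accuracy_timecourse> %d units x %d timepoints (%s, scope %s, chance %g)\n",
    nrow(x$accuracy), ncol(x$accuracy), x$scheme, x$scope, x$chance))
  cat(sprintf("  mean accuracy %.3f, peak %.3f at %g ms\n",
              mean(x$accuracy), max(colMeans(x$accuracy)),
              1000 * x$times[which.max(colMeans(x$accuracy))]))
  invisible(x)
}

resolve_scope <- function(epochs, channel_scope) {
  if (identical(channel_scope, "all")) {
    return(list(idx = seq_along(epochs$channels), tag = "all"))
  }
  if (length(channel_scope) == 1L && channel_scope %in% roi_labels) {
    mon_like <- montage(epochs$channels,
                        matrix(0, length(epochs$channels), 3) + 1)
    chans <- suppressWarnings(roi_channels(mon_like, channel_scope))
    if (length(chans) == 0L) {
      abort(sprintf("ROI '%s' matches no channel of these epochs.",
                    channel_scope))
    }
    return(list(idx = match(chans, epochs$channels), tag = channel_scope))
  }
  miss <- setdiff(channel_scope, epochs$channels)
  if (length(miss) > 0L) {
    abort(sprintf("Unknown channel(s) in scope: %s.",
                  paste(miss, collapse = ", ")))
  }
  list(idx = match(channel_scope, epochs$channels),
       tag = paste(channel_scope, collapse = "+"))
}

check_classes <- function(classes) {
  if (!all(classes %in% EXPRESSIONS) || !length(classes) %in% c(2L, 4L)) {
    abort("`classes` must be 2 or 4 of: happy, angry, sad, neutral.")
  }
  sort(classes)
}

# Shared fold loop. `fun(train_cube, y0, test_cube, yte0)` returns either
# a vector (timecourse) or matrix (channels x time); results are averaged
# over folds within each test unit.
run_folds <- function(epochs, plan, classes, test_epochs, shuffle_labels,
                      rng_seed, fun) {
  test_epochs <- test_epochs %||% epochs
  audit_fold_plan(plan, epochs, test_epochs)
  classes <- check_classes(classes)
  units <- sort(unique(plan$test_unit))
  acc_by_unit <- vector("list", length(units))
  names(acc_by_unit) <- units
  for (i in seq_len(nrow(plan))) {
    tr_idx <- plan$train_idx[[i]]
    tr_meta <- epochs$trials[tr_idx, ]
    sel_tr <- tr_idx[tr_meta$correct & tr_meta$expression %in% classes]
    te_idx <- plan$test_idx[[i]]
    te_meta <- test_epochs$trials[te_idx, ]
    sel_te <- te_idx[te_meta$correct & te_meta$expression %in% classes]
    y <- epochs$trials$expression[sel_tr]
    if (length(unique(y)) < length(classes)) {
      abort(sprintf("Fold %d training set lacks class(es): %s.",
                    plan$fold[i],
                    paste(setdiff(classes, unique(y)), collapse = ", ")))
    }
    if (shuffle_labels) {
      y <- with_stream(rng_seed, sprintf("shuffle_fold_%d", i),
                       sample(y))
    }
    y0 <- match(y, classes) - 1L
    yte0 <- match(test_epochs$trials$expression[sel_te], classes) - 1L
    res <- fun(epochs$data[sel_tr, , , drop = FALSE], y0,
               test_epochs$data[sel_te, , , drop = FALSE], yte0)
    u <- plan$test_unit[i]
    acc_by_unit[[u]] <- c(acc_by_unit[[u]], list(res))
  }
  lapply(acc_by_unit, function(pieces) {
    Reduce(`+`, pieces) / length(pieces)
  })
}

#' Time-resolved decoding accuracy
#'
#' At each timepoint, fits the pooled-covariance LDA on the fold's
#' training trials using the selected channels' amplitudes as features,
#' and evaluates proportion correct on the fold's test trials. Fold
#' accuracies are averaged within test participant, so each row of the
#' result is one participant. Chance is `1/length(classes)`.
#'
#' @param epochs `eeg_epochs` the plan's training indices refer to.
#' @param plan a [fold_plan].
#' @param classes 2 or 4 expression labels.
#' @param channel_scope `"all"`, an ROI label (see [roi_channels()]), or
#'   a character vector of channel names.
#' @param test_epochs for cross-dataset plans, the epochs the test
#'   indices refer to.
#' @param shuffle_labels randomly permute training labels within each
#'   fold (an empirical null).
#' @param rng_seed seed used when `shuffle_labels = TRUE`.
#' @return An [accuracy_timecourse()].
#' @export
decode_timecourse <- function(epochs, plan, classes = EXPRESSIONS,
                              channel_scope = "all", test_epochs = NULL,
                              shuffle_labels = FALSE, rng_seed = 1) {
  stopifnot(inherits(epochs, "eeg_epochs"), inherits(plan, "fold_plan"))
  scope <- resolve_scope(epochs, channel_scope)
  classes <- check_classes(classes)
  k <- length(classes)
  te <- test_epochs %||% epochs
  res <- run_folds(
    epochs, plan, classes, test_epochs, shuffle_labels, rng_seed,
    function(tr, y0, tte, yte0) {
      as.numeric(lda_timecourse_cpp(
        tr[, scope$idx, , drop = FALSE], y0,
        tte[, scope$idx, , drop = FALSE], yte0, k))
    })
  acc <- do.call(rbind, res)
  rownames(acc) <- names(res)
  accuracy_timecourse(acc, te$times, te$sfreq, chance = 1 / k,
                      scope = scope$tag, classes = classes,
                      scheme = attr(plan, "scheme"))
}

#' Searchlight decoding result
#'
#' @param accuracy numeric array units x channels x samples.
#' @param channels channel names matching the second dimension.
#' @param times,sfreq timebase.
#' @param chance chance level.
#' @param classes decoded classes.
#' @param scheme fold scheme tag.
#' @return An object of class `searchlight_result`.
#' @export
searchlight_result <- function(accuracy, channels, times, sfreq, chance,
                               classes = EXPRESSIONS,
                               scheme = "within_loso") {
  stopifnot(length(dim(accuracy)) == 3L,
            dim(accuracy)[2] == length(channels),
            dim(accuracy)[3] == length(times))
  if (any(accuracy < -1e-9 | accuracy > 1 + 1e-9, na.rm = TRUE)) {
    abort("Accuracies must lie in [0, 1].")
  }
  structure(list(accuracy = accuracy, channels = channels,
                 times = as.numeric(times), sfreq = sfreq, chance = chance,
                 classes = classes, scheme = scheme),
            class = "searchlight_result")
}

#' @export
print.searchlight_result <- function(x, ...) {
  m <- apply(x$accuracy, 2, mean)
  cat(sprintf(
    "<searchlight_result> %d units x %d channels x %d timepoints (chance %g)\n",
    dim(x$accuracy)[1], dim(x$accuracy)[2], dim(x$accuracy)[3], x$chance))
  cat(sprintf("  best channel (time-averaged): %s (%.3f)\n",
              x$channels[which.max(m)], max(m)))
  invisible(x)
}

#' Spatio-temporal searchlight decoding
#'
#' Runs [decode_timecourse()] repeatedly, once per channel, on the
#' electrode cluster formed by the channel and its immediately adjacent
#' neighbours, yielding a units x channels x samples accuracy array that
#' maps where and when the scalp carries class information.
#'
#' @inheritParams decode_timecourse
#' @param adjacency channel adjacency from [build_adjacency()]; its
#'   dimnames must cover the epochs' channels.
#' @return A [searchlight_result()].
#' @export
searchlight_decode <- function(epochs, plan, classes = EXPRESSIONS,
                               adjacency = NULL, test_epochs = NULL,
                               shuffle_labels = FALSE, rng_seed = 1) {
  stopifnot(inherits(epochs, "eeg_epochs"), inherits(plan, "fold_plan"))
  if (is.null(adjacency)) {
    abort("`adjacency` is required; build it with build_adjacency().")
  }
  if (!all(epochs$channels %in% rownames(adjacency))) {
    abort("Adjacency does not cover all epoch channels.")
  }
  classes <- check_classes(classes)
  k <- length(classes)
  nbrs <- lapply(epochs$channels, function(ch) {
    hood <- intersect(channel_neighborhood(adjacency, ch), epochs$channels)
    if (length(hood) < 2L) {
      abort(sprintf("Channel %s has no neighbours within the epochs.", ch))
    }
    match(hood, epochs$channels) - 1L
  })
  te <- test_epochs %||% epochs
  res <- run_folds(
    epochs, plan, classes, test_epochs, shuffle_labels, rng_seed,
    function(tr, y0, tte, yte0) {
      lda_searchlight_cpp(tr, y0, tte, yte0, nbrs, k)
    })
  acc <- array(0, c(length(res), length(epochs$channels),
                    length(te$times)))
  for (i in seq_along(res)) acc[i, , ] <- res[[i]]
  dimnames(acc) <- list(names(res), epochs$channels, NULL)
  searchlight_result(acc, epochs$channels, te$times, te$sfreq,
                     chance = 1 / k, classes = classes,
                     scheme = attr(plan, "scheme"))
}
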