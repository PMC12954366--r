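#' Cross-validation plans
#'
#' A fold plan is a tibble with one row per fold: integer list-columns
#' `train_idx` and `test_idx` (trial row indices), the `test_unit`
#' (participant id) the fold contributes to, and bookkeeping columns.
#' The attribute `scheme` is `"within_loso"` (nested
#' leave-one-participant-out / leave-one-stimulus-out) or
#' `"cross_dataset"` (train on the aggregate of one experiment, test on
#' each participant of the other). For cross plans, `train_idx` indexes
#' the training epochs and `test_idx` the test epochs.
#'
#' @name fold_plan
NULL

new_fold_plan <- function(df, scheme) {
  structure(tibble::as_tibble(df), scheme = scheme,
            class = c("fold_plan", class(tibble::tibble())))
}

#' Nested within-experiment folds
#'
#' One fold per participant x stimulus level: the classifier never sees
#' the test participant or the test stimulus during training. For
#' designs with stimulus sex metadata, sex-balanced training is
#' available: training uses six of eight identities, three per sex.
#' Removing the held-out identity leaves its sex under-represented, so
#' one identity of the opposite sex is additionally excluded, chosen
#' deterministically in round-robin over folds.
#'
#' @param epochs an `eeg_epochs` (normally pseudo-trials).
#' @param sex_balance if `TRUE`, balance training identities by sex;
#'   requires a `stimulus_sex` trial column.
#' @return A [fold_plan] with `n_participants * n_stimuli` rows.
#' @export
plan_within_folds <- function(epochs, sex_balance = FALSE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  tr <- epochs$trials
  participants <- sort(unique(tr$participant_id))
  stimuli <- sort(unique(tr$stimulus_id))
  if (length(participants) < 2L) abort("Need at least 2 participants.")
  if (length(stimuli) < 2L) abort("Need at least 2 stimulus levels.")
  if (sex_balance && !"stimulus_sex" %in% names(tr)) {
    abort("Sex-balanced folds require a `stimulus_sex` trial column.")
  }
  sex_of <- if (sex_balance) {
    s <- unique(tr[, c("stimulus_id", "stimulus_sex")])
    setNames(s$stimulus_sex, s$stimulus_id)
  }
  folds <- list()
  f <- 0L
  for (p_i in seq_along(participants)) {
    p <- participants[p_i]
    for (s_i in seq_along(stimuli)) {
      s <- stimuli[s_i]
      excluded <- s
      if (sex_balance) {
        partners <- sort(stimuli[sex_of[stimuli] != sex_of[[s]]])
        if (length(partners) > 0L) {
          excluded <- c(s, partners[(p_i + s_i) %% length(partners) + 1L])
        }
      }
      train_stims <- setdiff(stimuli, excluded)
      f <- f + 1L
      folds[[f]] <- tibble::tibble(
        fold = f, test_unit = p, test_stimulus = s,
        train_idx = list(which(tr$participant_id != p &
                                 tr$stimulus_id %in% train_stims)),
        test_idx = list(which(tr$participant_id == p &
                                tr$stimulus_id == s)))
    }
  }
  new_fold_plan(dplyr::bind_rows(folds), "within_loso")
}

#' Cross-dataset folds
#'
#' Trains on all pseudo-trials of one experiment (every participant,
#' every stimulus) and tests on each participant of the other
#' experiment individually; one fold per test participant.
#'
#' @param train_epochs,test_epochs `eeg_epochs` from two experiments
#'   with disjoint dataset and participant ids.
#' @return A [fold_plan] with one row per test-set participant.
#' @export
plan_cross_folds <- function(train_epochs, test_epochs) {
  stopifnot(inherits(train_epochs, "eeg_epochs"),
            inherits(test_epochs, "eeg_epochs"))
  tr_ids <- unique(train_epochs$trials$dataset_id)
  te_ids <- unique(test_epochs$trials$dataset_id)
  if (length(intersect(tr_ids, te_ids)) > 0L) {
    abort("Train and test epochs must come from different datasets.")
  }
  common <- intersect(unique(train_epochs$trials$participant_id),
                      unique(test_epochs$trials$participant_id))
  if (length(common) > 0L) {
    abort(sprintf(
      "Participant id(s) %s appear in both datasets; aggregation would be ambiguous.",
      paste(common, collapse = ", ")))
  }
  if (!setequal(unique(train_epochs$trials$expression),
                unique(test_epochs$trials$expression))) {
    abort("Train and test datasets must share expression labels.")
  }
  participants <- sort(unique(test_epochs$trials$participant_id))
  all_train <- seq_len(nrow(train_epochs$trials))
  folds <- lapply(seq_along(participants), function(i) {
    tibble::tibble(
      fold = i, test_unit = participants[i], test_stimulus = NA_character_,
      train_idx = list(all_train),
      test_idx = list(which(test_epochs$trials$participant_id ==
                              participants[i])))
  })
  new_fold_plan(dplyr::bind_rows(folds), "cross_dataset")
}

#' Audit a fold plan for information leakage
#'
#' Asserts the scheme invariants: within folds share no participant and
#' no stimulus between train and test; cross folds share no dataset.
#' Called internally by [decode_timecourse()]; exposed for explicit
#' checks.
#'
#' @param plan a [fold_plan].
#' @param epochs the epochs the plan's training indices refer to.
#' @param test_epochs for cross plans, the epochs the test indices refer
#'   to; defaults to `epochs`.
#' @return A tibble with one row per fold and logical `leak_free`,
#'   invisibly. Errors if any fold leaks.
#' @export
audit_fold_plan <- function(plan, epochs, test_epochs = NULL) {
  stopifnot(inherits(plan, "fold_plan"))
  test_epochs <- test_epochs %||% epochs
  scheme <- attr(plan, "scheme")
  res <- lapply(seq_len(nrow(plan)), function(i) {
    tr <- epochs$trials[plan$train_idx[[i]], ]
    te <- test_epochs$trials[plan$test_idx[[i]], ]
    leak <- if (scheme == "within_loso") {
      length(intersect(tr$participant_id, te$participant_id)) > 0L ||
        length(intersect(tr$stimulus_id, te$stimulus_id)) > 0L
    } else {
      length(intersect(tr$dataset_id, te$dataset_id)) > 0L
    }
    overlap <- if (identical(epochs, test_epochs)) {
      length(intersect(plan$train_idx[[i]], plan$test_idx[[i]])) > 0L
    } else {
      FALSE
    }
    tibble::tibble(fold = plan$fold[i], leak_free = !(leak || overlap))
  })
  res <- dplyr::bind_rows(res)
  if (!all(res$leak_free)) {
    abort(sprintf("Fold plan leaks information in fold(s): %s.",
                  paste(res$fold[!res$leak_free], collapse = ", ")))
  }
  invisible(res)
}
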