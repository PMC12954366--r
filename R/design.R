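#' Experimental design specification
#'
#' Describes one experiment: how many participants, which stimulus
#' levels (face identities or emoji platforms), how often each unique
#' image (stimulus x expression) repeats, and the recording timebase.
#' Total trials per participant are
#' `length(stimulus_levels) * length(expressions) * reps_per_image`.
#'
#' @param n_participants number of participants.
#' @param stimulus_levels character vector of stimulus identifiers.
#' @param reps_per_image presentations of each unique image.
#' @param dataset_id label carried into the trial table.
#' @param sfreq sampling frequency, Hz.
#' @param window epoch window `c(tmin, tmax)` in seconds; sampled on the
#'   half-open interval `[tmin, tmax)` so the standard -0.2..1.2 s window
#'   at 200 Hz has exactly 280 samples.
#' @param expressions expression labels (fixed four-class set).
#' @param stimulus_sex optional named character vector giving each
#'   stimulus level's sex (`"male"`/`"female"`), used by sex-balanced
#'   fold construction.
#' @param participant_prefix prefix for generated participant ids.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n_participants, stimulus_levels, reps_per_image,
                        dataset_id, sfreq = 200, window = c(-0.2, 1.2),
                        expressions = EXPRESSIONS, stimulus_sex = NULL,
                        participant_prefix = "S") {
  assert_scalar_number(n_participants, "n_participants", lower = 1)
  assert_scalar_number(reps_per_image, "reps_per_image", lower = 1)
  stimulus_levels <- as.character(stimulus_levels)
  if (length(stimulus_levels) < 1L || anyDuplicated(stimulus_levels)) {
    abort("`stimulus_levels` must be non-empty and unique.")
  }
  if (!all(expressions %in% EXPRESSIONS)) {
    abort("`expressions` must be drawn from the four-class label set.")
  }
  if (length(window) != 2L || window[1] >= window[2]) {
    abort("`window` must be c(tmin, tmax) with tmin < tmax.")
  }
  if (!is.null(stimulus_sex)) {
    if (!setequal(names(stimulus_sex), stimulus_levels)) {
      abort("`stimulus_sex` must be named by the stimulus levels.")
    }
    stimulus_sex <- stimulus_sex[stimulus_levels]
  }
  structure(list(
    n_participants = as.integer(n_participants),
    stimulus_levels = stimulus_levels,
    expressions = expressions,
    reps_per_image = as.integer(reps_per_image),
    dataset_id = as.character(dataset_id),
    sfreq = sfreq,
    window = as.numeric(window),
    stimulus_sex = stimulus_sex,
    participant_prefix = participant_prefix
  ), class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf(
    "<design_spec> '%s': %d participants, %d stimuli x %d expressions x %d reps = %d trials\n",
    x$dataset_id, x$n_participants, length(x$stimulus_levels),
    length(x$expressions), x$reps_per_image, design_trial_count(x)))
  invisible(x)
}

#' Trials per participant implied by a design
#' @param design a `design_spec`.
#' @return integer trial count.
#' @export
design_trial_count <- function(design) {
  length(design$stimulus_levels) * length(design$expressions) *
    design$reps_per_image
}

#' The real-faces study design
#'
#' Eight face identities (four male, four female), four expressions, 12
#' presentations per image: 384 trials per participant, 96 per
#' expression, 48 per identity; 24 participants.
#'
#' @param n_participants number of participants (24 in the study).
#' @param sfreq,window timebase, see [design_spec()].
#' @return A `design_spec`.
#' @export
real_faces_design <- function(n_participants = 24, sfreq = 200,
                              window = c(-0.2, 1.2)) {
  ids <- c("AM10", "AM17", "AM24", "AM31", "AF07", "AF15", "AF26", "AF28")
  sex <- setNames(rep(c("male", "female"), each = 4), ids)
  design_spec(n_participants, ids, reps_per_image = 12,
              dataset_id = "real", sfreq = sfreq, window = window,
              stimulus_sex = sex, participant_prefix = "R")
}

#' The emoji study design
#'
#' Six emoji platforms, four expressions, 12 presentations per image:
#' 288 trials per participant, 72 per expression, 48 per platform; 25
#' participants.
#'
#' @inheritParams real_faces_design
#' @return A `design_spec`.
#' @export
emoji_faces_design <- function(n_participants = 25, sfreq = 200,
                               window = c(-0.2, 1.2)) {
  platforms <- c("Apple", "EmojiOne", "Facebook", "NotoKitKat", "NotoPie",
                 "Twemoji")
  design_spec(n_participants, platforms, reps_per_image = 12,
              dataset_id = "emoji", sfreq = sfreq, window = window,
              participant_prefix = "E")
}
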