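#' Evoked-signal specification for the synthetic generator
#'
#' Describes the class-discriminative evoked component injected into
#' synthetic experiments. The component is a sum of temporal Gaussian
#' bumps clustered around `peak_s`, hard-zeroed before `onset_s` so that
#' no expression information exists in the signal before the nominal
#' onset, weighted by per-class amplitude vectors that are mutually
#' orthogonal (so all pairwise contrasts are linearly decodable), and
#' projected onto the scalp through spatial Gaussians centred near
#' `topography_center`.
#'
#' Two such components enter each experiment: a *shared* component
#' (weight `shared_weight`) identical across the two experiments of a
#' pair, carrying the transferable expression code, and a *format*
#' component (weight `format_weight`) redrawn per experiment, carrying
#' expression information that does not generalise across stimulus
#' formats.
#'
#' @param onset_s signal onset, seconds after stimulus.
#' @param peak_s signal peak, seconds; must exceed `onset_s`.
#' @param width_s temporal Gaussian SD, seconds.
#' @param shared_weight,format_weight non-negative component weights.
#' @param amplitude_uv peak amplitude of a unit-weight component, µV.
#' @param topography_center channel name at the centre of the spatial
#'   pattern.
#' @param topography_sd spatial Gaussian SD, radians on the projected
#'   scalp.
#' @return An object of class `signal_spec`.
#' @export
signal_spec <- function(onset_s = 0.10, peak_s = 0.155, width_s = 0.025,
                        shared_weight = 1, format_weight = 1,
                        amplitude_uv = 2.5, topography_center = "PO8",
                        topography_sd = 0.5) {
  assert_scalar_number(onset_s, "onset_s")
  assert_scalar_number(peak_s, "peak_s")
  if (onset_s >= peak_s) abort("`onset_s` must precede `peak_s`.")
  assert_scalar_number(width_s, "width_s", lower = 1e-6)
  assert_scalar_number(shared_weight, "shared_weight", lower = 0)
  assert_scalar_number(format_weight, "format_weight", lower = 0)
  assert_scalar_number(amplitude_uv, "amplitude_uv", lower = 1e-12)
  assert_scalar_number(topography_sd, "topography_sd", lower = 1e-6)
  structure(list(onset_s = onset_s, peak_s = peak_s, width_s = width_s,
                 shared_weight = shared_weight,
                 format_weight = format_weight,
                 amplitude_uv = amplitude_uv,
                 topography_center = topography_center,
                 topography_sd = topography_sd),
            class = "signal_spec")
}

#' Noise specification for the synthetic generator
#'
#' @param trial_noise_sd per-sample noise SD, µV.
#' @param spatial_corr_length spatial correlation length of the noise on
#'   the projected scalp (radians); covariance decays as
#'   `exp(-d^2 / l^2)`.
#' @param temporal_exponent exponent `a` of the `1/f^a` noise spectrum,
#'   in `[0, 2]` (0 = white, 1 = pink).
#' @param participant_gain_sd SD of the multiplicative participant gain
#'   (mean 1) applied to the evoked signal.
#' @param participant_code_sd weight of a participant-specific
#'   class-discriminative component (relative to the common template's
#'   unit scale, multiplied by the signal amplitude). Individual
#'   expression codes are only partially shared across people, which is
#'   why leave-one-participant-out decoding is harder than
#'   within-participant decoding; this term injects that idiosyncrasy.
#' @param stimulus_effect_sd SD of the per-stimulus evoked offset, µV;
#'   constant across trials of the same stimulus and shared by all of
#'   that stimulus's expressions, so it carries no expression
#'   information but breaks stimulus-level generalisation.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(trial_noise_sd = 8, spatial_corr_length = 0.6,
                       temporal_exponent = 1, participant_gain_sd = 0.2,
                       stimulus_effect_sd = 1, participant_code_sd = 0.4) {
  assert_scalar_number(trial_noise_sd, "trial_noise_sd", lower = 0)
  assert_scalar_number(spatial_corr_length, "spatial_corr_length",
                       lower = 1e-9)
  assert_scalar_number(temporal_exponent, "temporal_exponent",
                       lower = 0, upper = 2)
  assert_scalar_number(participant_gain_sd, "participant_gain_sd",
                       lower = 0)
  assert_scalar_number(stimulus_effect_sd, "stimulus_effect_sd", lower = 0)
  assert_scalar_number(participant_code_sd, "participant_code_sd",
                       lower = 0)
  structure(list(trial_noise_sd = trial_noise_sd,
                 spatial_corr_length = spatial_corr_length,
                 temporal_exponent = temporal_exponent,
                 participant_gain_sd = participant_gain_sd,
                 stimulus_effect_sd = stimulus_effect_sd,
                 participant_code_sd = participant_code_sd),
            class = "noise_spec")
}

# One unit-amplitude evoked component: classes x channels x samples.
# K = n_classes temporal bumps straddling peak_s, orthonormal class
# weights (QR with fixed sign), spatial Gaussians around the topography
# centre. Zero before onset_s. `center_jitter_sd` displaces the whole
# component's centre: ~0 for the shared component (anchored at the
# canonical site), wide for format- and participant-specific components
# whose scalp sites are not tied to the shared code's.
class_component <- function(signal, mon, times, n_classes, seed,
                            center_jitter_sd = signal$topography_sd / 10,
                            width_scale = 1) {
  k <- n_classes
  xy <- project_scalp(mon)
  if (!signal$topography_center %in% mon$channels) {
    abort(sprintf("Unknown topography_center channel '%s'.",
                  signal$topography_center))
  }
  center <- xy[signal$topography_center, ]
  with_stream(seed, "component", {
    # orthonormal class weight vectors
    v <- qr.Q(qr(matrix(rnorm(k * k), k, k)))
    v <- sweep(v, 2, sign(diag(v) + (diag(v) == 0)), `*`)
    v <- t(v) # rows = classes
    # spatial maps: concentric Gaussians of graded width at the
    # (possibly displaced) centre, plus a slight per-map jitter for
    # asymmetry; distinct widths keep the maps linearly independent
    # while the accuracy peak stays at the component's centre
    center <- center + rnorm(2, sd = center_jitter_sd)
    jit <- matrix(rnorm(2 * k, sd = signal$topography_sd / 10), k, 2)
    widths <- width_scale * signal$topography_sd *
      (0.7 + 0.2 * (seq_len(k) - 1))
    tops <- vapply(seq_len(k), function(i) {
      d2 <- (xy[, 1] - (center[1] + jit[i, 1]))^2 +
        (xy[, 2] - (center[2] + jit[i, 2]))^2
      exp(-d2 / (2 * widths[i]^2))
    }, numeric(nrow(xy))) # channels x K
    # temporal bumps tightly clustered at the peak, hard-zeroed before
    # onset; the narrow spacing keeps the discriminability envelope
    # peaked at peak_s
    offs <- (seq_len(k) - (k + 1) / 2) * signal$width_s / 4
    bumps <- vapply(offs, function(o) {
      b <- exp(-(times - (signal$peak_s + o))^2 / (2 * signal$width_s^2))
      b[times < signal$onset_s] <- 0
      b
    }, numeric(length(times))) # samples x K
    comp <- array(0, c(k, nrow(xy), length(times)))
    for (c_i in seq_len(k)) {
      m <- matrix(0, nrow(xy), length(times))
      for (b_i in seq_len(k)) {
        m <- m + v[c_i, b_i] * outer(tops[, b_i], bumps[, b_i])
      }
      comp[c_i, , ] <- m
    }
    # unit normalisation: largest absolute class-template value is 1
    peak <- max(abs(comp))
    if (peak > 0) comp <- comp / peak
    comp
  })
}

#' Build per-class evoked templates
#'
#' Combines the shared and format components into per-class channels x
#' samples templates scaled to `amplitude_uv`:
#' `amplitude * (shared_weight * shared + format_weight * format)`.
#'
#' @param signal a [signal_spec()].
#' @param mon an `eeg_montage`.
#' @param times sample times (seconds); defaults to the standard
#'   -0.2..1.2 s window at 200 Hz.
#' @param n_classes number of classes (4 expressions).
#' @param rng_seed integer seed; the shared and format components draw
#'   from independent sub-streams.
#' @param shared_component optional pre-built shared component (classes x
#'   channels x samples, unit scale) as produced for the first member of
#'   an experiment pair; when `NULL` it is drawn from the seed.
#' @return A `class_templates` object: list with `template` (classes x
#'   channels x samples, µV), the unit-scale `shared` and `format`
#'   components, and the class labels.
#' @export
make_class_templates <- function(signal, mon, times = NULL, n_classes = 4,
                                 rng_seed = 1, shared_component = NULL) {
  stopifnot(inherits(signal, "signal_spec"), inherits(mon, "eeg_montage"))
  if (is.null(times)) {
    n <- window_samples(-0.2, 1.2, 200)
    times <- -0.2 + seq(0, n - 1) / 200
  }
  if (is.null(shared_component)) {
    shared_component <- class_component(signal, mon, times, n_classes,
                                        substream_seed(rng_seed, "shared"))
  }
  format_component <- class_component(signal, mon, times, n_classes,
                                      substream_seed(rng_seed, "format"),
                                      center_jitter_sd =
                                        2 * signal$topography_sd,
                                      width_scale = 0.5)
  template <- signal$amplitude_uv *
    (signal$shared_weight * shared_component +
       signal$format_weight * format_component)
  structure(list(template = template, shared = shared_component,
                 format = format_component,
                 classes = EXPRESSIONS[seq_len(n_classes)],
                 times = times, channels = mon$channels),
            class = "class_templates")
}

# Spatio-temporally correlated noise for one trial: channels x samples.
# `chol_l` is the Cholesky factor of the spatial correlation matrix;
# `tshape` the unit-power 1/f^a spectral weights (length n_samples).
correlated_noise <- function(n_ch, n_t, chol_l, tshape, sd) {
  e <- matrix(rnorm(n_ch * n_t), n_t, n_ch)
  if (!is.null(tshape)) {
    e <- Re(mvfft(mvfft(e) * tshape, inverse = TRUE)) / n_t
  }
  sd * t(e %*% chol_l) # channels x samples
}

spectral_weights <- function(n_t, alpha) {
  if (alpha <= 0) return(NULL)
  k <- c(0, seq_len(n_t - 1))
  f <- pmin(k, n_t - k) # two-sided frequency index
  w <- c(1, f[-1]^(-alpha / 2)) # DC weighted as the first bin
  w / sqrt(mean(w^2)) # unit output variance
}

#' Generate one synthetic experiment
#'
#' Simulates single-trial EEG epochs for every participant of a design.
#' Each trial is
#' `gain_p * (class template + stimulus offset) + noise`, where `gain_p`
#' is a per-participant multiplicative gain, the stimulus offset is a
#' smooth per-stimulus evoked deviation common to that stimulus's trials
#' (no expression information), and the noise is spatio-temporally
#' correlated (`1/f^a` spectrum, squared-exponential spatial
#' covariance). All trials are flagged `correct = TRUE`: the paradigm
#' re-inserts incorrectly answered trials, so a complete dataset
#' contains the full design count of correct trials; the pipeline still
#' filters on the flag.
#'
#' @param design a [design_spec()].
#' @param signal a [signal_spec()].
#' @param noise a [noise_spec()].
#' @param mon an `eeg_montage`.
#' @param shared_templates optional unit-scale shared component from
#'   [make_class_templates()] (its `$shared` element) to tie the
#'   experiment to a partner experiment.
#' @param rng_seed integer seed. Named sub-streams (`templates`,
#'   `stimuli`, `participants`, `noise`) are derived from it.
#' @return An `eeg_epochs` with
#'   `n_participants * levels * expressions * reps` trials.
#' @export
#' @examples
#' mon <- biosemi64_montage()
#' des <- design_spec(2, c("a", "b"), 3, "demo", window = c(-0.2, 0.4))
#' ep <- generate_experiment(des, signal_spec(), noise_spec(), mon,
#'                           rng_seed = 1)
#' dim(ep)
generate_experiment <- function(design, signal, noise, mon,
                                shared_templates = NULL, rng_seed = 1) {
  stopifnot(inherits(design, "design_spec"), inherits(signal, "signal_spec"),
            inherits(noise, "noise_spec"), inherits(mon, "eeg_montage"))
  n_samp <- window_samples(design$window[1], design$window[2], design$sfreq)
  times <- design$window[1] + seq(0, n_samp - 1) / design$sfreq
  n_ch <- length(mon$channels)
  classes <- design$expressions
  n_classes <- length(classes)

  tmpl <- make_class_templates(
    signal, mon, times = times, n_classes = n_classes,
    rng_seed = substream_seed(rng_seed, "templates"),
    shared_component = shared_templates)

  # per-stimulus evoked offsets: temporally smoothed white patterns,
  # zero before stimulus onset
  stim_levels <- design$stimulus_levels
  post <- times >= 0
  smooth_k <- max(1L, round(0.025 * design$sfreq))
  kern <- exp(-((seq(-3 * smooth_k, 3 * smooth_k)) / smooth_k)^2 / 2)
  kern <- kern / sum(kern)
  stim_offsets <- with_stream(rng_seed, "stimuli", {
    lapply(stim_levels, function(s) {
      m <- matrix(rnorm(n_ch * n_samp, sd = noise$stimulus_effect_sd),
                  n_ch, n_samp)
      m <- t(apply(m, 1, function(r) {
        stats::convolve(r, kern, type = "open")[
          (3 * smooth_k + 1):(3 * smooth_k + n_samp)]
      }))
      m[, !post] <- 0
      m
    })
  })
  names(stim_offsets) <- stim_levels

  gains <- with_stream(rng_seed, "participants", {
    rnorm(design$n_participants, mean = 1, sd = noise$participant_gain_sd)
  })

  # trial bookkeeping
  per_part <- design_trial_count(design)
  grid <- expand.grid(rep = seq_len(design$reps_per_image),
                      expression = classes, stimulus_id = stim_levels,
                      stringsAsFactors = FALSE)
  participant_ids <- sprintf("%s%02d", design$participant_prefix,
                             seq_len(design$n_participants))

  xy <- project_scalp(mon)
  d2 <- as.matrix(stats::dist(xy))^2
  k_sp <- exp(-d2 / noise$spatial_corr_length^2)
  chol_l <- chol(k_sp + diag(1e-8, n_ch))
  tshape <- spectral_weights(n_samp, noise$temporal_exponent)

  data <- array(0, c(design$n_participants * per_part, n_ch, n_samp))
  trials <- vector("list", design$n_participants)
  class_idx <- match(grid$expression, classes)
  stim_idx <- match(grid$stimulus_id, stim_levels)
  # evoked part common to all participants up to the gain: trials x ch x t
  offs_arr <- array(0, c(length(stim_levels), n_ch, n_samp))
  for (s in seq_along(stim_levels)) offs_arr[s, , ] <- stim_offsets[[s]]
  evoked <- tmpl$template[class_idx, , , drop = FALSE] +
    offs_arr[stim_idx, , , drop = FALSE]
  # participant-idiosyncratic class codes: same construction as the
  # common component, drawn per participant at displaced, more local
  # sites. Scaled by the overall code weight so that a signal-free
  # configuration (both component weights zero) stays at chance.
  code_weight <- sqrt(signal$shared_weight^2 + signal$format_weight^2)
  pcode <- if (noise$participant_code_sd > 0 && code_weight > 0) {
    lapply(seq_len(design$n_participants), function(p) {
      noise$participant_code_sd * code_weight * signal$amplitude_uv *
        class_component(signal, mon, times, n_classes,
                        substream_seed(rng_seed, sprintf("pcode_%d", p)),
                        center_jitter_sd = 2 * signal$topography_sd,
                        width_scale = 0.5)
    })
  }
  with_stream(rng_seed, "noise", {
    for (p in seq_len(design$n_participants)) {
      rows <- (p - 1L) * per_part + seq_len(per_part)
      evoked_p <- if (is.null(pcode)) evoked else
        evoked + pcode[[p]][class_idx, , , drop = FALSE]
      # one draw of spatio-temporally correlated noise for all trials
      e <- matrix(rnorm(n_samp * n_ch * per_part), n_samp,
                  n_ch * per_part)
      if (!is.null(tshape)) {
        e <- Re(mvfft(mvfft(e) * tshape, inverse = TRUE)) / n_samp
      }
      dim(e) <- c(n_samp, n_ch, per_part)
      e <- matrix(aperm(e, c(3, 2, 1)), per_part * n_ch, n_samp)
      dim(e) <- c(per_part, n_ch, n_samp)
      for (t in seq_len(n_samp)) {
        e[, , t] <- e[, , t] %*% chol_l
      }
      data[rows, , ] <- gains[p] * evoked_p +
        noise$trial_noise_sd * e
      trials[[p]] <- tibble::tibble(
        participant_id = participant_ids[p],
        dataset_id = design$dataset_id,
        expression = grid$expression,
        stimulus_id = grid$stimulus_id,
        correct = TRUE,
        is_pseudotrial = FALSE)
    }
  })
  trials <- dplyr::bind_rows(trials)
  if (!is.null(design$stimulus_sex)) {
    trials$stimulus_sex <- unname(design$stimulus_sex[trials$stimulus_id])
  }
  epoch_set(data, times, mon$channels, trials, design$sfreq)
}

#' Generate a linked pair of synthetic experiments
#'
#' The two experiments share the same unit-scale shared component
#' (weighted by `signal$shared_weight`), draw independent format
#' components (weighted by `signal$format_weight`), and have independent
#' participants, stimulus effects and noise. With `shared_weight > 0`
#' a classifier trained on one experiment transfers to the other; with
#' `shared_weight = 0` and `format_weight > 0` each experiment is
#' decodable internally but nothing transfers.
#'
#' @param design_a,design_b [design_spec()]s with distinct `dataset_id`
#'   and identical timebase.
#' @inheritParams generate_experiment
#' @return A named list with `eeg_epochs` elements `a` and `b`.
#' @export
generate_experiment_pair <- function(design_a, design_b, signal, noise,
                                     mon, rng_seed = 1) {
  if (identical(design_a$dataset_id, design_b$dataset_id)) {
    abort("The two designs must carry distinct dataset ids.")
  }
  if (!isTRUE(all.equal(design_a$window, design_b$window)) ||
      design_a$sfreq != design_b$sfreq) {
    abort("The two designs must share sfreq and epoch window.")
  }
  if (!setequal(design_a$expressions, design_b$expressions)) {
    abort("The two designs must share the expression label set.")
  }
  n_samp <- window_samples(design_a$window[1], design_a$window[2],
                           design_a$sfreq)
  times <- design_a$window[1] + seq(0, n_samp - 1) / design_a$sfreq
  shared <- class_component(signal, mon, times,
                            length(design_a$expressions),
                            substream_seed(rng_seed, "pair_shared"))
  list(
    a = generate_experiment(design_a, signal, noise, mon,
                            shared_templates = shared,
                            rng_seed = substream_seed(rng_seed, "exp_a")),
    b = generate_experiment(design_b, signal, noise, mon,
                            shared_templates = shared,
                            rng_seed = substream_seed(rng_seed, "exp_b")))
}
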