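test_that("study designs reproduce the published trial arithmetic", {
  real <- real_faces_design()
  emoji <- emoji_faces_design()
  expect_equal(design_trial_count(real), 384)
  expect_equal(design_trial_count(emoji), 288)
  expect_equal(real$n_participants, 24)
  expect_equal(emoji$n_participants, 25)

  # generated per-participant counts follow the design exactly
  mon <- std_montage()
  short <- c(-0.2, -0.15) # counts do not depend on the window
  ep <- generate_experiment(real_faces_design(1, window = short),
                            signal_spec(), noise_spec(), mon, rng_seed = 1)
  expect_equal(nrow(ep$trials), 384)
  expect_true(all(table(ep$trials$expression) == 96))
  expect_true(all(table(ep$trials$stimulus_id) == 48))
  ep2 <- generate_experiment(emoji_faces_design(1, window = short),
                             signal_spec(), noise_spec(), mon,
                             rng_seed = 1)
  expect_equal(nrow(ep2$trials), 288)
  expect_true(all(table(ep2$trials$expression) == 72))
  expect_true(all(table(ep2$trials$stimulus_id) == 48))
  expect_true(all(ep2$trials$correct))
})

test_that("generation is deterministic in the seed", {
  mon <- std_montage()
  des <- small_design(2, 2, 3, window = c(-0.1, 0.1))
  a <- generate_experiment(des, signal_spec(), noise_spec(), mon,
                           rng_seed = 7)
  b <- generate_experiment(des, signal_spec(), noise_spec(), mon,
                           rng_seed = 7)
  c <- generate_experiment(des, signal_spec(), noise_spec(), mon,
                           rng_seed = 8)
  expect_identical(a$data, b$data)
  expect_identical(a$trials, b$trials)
  expect_false(identical(a$data, c$data))
})

test_that("class templates honour weights, support and discriminability", {
  mon <- std_montage()
  times <- -0.2 + (0:139) / 200
  zero <- make_class_templates(signal_spec(shared_weight = 0,
                                           format_weight = 0),
                               mon, times = times, rng_seed = 1)
  expect_true(all(zero$template == 0))

  tm <- make_class_templates(signal_spec(shared_weight = 1,
                                         format_weight = 0.5),
                             mon, times = times, rng_seed = 1)
  # no class information before the onset (and none pre-stimulus)
  expect_true(all(tm$template[, , times < 0.1] == 0))
  # all pairwise class contrasts carry energy near the peak
  sig <- signal_spec()
  win <- times >= sig$onset_s & times <= sig$onset_s + 4 * sig$width_s
  for (a in 1:3) for (b in (a + 1):4) {
    expect_gt(max(abs(tm$template[a, , win] - tm$template[b, , win])), 0)
  }
  expect_error(
    make_class_templates(signal_spec(topography_center = "Zz9"), mon,
                         times = times), "Zz9")
})

test_that("trial averages converge to the class templates", {
  mon <- std_montage()
  des <- design_spec(1, "s1", reps_per_image = 40, dataset_id = "conv",
                     window = c(-0.1, 0.3))
  sig <- signal_spec(amplitude_uv = 3, format_weight = 0)
  noi <- noise_spec(trial_noise_sd = 1, participant_gain_sd = 0,
                    stimulus_effect_sd = 0, participant_code_sd = 0)
  ep <- generate_experiment(des, sig, noi, mon, rng_seed = 3)
  times <- ep$times
  tmpl <- make_class_templates(sig, mon, times = times,
                               rng_seed = substream_seed(3, "templates"))
  for (cl in c("happy", "neutral")) {
    idx <- which(ep$trials$expression == cl)
    avg <- colMeans(ep$data[idx, , , drop = FALSE], dims = 1)
    want <- tmpl$template[match(cl, tmpl$classes), , ]
    expect_lt(max(abs(avg - want)), 5 * 1 / sqrt(40)) # generous LLN bound
  }
})

test_that("noise correlation decays with sensor distance", {
  mon <- std_montage()
  des <- design_spec(1, "s1", reps_per_image = 30, dataset_id = "noise",
                     window = c(-0.1, 0.3))
  sig <- signal_spec(shared_weight = 0, format_weight = 0)
  noi <- noise_spec(trial_noise_sd = 5, stimulus_effect_sd = 0,
                    participant_gain_sd = 0)
  ep <- generate_experiment(des, sig, noi, mon, rng_seed = 5)
  flat <- matrix(aperm(ep$data, c(3, 1, 2)),
                 dim(ep$data)[1] * dim(ep$data)[3], dim(ep$data)[2])
  cc <- stats::cor(flat)
  xy <- project_scalp(mon)
  d <- as.matrix(stats::dist(xy))
  near <- d > 0 & d < 0.4
  mid <- d >= 0.4 & d < 1.0
  far <- d >= 2.0
  expect_gt(mean(cc[near]), mean(cc[mid]))
  expect_gt(mean(cc[mid]), mean(cc[far]))
})

test_that("experiment pairs share exactly the shared component", {
  mon <- std_montage()
  da <- small_design(1, 2, 30, "expA", "A", window = c(-0.1, 0.3))
  db <- small_design(1, 2, 30, "expB", "B", window = c(-0.1, 0.3))
  noi <- noise_spec(trial_noise_sd = 0.5, participant_gain_sd = 0,
                    stimulus_effect_sd = 0, participant_code_sd = 0)
  class_contrast <- function(ep) {
    h <- colMeans(ep$data[ep$trials$expression == "happy", , ,
                          drop = FALSE], dims = 1)
    n <- colMeans(ep$data[ep$trials$expression == "neutral", , ,
                          drop = FALSE], dims = 1)
    h - n
  }
  # shared-only signal: the class contrast transfers across experiments
  pair <- generate_experiment_pair(
    da, db, signal_spec(shared_weight = 1, format_weight = 0,
                        amplitude_uv = 4), noi, mon, rng_seed = 2)
  d_a <- class_contrast(pair$a)
  d_b <- class_contrast(pair$b)
  expect_lt(max(abs(d_a - d_b)), 0.5) # equal up to averaged noise
  expect_gt(max(abs(d_a)), 1)

  # format-only signal: contrasts are independent across experiments
  pair0 <- generate_experiment_pair(
    da, db, signal_spec(shared_weight = 0, format_weight = 1,
                        amplitude_uv = 4), noi, mon, rng_seed = 2)
  d_a0 <- class_contrast(pair0$a)
  d_b0 <- class_contrast(pair0$b)
  expect_gt(max(abs(d_a0 - d_b0)), 1)
  expect_identical(unique(pair0$a$trials$dataset_id), "expA")
  expect_identical(unique(pair0$b$trials$dataset_id), "expB")
})

test_that("mismatched pair designs are rejected", {
  mon <- std_montage()
  da <- small_design(1, 2, 3, "expA", "A")
  expect_error(generate_experiment_pair(da, da, signal_spec(),
                                        noise_spec(), mon),
               "distinct dataset ids")
  db <- small_design(1, 2, 3, "expB", "B", window = c(-0.1, 0.5))
  expect_error(generate_experiment_pair(da, db, signal_spec(),
                                        noise_spec(), mon),
               "sfreq and epoch window")
})

test_that("named substreams are independent and stable", {
  expect_identical(substream_seed(1, "noise"), substream_seed(1, "noise"))
  expect_false(substream_seed(1, "noise") == substream_seed(1, "stimuli"))
  expect_false(substream_seed(1, "noise") == substream_seed(2, "noise"))
  expect_true(substream_seed(.Machine$integer.max, "x") < 2^31)
})
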