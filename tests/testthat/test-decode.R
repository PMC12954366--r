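# one small, signal-bearing experiment pair reused across decode tests
decode_fixture <- function() {
  cached("decode_pair", {
    mon <- std_montage()
    da <- small_design(4, 4, 6, "expA", "A")
    db <- small_design(4, 3, 6, "expB", "B")
    sig <- signal_spec(shared_weight = 1, format_weight = 0.3,
                       amplitude_uv = 10)
    noi <- noise_spec(trial_noise_sd = 4, participant_gain_sd = 0.1,
                      stimulus_effect_sd = 0.5)
    pair <- generate_experiment_pair(da, db, sig, noi, mon, rng_seed = 7)
    list(a = preprocess(pair$a, preprocess_config(rng_seed = 3)),
         b = preprocess(pair$b, preprocess_config(rng_seed = 3)),
         signal = sig)
  })
}

test_that("decoding rises above chance only inside the signal window", {
  fx <- decode_fixture()
  plan <- plan_within_folds(fx$a)
  tc <- decode_timecourse(fx$a, plan)
  expect_s3_class(tc, "accuracy_timecourse")
  expect_equal(tc$chance, 0.25)
  expect_equal(nrow(tc$accuracy), 4) # one row per participant
  m <- colMeans(tc$accuracy)
  pre <- tc$times < 0
  sig_win <- tc$times >= fx$signal$onset_s &
    tc$times <= fx$signal$onset_s + 3 * fx$signal$width_s + 0.05
  expect_lt(abs(mean(m[pre]) - 0.25), 0.04)
  expect_gt(mean(m[sig_win]), mean(m[pre]) + 0.04)
  expect_gt(max(m[sig_win]), 0.32)
})

test_that("pairwise contrasts record chance 0.5", {
  fx <- decode_fixture()
  plan <- plan_within_folds(fx$a)
  tc <- decode_timecourse(fx$a, plan, classes = c("angry", "neutral"))
  expect_equal(tc$chance, 0.5)
  expect_gt(max(colMeans(tc$accuracy)), 0.6)
})

test_that("label shuffling brings accuracy back to chance", {
  fx <- decode_fixture()
  plan <- plan_within_folds(fx$a)
  tc <- decode_timecourse(fx$a, plan, shuffle_labels = TRUE, rng_seed = 1)
  se <- sd(rowMeans(tc$accuracy)) / sqrt(nrow(tc$accuracy))
  expect_lt(abs(mean(tc$accuracy) - 0.25), max(2 * se, 0.02))
})

test_that("decoding is invariant to channel order", {
  fx <- decode_fixture()
  ep <- fx$a
  set.seed(33)
  perm <- sample(length(ep$channels))
  ep2 <- epoch_set(ep$data[, perm, , drop = FALSE], ep$times,
                   ep$channels[perm], ep$trials, ep$sfreq)
  plan <- plan_within_folds(ep)
  t1 <- decode_timecourse(ep, plan)
  t2 <- decode_timecourse(ep2, plan)
  expect_equal(t1$accuracy, t2$accuracy, tolerance = 1e-9)
})

test_that("ROI scopes restrict the feature set", {
  fx <- decode_fixture()
  plan <- plan_within_folds(fx$a)
  tc_post <- decode_timecourse(fx$a, plan,
                               channel_scope = "right_posterior")
  tc_two <- decode_timecourse(fx$a, plan,
                              channel_scope = c("PO8", "PO4"))
  expect_identical(tc_post$scope, "right_posterior")
  expect_identical(tc_two$scope, "PO8+PO4")
  expect_error(decode_timecourse(fx$a, plan, channel_scope = "Qz"),
               "Unknown channel")
})

test_that("cross-dataset decoding transfers a shared code", {
  fx <- decode_fixture()
  plan <- plan_cross_folds(fx$a, fx$b)
  tc <- decode_timecourse(fx$a, plan, test_epochs = fx$b)
  expect_identical(tc$scheme, "cross_dataset")
  expect_equal(nrow(tc$accuracy), 4)
  sig_win <- tc$times >= 0.1 & tc$times <= 0.25
  expect_gt(mean(colMeans(tc$accuracy)[sig_win]), 0.30)
})

test_that("a training fold missing a class is an error", {
  fx <- decode_fixture()
  ep <- subset_trials(fx$a, fx$a$trials$expression != "sad" |
                        fx$a$trials$participant_id == "A01")
  plan <- plan_within_folds(ep)
  expect_error(decode_timecourse(ep, plan), "lacks class")
})

test_that("searchlight peaks at the injected topography", {
  fx <- decode_fixture()
  adj <- std_adjacency()
  plan <- plan_within_folds(fx$a)
  sl <- searchlight_decode(fx$a, plan, adjacency = adj)
  expect_equal(dim(sl$accuracy), c(4, 64, length(sl$times)))
  win <- sl$times >= 0.1 & sl$times <= 0.25
  cm <- apply(sl$accuracy[, , win, drop = FALSE], 2, mean)
  names(cm) <- sl$channels
  hood <- channel_neighborhood(adj, fx$signal$topography_center)
  expect_true(names(which.max(cm)) %in% hood)
  # the injected posterior site beats the farthest frontal channel
  expect_gt(cm[fx$signal$topography_center], cm["Fpz"])
})
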