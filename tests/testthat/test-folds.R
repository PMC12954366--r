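# plans only need metadata, so epochs carry a minimal data array
meta_epochs <- function(design) {
  grid <- expand.grid(rep = seq_len(design$reps_per_image),
                      expression = design$expressions,
                      stimulus_id = design$stimulus_levels,
                      participant = seq_len(design$n_participants),
                      stringsAsFactors = FALSE)
  trials <- tibble::tibble(
    participant_id = sprintf("%s%02d", design$participant_prefix,
                             grid$participant),
    dataset_id = design$dataset_id,
    expression = grid$expression, stimulus_id = grid$stimulus_id,
    correct = TRUE, is_pseudotrial = TRUE)
  if (!is.null(design$stimulus_sex)) {
    trials$stimulus_sex <- unname(design$stimulus_sex[trials$stimulus_id])
  }
  epoch_set(array(0, c(nrow(trials), 1, 1)), 0, "Cz", trials,
            design$sfreq)
}

test_that("the emoji scheme yields participant x platform folds", {
  ep <- meta_epochs(emoji_faces_design())
  plan <- plan_within_folds(ep)
  expect_equal(nrow(plan), 25 * 6)
  expect_identical(attr(plan, "scheme"), "within_loso")
  tr <- ep$trials
  for (i in c(1, 77, 150)) {
    train <- tr[plan$train_idx[[i]], ]
    test <- tr[plan$test_idx[[i]], ]
    expect_length(unique(test$participant_id), 1)
    expect_length(unique(test$stimulus_id), 1)
    expect_length(setdiff(unique(tr$stimulus_id),
                          unique(train$stimulus_id)), 1)
    expect_false(test$participant_id[1] %in% train$participant_id)
    expect_false(test$stimulus_id[1] %in% train$stimulus_id)
  }
  audit <- audit_fold_plan(plan, ep)
  expect_true(all(audit$leak_free))
})

test_that("the real-faces scheme trains on six sex-balanced identities", {
  des <- real_faces_design()
  ep <- meta_epochs(des)
  plan <- plan_within_folds(ep, sex_balance = TRUE)
  expect_equal(nrow(plan), 24 * 8)
  tr <- ep$trials
  for (i in c(1, 50, 100, 192)) {
    train <- tr[plan$train_idx[[i]], ]
    ids <- unique(train$stimulus_id)
    expect_length(ids, 6)
    expect_equal(sum(startsWith(ids, "AM")), 3)
    expect_equal(sum(startsWith(ids, "AF")), 3)
    expect_false(plan$test_stimulus[i] %in% ids)
  }
  # round-robin partner exclusion varies across folds
  excluded <- vapply(seq_len(nrow(plan)), function(i) {
    setdiff(setdiff(unique(tr$stimulus_id),
                    unique(tr$stimulus_id[plan$train_idx[[i]]])),
            plan$test_stimulus[i])
  }, character(1))
  expect_gt(length(unique(excluded)), 1)
  expect_true(all(audit_fold_plan(plan, ep)$leak_free))
})

test_that("sex balancing demands sex metadata", {
  ep <- meta_epochs(emoji_faces_design())
  expect_error(plan_within_folds(ep, sex_balance = TRUE), "stimulus_sex")
})

test_that("cross-dataset folds aggregate the whole training set", {
  ep_r <- meta_epochs(real_faces_design())
  ep_e <- meta_epochs(emoji_faces_design())
  r2e <- plan_cross_folds(ep_r, ep_e)
  e2r <- plan_cross_folds(ep_e, ep_r)
  expect_equal(nrow(r2e), 25)
  expect_equal(nrow(e2r), 24)
  expect_identical(attr(r2e, "scheme"), "cross_dataset")
  for (i in c(1, 13, 25)) {
    expect_length(r2e$train_idx[[i]], nrow(ep_r$trials))
    te <- ep_e$trials[r2e$test_idx[[i]], ]
    expect_length(unique(te$participant_id), 1)
  }
  expect_true(all(audit_fold_plan(r2e, ep_r, ep_e)$leak_free))
})

test_that("ambiguous or overlapping datasets are rejected", {
  ep_r <- meta_epochs(real_faces_design(3))
  expect_error(plan_cross_folds(ep_r, ep_r), "different datasets")
  clash <- meta_epochs(design_spec(3, c("x1", "x2"), 2, "other",
                                   participant_prefix = "R"))
  expect_error(plan_cross_folds(ep_r, clash), "ambiguous")
})
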