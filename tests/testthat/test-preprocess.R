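test_that("band-pass removes DC and keeps the passband", {
  fs <- 512
  n <- round(1.4 * fs)
  tvec <- (0:(n - 1)) / fs
  mid <- seq(round(n / 3), round(2 * n / 3))
  mk <- function(x) toy_epochs(array(x, c(1, 1, n)), sfreq = fs)

  flat <- bandpass(mk(rep(5, n)), c(0.1, 40))
  expect_lt(max(abs(flat$data[1, 1, mid])), 0.1)

  s10 <- bandpass(mk(sin(2 * pi * 10 * tvec)), c(0.1, 40))
  expect_lt(abs(max(abs(s10$data[1, 1, mid])) - 1), 0.05)

  s80 <- bandpass(mk(sin(2 * pi * 80 * tvec)), c(0.1, 40))
  expect_lt(20 * log10(max(abs(s80$data[1, 1, mid]))), -20)

  expect_equal(dim(s10), c(1, 1, n))
  expect_error(bandpass(mk(rep(0, n)), c(0.1, 300)), "Nyquist")
  expect_error(bandpass(mk(rep(0, n)), c(40, 0.1)), "low < high")
})

test_that("baseline correction zeroes the pre-stimulus mean", {
  const <- toy_epochs(array(3, c(2, 2, 80)))
  bc <- baseline_correct(const)
  expect_true(all(abs(bc$data) < 1e-12))

  set.seed(4)
  ep <- toy_epochs(array(rnorm(2 * 2 * 80), c(2, 2, 80)))
  bc1 <- baseline_correct(ep)
  sel <- bc1$times >= -0.2 & bc1$times < 0
  bl <- apply(bc1$data[, , sel], c(1, 2), mean)
  expect_lt(max(abs(bl)), 1e-12)
  # idempotent
  bc2 <- baseline_correct(bc1)
  expect_equal(bc2$data, bc1$data, tolerance = 1e-12)
  expect_error(baseline_correct(ep, c(0.9, 1.0)), "no samples")
})

test_that("resampling follows the half-open window convention", {
  fs <- 2048
  n <- window_samples <- round(1.4 * fs)
  tvec <- -0.2 + (0:(n - 1)) / fs
  x <- sin(2 * pi * 5 * (tvec + 0.2))
  ep <- toy_epochs(array(x, c(1, 1, n)), sfreq = fs, t0 = -0.2)
  rs <- resample_epochs(ep, 200)
  expect_equal(dim(rs)[3], 280)
  expect_equal(rs$sfreq, 200)
  expect_equal(rs$times[1], -0.2)
  # the 5 Hz component survives (compare mid-epoch, away from edges)
  want <- sin(2 * pi * 5 * (rs$times + 0.2))
  mid <- 40:240
  expect_lt(max(abs(rs$data[1, 1, mid] - want[mid])), 0.05)

  expect_identical(resample_epochs(ep, 2048), ep)
  expect_error(resample_epochs(ep, 4096), "must not exceed")
})

test_that("pseudo-trial counts follow the floor rule", {
  mon <- std_montage()
  short <- c(-0.2, -0.1)
  real1 <- generate_experiment(real_faces_design(1, window = short),
                               signal_spec(), noise_spec(), mon,
                               rng_seed = 1)
  ps <- make_pseudotrials(real1, 3, rng_seed = 1)
  expect_equal(nrow(ps$trials), 128) # floor(12/3) * 32 images
  expect_true(all(table(ps$trials$expression) == 32))
  expect_true(all(ps$trials$is_pseudotrial))

  emoji1 <- generate_experiment(emoji_faces_design(1, window = short),
                                signal_spec(), noise_spec(), mon,
                                rng_seed = 1)
  expect_equal(nrow(make_pseudotrials(emoji1, 3, rng_seed = 1)$trials), 96)
})

test_that("remainder trials are dropped and groups never mix", {
  # 7 same-image trials -> 2 pseudo-trials, 1 dropped
  dat <- array(rep(1:7, 2 * 4), c(7, 2, 4))
  for (i in 1:7) dat[i, , ] <- i
  ep <- toy_epochs(dat, expression = rep("sad", 7))
  ps <- make_pseudotrials(ep, 3, rng_seed = 2)
  expect_equal(nrow(ps$trials), 2)
  # each pseudo-trial is a mean of 3 distinct original trials
  expect_true(all(ps$data * 3 == round(ps$data * 3)))

  # different images are never averaged together
  ep2 <- toy_epochs(array(rep(c(0, 100), each = 3), c(6, 1, 2)),
                    expression = rep(c("happy", "sad"), each = 3))
  ps2 <- make_pseudotrials(ep2, 3, rng_seed = 1)
  expect_setequal(as.numeric(ps2$data), c(0, 100))

  # incorrect trials are excluded before binning
  ep3 <- toy_epochs(array(1, c(6, 1, 2)),
                    correct = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(nrow(make_pseudotrials(ep3, 3, rng_seed = 1)$trials), 1)
  expect_error(make_pseudotrials(ep3, 0), "bin_size")
})

test_that("bin averaging commutes with linear preprocessing", {
  set.seed(9)
  ep <- toy_epochs(array(rnorm(6 * 3 * 60), c(6, 3, 60)),
                   expression = rep("angry", 6))
  a <- baseline_correct(make_pseudotrials(ep, 3, rng_seed = 5),
                        c(-0.2, 0))
  b <- make_pseudotrials(baseline_correct(ep, c(-0.2, 0)), 3,
                         rng_seed = 5)
  expect_equal(a$data, b$data, tolerance = 1e-12)
})

test_that("the full chain reproduces the study's pseudo-trial counts", {
  mon <- std_montage()
  raw <- generate_experiment(real_faces_design(1, sfreq = 512,
                                               window = c(-0.2, 0.3)),
                             signal_spec(), noise_spec(), mon,
                             rng_seed = 2)
  out <- preprocess(raw, preprocess_config(rng_seed = 1))
  expect_equal(out$sfreq, 200)
  expect_equal(dim(out)[3], round(0.5 * 200))
  expect_equal(nrow(out$trials), 128)
})
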