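test_that("the smoothing window covers 7 samples at 200 Hz", {
  n_t <- 41
  imp <- matrix(0, 1, n_t)
  imp[1, 21] <- 1
  sm <- moving_average(imp, 0.035, sfreq = 200)
  expect_equal(sum(sm > 0), 7)
  expect_equal(unname(sm[1, 18:24]), rep(1 / 7, 7))
  expect_equal(sum(sm), 1) # interior mass preserved

  const <- moving_average(matrix(2, 3, 20), 0.035, sfreq = 200)
  expect_true(all(const == 2))

  # edges use the shrinking window
  step <- matrix(c(1, rep(0, 19)), 1, 20)
  sm2 <- moving_average(step, 0.035, sfreq = 200)
  expect_equal(sm2[1, 1], 1 / 4) # window truncated to 4 samples
  expect_error(moving_average(imp, 0.001, sfreq = 200), "one sample")
})

test_that("one-sample effect sizes match hand computation", {
  expect_equal(cohens_d_one_sample(c(0.2, 0.3), 0.25), 0)
  # frozen from an independent spreadsheet-style computation:
  # mean 0.375, sd sqrt(0.0125/3), d = 0.125/0.06454972 = 1.9364917
  expect_equal(cohens_d_one_sample(c(0.30, 0.40, 0.35, 0.45), 0.25),
               1.9364917, tolerance = 1e-6)
  expect_error(cohens_d_one_sample(c(0.35, 0.35, 0.35), 0.25),
               "zero standard deviation")
})

test_that("a strong deflection forms one floor-p cluster", {
  set.seed(10)
  n <- 12
  n_t <- 80
  x <- matrix(rnorm(n * n_t, 0.25, 0.02), n, n_t)
  x[, 31:45] <- x[, 31:45] + 0.2
  cl <- cluster_perm_1d(x, chance = 0.25, n_perm = 500, rng_seed = 4)
  big <- cl$clusters[which.max(abs(cl$clusters$mass)), ]
  expect_equal(big$p, 1 / 501)
  expect_true(all(31:45 %in% big$timepoints[[1]]))
  expect_true(all(cl$mask[big$timepoints[[1]]]))

  # two-sided symmetry: negating the data flips signs, keeps p
  cl2 <- cluster_perm_1d(0.5 - x, chance = 0.25, n_perm = 500,
                         rng_seed = 4)
  big2 <- cl2$clusters[which.max(abs(cl2$clusters$mass)), ]
  expect_equal(big2$p, big$p)
  expect_equal(big2$mass, -big$mass, tolerance = 1e-9)
  expect_equal(big2$sign, -big$sign)
})

test_that("accuracy timecourses drive the cluster test directly", {
  set.seed(2)
  acc <- matrix(runif(8 * 30, 0.4, 0.6), 8, 30)
  tc <- accuracy_timecourse(acc, seq(0, by = 0.005, length.out = 30),
                            200, 0.5)
  cl <- cluster_perm_1d(tc, n_perm = 200, rng_seed = 1)
  expect_s3_class(cl, "cluster_result")
  expect_true(all(cl$clusters$p >= 1 / 201))
})

test_that("identity adjacency reduces the spatio-temporal test to 1D", {
  set.seed(20)
  n <- 10
  n_ch <- 3
  n_t <- 25
  x <- array(rnorm(n * n_ch * n_t, 0, 0.05) + 0.25, c(n, n_ch, n_t))
  x[, 2, 10:18] <- x[, 2, 10:18] + 0.3
  adj <- diag(TRUE, n_ch)
  dimnames(adj) <- list(paste0("c", 1:3), paste0("c", 1:3))
  dimnames(x) <- list(NULL, paste0("c", 1:3), NULL)
  st <- cluster_perm_spatiotemporal(x, adj, chance = 0.25, n_perm = 300,
                                    rng_seed = 9)
  # every cluster lives on a single channel
  for (i in seq_len(nrow(st$clusters))) {
    expect_length(unique(st$clusters$members[[i]][, "channel"]), 1)
  }
  # per-channel cluster masses equal the 1D test's masses
  for (ch in 1:3) {
    cl1 <- cluster_perm_1d(x[, ch, ], chance = 0.25, n_perm = 10,
                           rng_seed = 1)
    m_st <- sort(st$clusters$mass[
      vapply(st$clusters$members,
             function(m) m[1, "channel"] == ch, TRUE)])
    expect_equal(m_st, sort(cl1$clusters$mass), tolerance = 1e-9)
  }
})

test_that("a spatio-temporal blob is recovered as one cluster", {
  set.seed(30)
  adj <- std_adjacency()[1:8, 1:8]
  n <- 12
  n_ch <- 8
  n_t <- 30
  x <- array(rnorm(n * n_ch * n_t, 0.25, 0.03), c(n, n_ch, n_t))
  blob_ch <- which(adj[2, ]) # channel 2 and its neighbours
  x[, blob_ch, 12:20] <- x[, blob_ch, 12:20] + 0.25
  dimnames(x) <- list(NULL, rownames(adj), NULL)
  st <- cluster_perm_spatiotemporal(x, adj, chance = 0.25, n_perm = 300,
                                    rng_seed = 2)
  sig <- st$clusters[st$clusters$p < 0.05, ]
  expect_equal(nrow(sig), 1)
  got <- sig$members[[1]]
  expect_true(all(blob_ch %in% got[, "channel"]))
  expect_true(all(12:20 %in% got[got[, "channel"] == blob_ch[1], "time"]))
  expect_true(all(st$mask[cbind(got[, "channel"], got[, "time"])]))
})

test_that("interval-null Bayes factors match independent quadrature", {
  for (n in c(10, 25, 50)) {
    for (tt in c(0, 2, 5)) {
      x <- scale(rnorm(n))[, 1]
      x <- x + tt / sqrt(n) # mean tt/sqrt(n), sd 1 -> t = tt
      got <- bf_interval_ttest(x, 0)
      expect_equal(got$t, tt, tolerance = 1e-9)
      expect_equal(got$bf10, oracle_bf10(tt, n), tolerance = 1e-3)
    }
  }
})

test_that("evidence grows monotonically with |t|", {
  n <- 20
  bf_at <- function(tt) {
    x <- scale(rnorm(n))[, 1] + tt / sqrt(n)
    bf_interval_ttest(x, 0)$bf10
  }
  set.seed(1)
  grid <- seq(0, 8, by = 0.5)
  bfs <- vapply(grid, bf_at, numeric(1))
  expect_true(all(diff(bfs) > 0))
  expect_lt(bfs[1], 1) # t = 0 favours the null
})

test_that("Bayes-factor timecourses threshold and flag degeneracy", {
  set.seed(8)
  acc <- matrix(rnorm(10 * 20, 0.25, 0.02), 10, 20)
  acc[, 15:18] <- acc[, 15:18] + 0.3
  tc <- accuracy_timecourse(acc, seq(0.005, by = 0.005, length.out = 20),
                            200, 0.25)
  bf <- bf_timecourse(tc, threshold = 10)
  expect_true(all(bf$exceeds[15:18]))
  expect_false(any(bf$exceeds[1:10]))
  bf_inf <- bf_timecourse(tc, threshold = Inf)
  expect_false(any(bf_inf$exceeds))

  acc[, 3] <- 0.25 # zero variance at one timepoint
  tc2 <- accuracy_timecourse(acc, tc$times, 200, 0.25)
  expect_warning(bf2 <- bf_timecourse(tc2), "Degenerate")
  expect_true(is.na(bf2$bf10[3]))
  expect_false(bf2$exceeds[3])
})

test_that("degenerate and invalid Bayes-factor inputs error", {
  expect_error(bf_interval_ttest(c(1, 1, 1), 0), "zero variance")
  expect_error(bf_interval_ttest(c(1), 0), "at least 2")
  expect_error(bf_interval_ttest(c(1, 2, NA), 0), "finite")
  expect_error(bf_interval_ttest(rnorm(5), 0, null_excl = c(-0.2, 0.5)),
               "symmetric")
})
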