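# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

std_montage <- function() cached("montage", biosemi64_montage())
std_adjacency <- function() cached("adjacency", build_adjacency(std_montage()))

# a small two-experiment design pair used by several decode tests
small_design <- function(n_participants = 4, n_stim = 4, reps = 6,
                         dataset_id = "expA", prefix = "A",
                         window = c(-0.1, 0.35)) {
  design_spec(n_participants,
              paste0(tolower(substr(dataset_id, 4, 4)), seq_len(n_stim)),
              reps, dataset_id, window = window,
              participant_prefix = prefix)
}

# epochs with hand-set data: trials x channels x samples
toy_epochs <- function(data, sfreq = 200, t0 = -0.2,
                       participant = "S01", expression = NULL,
                       stimulus = "s1", correct = TRUE) {
  n <- dim(data)[1]
  times <- t0 + seq(0, dim(data)[3] - 1) / sfreq
  channels <- paste0("C", seq_len(dim(data)[2]))
  expression <- expression %||% rep("happy", n)
  trials <- tibble::tibble(
    participant_id = rep_len(participant, n), dataset_id = "toy",
    expression = rep_len(expression, n),
    stimulus_id = rep_len(stimulus, n),
    correct = rep_len(correct, n), is_pseudotrial = FALSE)
  epoch_set(data, times, channels, trials, sfreq)
}

`%||%` <- rlang::`%||%`

# Independent brute-force LDA oracle: explicit scatter matrices and an
# explicit eigendecomposition pseudo-inverse, kept free of any code from
# the package's fit path.
oracle_lda_predict <- function(xtr, ytr, xte) {
  ytr <- factor(ytr)
  cls <- levels(ytr)
  p <- ncol(xtr)
  mu <- lapply(cls, function(cl) colMeans(xtr[ytr == cl, , drop = FALSE]))
  sw <- matrix(0, p, p)
  for (i in seq_along(cls)) {
    xc <- xtr[ytr == cls[i], , drop = FALSE]
    xc <- sweep(xc, 2, mu[[i]], `-`)
    sw <- sw + t(xc) %*% xc
  }
  sw <- sw / (nrow(xtr) - length(cls))
  ee <- eigen(sw, symmetric = TRUE)
  keep <- ee$values > max(ee$values) * p * .Machine$double.eps
  sinv <- matrix(0, p, p)
  for (j in which(keep)) {
    sinv <- sinv + (ee$vectors[, j] %*% t(ee$vectors[, j])) / ee$values[j]
  }
  pri <- as.numeric(table(ytr)) / nrow(xtr)
  scores <- sapply(seq_along(cls), function(i) {
    as.numeric(xte %*% (sinv %*% mu[[i]])) -
      0.5 * as.numeric(t(mu[[i]]) %*% sinv %*% mu[[i]]) + log(pri[i])
  })
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  cls[apply(scores, 1, which.max)]
}

# Independent high-resolution trapezoid oracle for the interval-null
# Bayes factor.
oracle_bf10 <- function(tstat, n, r = 0.707, lo = 0.5, hi = 40,
                        step = 5e-4) {
  df <- n - 1
  z <- 2 * pcauchy(-lo, 0, r)
  grid <- seq(lo, hi, by = step)
  f <- function(delta) {
    suppressWarnings(dt(tstat, df, ncp = delta * sqrt(n))) *
      dcauchy(delta, 0, r) / z
  }
  trap <- function(v) (sum(v) - (v[1] + v[length(v)]) / 2) * step
  (trap(f(grid)) + trap(f(-grid))) / dt(tstat, df)
}
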