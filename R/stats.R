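#' Centered moving average of accuracy timecourses
#'
#' Smooths each unit's accuracy with a centered boxcar whose span is
#' given in seconds: 35 ms at 200 Hz covers 7 consecutive timepoints.
#' The window length is `round(span * sfreq)` when that is odd,
#' otherwise one more; at the edges the window shrinks symmetrically so
#' the output length is unchanged.
#'
#' @param tc an [accuracy_timecourse()] (or a plain units x samples
#'   matrix together with `sfreq`).
#' @param span_s window span in seconds.
#' @param sfreq sampling rate, only needed for matrix input.
#' @return Smoothed object of the same type.
#' @export
moving_average <- function(tc, span_s = 0.035, sfreq = NULL) {
  if (inherits(tc, "accuracy_timecourse")) {
    out <- tc
    out$accuracy <- moving_average(tc$accuracy, span_s, tc$sfreq)
    return(out)
  }
  x <- as.matrix(tc)
  if (is.null(sfreq)) abort("`sfreq` is required for matrix input.")
  n_w <- round(span_s * sfreq)
  if (n_w < 1) abort("Smoothing span is shorter than one sample.")
  if (n_w %% 2 == 0) n_w <- n_w + 1
  half <- (n_w - 1) / 2
  n_t <- ncol(x)
  out <- x
  for (t in seq_len(n_t)) {
    lo <- max(1, t - half)
    hi <- min(n_t, t + half)
    out[, t] <- rowMeans(x[, lo:hi, drop = FALSE])
  }
  out
}

#' One-sample Cohen's d against a reference value
#'
#' `d = (mean(x) - mu) / sd(x)` with the n-1 sample standard deviation.
#'
#' @param values per-unit scalars (e.g. participant accuracies at one
#'   timepoint).
#' @param mu reference (chance) value.
#' @return Cohen's d. Errors when the sample standard deviation is zero.
#' @export
cohens_d_one_sample <- function(values, mu) {
  if (length(values) < 2L) abort("Need at least 2 values.")
  s <- sd(values)
  if (s == 0) abort("Cohen's d is undefined: zero standard deviation.")
  (mean(values) - mu) / s
}

# Large stand-in for an infinite t at zero within-unit variance; keeps
# cluster masses finite and ordered while dominating any finite t.
BIG_T <- 1e6

one_sample_t <- function(x) {
  # columns of x are tested against 0
  n <- nrow(x)
  m <- colMeans(x)
  s <- sqrt(pmax(colSums(x^2) - n * m^2, 0) / (n - 1))
  t <- m / (s / sqrt(n))
  zero <- s == 0
  if (any(zero)) t[zero] <- sign(m[zero]) * BIG_T
  list(t = t, n = n)
}

fix_zero_sd_t <- function(tm, pm, sdm) {
  zero <- sdm == 0
  if (any(zero)) tm[zero] <- sign(pm[zero]) * BIG_T
  tm
}

# contiguous same-sign runs above threshold; returns list of index
# vectors and signed masses
runs_1d <- function(tvals, thresh) {
  sgn <- ifelse(tvals > thresh, 1L, ifelse(tvals < -thresh, -1L, 0L))
  r <- rle(sgn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values != 0L)
  lapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    list(idx = idx, mass = sum(tvals[idx]), sign = r$values[k])
  })
}

new_cluster_result <- function(clusters, mask, alpha, thresh, n_perm,
                               times, channels = NULL) {
  structure(list(clusters = clusters, mask = mask, alpha = alpha,
                 cluster_threshold = thresh, n_perm = n_perm,
                 times = times, channels = channels),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  sig <- sum(x$clusters$p < x$alpha)
  cat(sprintf("<cluster_result> %d cluster(s), %d significant at alpha = %g (n_perm = %d)\n",
              nrow(x$clusters), sig, x$alpha, x$n_perm))
  if (nrow(x$clusters) > 0) {
    print(x$clusters[, setdiff(names(x$clusters),
                               c("timepoints", "members"))])
  }
  invisible(x)
}

#' One-dimensional cluster-based sign-flip permutation test
#'
#' Two-sided one-sample test of unit x time accuracies against chance.
#' Per timepoint a one-sample t statistic is formed; contiguous
#' same-sign runs exceeding the two-sided parametric threshold
#' `t(1 - cluster_alpha/2, n-1)` become clusters scored by their summed
#' t (mass). The null distribution is the maximum absolute cluster mass
#' over random sign flips of the unit-level deviations, and cluster
#' p-values use the add-one estimator
#' `p = (1 + #{null >= |mass|}) / (1 + n_perm)`.
#'
#' Timepoints where every unit deviates identically from chance (zero
#' within-unit variance, as happens in tiny saturated problems) get a
#' large finite stand-in for the infinite t — in the observed and the
#' permuted statistics alike — so they join clusters without breaking
#' the mass ordering; an entirely constant input is an error.
#'
#' @param x units x time matrix of accuracies, or an
#'   [accuracy_timecourse()].
#' @param chance chance level subtracted before testing (taken from the
#'   timecourse when omitted).
#' @param n_perm number of sign-flip permutations.
#' @param alpha significance level for the cluster mask.
#' @param cluster_alpha two-sided alpha of the cluster-forming t
#'   threshold.
#' @param rng_seed permutation seed.
#' @return A `cluster_result`: tibble of clusters (`id`, `sign`,
#'   `t_start`, `t_end`, `mass`, `p`, list-column `timepoints`) and a
#'   logical per-timepoint `mask` of membership in significant clusters.
#' @export
cluster_perm_1d <- function(x, chance = NULL, n_perm = 10000,
                            alpha = 0.05, cluster_alpha = 0.05,
                            rng_seed = 1) {
  times <- NULL
  if (inherits(x, "accuracy_timecourse")) {
    chance <- chance %||% x$chance
    times <- x$times
    x <- x$accuracy
  }
  if (is.null(chance)) abort("`chance` is required for matrix input.")
  x <- as.matrix(x) - chance
  n <- nrow(x)
  n_t <- ncol(x)
  if (n < 2L) abort("Need at least 2 units.")
  if (n_perm < 1) abort("`n_perm` must be at least 1.")
  if (is.null(times)) times <- seq_len(n_t)
  if (all(x == x[1])) {
    abort("All unit deviations are identical; the test is undefined.")
  }
  thresh <- qt(1 - cluster_alpha / 2, df = n - 1)
  obs <- one_sample_t(x)$t
  clusters <- runs_1d(obs, thresh)

  set.seed(substream_seed(rng_seed, "cluster_perm"))
  flips <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  ssq <- colSums(x^2)
  null_max <- numeric(n_perm)
  pm <- (flips %*% x) / n # permuted means
  sdm <- sqrt(pmax(sweep(-n * pm^2, 2, ssq, `+`), 0) / (n - 1))
  tm <- fix_zero_sd_t(pm / (sdm / sqrt(n)), pm, sdm)
  for (i in seq_len(n_perm)) {
    cl <- runs_1d(tm[i, ], thresh)
    null_max[i] <- if (length(cl) == 0) 0 else
      max(abs(vapply(cl, `[[`, 0, "mass")))
  }
  tab <- if (length(clusters) == 0) {
    tibble::tibble(id = integer(), sign = integer(), t_start = numeric(),
                   t_end = numeric(), n_points = integer(),
                   mass = numeric(), p = numeric(), timepoints = list())
  } else {
    dplyr::bind_rows(lapply(seq_along(clusters), function(i) {
      cl <- clusters[[i]]
      tibble::tibble(
        id = i, sign = cl$sign, t_start = times[min(cl$idx)],
        t_end = times[max(cl$idx)], n_points = length(cl$idx),
        mass = cl$mass,
        p = (1 + sum(null_max >= abs(cl$mass))) / (1 + n_perm),
        timepoints = list(cl$idx))
    }))
  }
  mask <- logical(n_t)
  for (i in seq_len(nrow(tab))) {
    if (tab$p[i] < alpha) mask[tab$timepoints[[i]]] <- TRUE
  }
  new_cluster_result(tab, mask, alpha, thresh, n_perm, times)
}

# connected components of supra-threshold same-sign (channel, time)
# points under channel adjacency x temporal contiguity
spatiotemporal_clusters <- function(tmat, thresh, adj_idx) {
  n_ch <- nrow(tmat)
  n_t <- ncol(tmat)
  state <- ifelse(tmat > thresh, 1L, ifelse(tmat < -thresh, -1L, 0L))
  labels <- matrix(0L, n_ch, n_t)
  clusters <- list()
  n_cl <- 0L
  for (start in which(state != 0L)) {
    if (labels[start] != 0L) next
    n_cl <- n_cl + 1L
    sgn <- state[start]
    queue <- start
    labels[start] <- n_cl
    members <- integer(0)
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      members <- c(members, cur)
      ch <- (cur - 1L) %% n_ch + 1L
      t <- (cur - 1L) %/% n_ch + 1L
      cand <- c(
        if (t > 1L) (t - 2L) * n_ch + ch,
        if (t < n_t) t * n_ch + ch,
        (t - 1L) * n_ch + adj_idx[[ch]])
      for (nb in cand) {
        if (labels[nb] == 0L && state[nb] == sgn) {
          labels[nb] <- n_cl
          queue <- c(queue, nb)
        }
      }
    }
    clusters[[n_cl]] <- list(members = members, sign = sgn,
                             mass = sum(tmat[members]))
  }
  clusters
}

#' Spatio-temporal cluster-based sign-flip permutation test
#'
#' As [cluster_perm_1d()], but clusters are connected components of
#' supra-threshold same-sign points in the graph formed by channel
#' adjacency crossed with temporal contiguity, as used for searchlight
#' accuracy maps.
#'
#' @param x units x channels x time array, or a [searchlight_result()].
#' @param adjacency channel adjacency matrix matching the channel axis.
#' @inheritParams cluster_perm_1d
#' @return A `cluster_result` whose cluster table carries a `members`
#'   list-column of (channel, time) index matrices, and whose `mask` is
#'   channels x time.
#' @export
cluster_perm_spatiotemporal <- function(x, adjacency, chance = NULL,
                                        n_perm = 1000, alpha = 0.05,
                                        cluster_alpha = 0.05,
                                        rng_seed = 1) {
  channels <- NULL
  times <- NULL
  if (inherits(x, "searchlight_result")) {
    chance <- chance %||% x$chance
    channels <- x$channels
    times <- x$times
    x <- x$accuracy
  }
  if (is.null(chance)) abort("`chance` is required for array input.")
  stopifnot(length(dim(x)) == 3L)
  n <- dim(x)[1]
  n_ch <- dim(x)[2]
  n_t <- dim(x)[3]
  if (n < 2L) abort("Need at least 2 units.")
  channels <- channels %||% dimnames(x)[[2]] %||% as.character(seq_len(n_ch))
  times <- times %||% seq_len(n_t)
  adjacency <- adjacency[channels, channels]
  adj_idx <- lapply(seq_len(n_ch), function(i) {
    setdiff(which(adjacency[i, ]), i)
  })
  xc <- x - chance
  xf <- matrix(xc, n, n_ch * n_t) # unit x (channel, time) flattened
  if (all(xf == xf[1])) {
    abort("All unit deviations are identical; the test is undefined.")
  }
  thresh <- qt(1 - cluster_alpha / 2, df = n - 1)
  obs <- one_sample_t(xf)$t
  tmat <- matrix(obs, n_ch, n_t)
  clusters <- spatiotemporal_clusters(tmat, thresh, adj_idx)

  set.seed(substream_seed(rng_seed, "cluster_perm_st"))
  ssq <- colSums(xf^2)
  null_max <- numeric(n_perm)
  block <- 500L # bounds the permutation t matrix held in memory
  done <- 0L
  while (done < n_perm) {
    nb <- min(block, n_perm - done)
    flips <- matrix(sample(c(-1, 1), nb * n, replace = TRUE), nb, n)
    pm <- (flips %*% xf) / n
    sdm <- sqrt(pmax(sweep(-n * pm^2, 2, ssq, `+`), 0) / (n - 1))
    tm <- fix_zero_sd_t(pm / (sdm / sqrt(n)), pm, sdm)
    for (i in seq_len(nb)) {
      tp <- matrix(tm[i, ], n_ch, n_t)
      cl <- spatiotemporal_clusters(tp, thresh, adj_idx)
      null_max[done + i] <- if (length(cl) == 0) 0 else
        max(abs(vapply(cl, `[[`, 0, "mass")))
    }
    done <- done + nb
  }
  tab <- if (length(clusters) == 0) {
    tibble::tibble(id = integer(), sign = integer(), t_start = numeric(),
                   t_end = numeric(), n_points = integer(),
                   mass = numeric(), p = numeric(), members = list())
  } else {
    dplyr::bind_rows(lapply(seq_along(clusters), function(i) {
      cl <- clusters[[i]]
      ch_i <- (cl$members - 1L) %% n_ch + 1L
      t_i <- (cl$members - 1L) %/% n_ch + 1L
      tibble::tibble(
        id = i, sign = cl$sign, t_start = times[min(t_i)],
        t_end = times[max(t_i)], n_points = length(cl$members),
        mass = cl$mass,
        p = (1 + sum(null_max >= abs(cl$mass))) / (1 + n_perm),
        members = list(cbind(channel = ch_i, time = t_i)))
    }))
  }
  mask <- matrix(FALSE, n_ch, n_t, dimnames = list(channels, NULL))
  for (i in seq_len(nrow(tab))) {
    if (tab$p[i] < alpha) mask[tab$members[[i]]] <- TRUE
  }
  new_cluster_result(tab, mask, alpha, thresh, n_perm, times, channels)
}

#' Interval-null Jeffreys-Zellner-Siow Bayes factor
#'
#' One-sample Bayes factor for values against `mu`. The alternative
#' places a Cauchy prior of scale `r` on the standardised effect,
#' truncated to exclude the interval `|delta| < null_lo` and
#' renormalised; the null is the point `delta = 0`. The Bayes factor is
#' the ratio of the noncentral-t marginal likelihood under the truncated
#' prior to the central-t likelihood, computed by adaptive quadrature
#' over the two prior tails. Values above 1 favour an effect beyond the
#' excluded interval.
#'
#' @param values per-unit scalars.
#' @param mu reference value.
#' @param r Cauchy prior scale (0.707 = "medium").
#' @param null_excl excluded interval `c(-lo, +lo)`; must be symmetric
#'   about zero.
#' @return A list with `bf10`, the t statistic `t`, sample effect size
#'   `delta`, and `n`.
#' @export
bf_interval_ttest <- function(values, mu, r = 0.707,
                              null_excl = c(-0.5, 0.5)) {
  if (length(values) < 2L) abort("Need at least 2 values.")
  if (any(!is.finite(values))) abort("Values must be finite.")
  if (length(null_excl) != 2L || abs(null_excl[1] + null_excl[2]) > 1e-12) {
    abort("`null_excl` must be a symmetric interval c(-a, a).")
  }
  lo <- null_excl[2]
  n <- length(values)
  s <- sd(values)
  if (s == 0) abort("Bayes factor undefined: zero variance.")
  tstat <- (mean(values) - mu) / (s / sqrt(n))
  df <- n - 1
  z <- 2 * pcauchy(-lo, 0, r) # prior mass outside the interval
  f <- function(delta) {
    suppressWarnings(dt(tstat, df, ncp = delta * sqrt(n))) *
      dcauchy(delta, 0, r) / z
  }
  num <- integrate(f, lo, Inf, rel.tol = 1e-8)$value +
    integrate(f, -Inf, -lo, rel.tol = 1e-8)$value
  den <- dt(tstat, df)
  list(bf10 = num / den, t = tstat, delta = (mean(values) - mu) / s, n = n)
}

#' Bayes factor timecourse
#'
#' Applies [bf_interval_ttest()] at every timepoint of a (smoothed)
#' accuracy timecourse against its chance level and thresholds the
#' result. Timepoints with degenerate input (zero variance) yield `NA`
#' Bayes factors, an unset mask, and a warning.
#'
#' @param tc an [accuracy_timecourse()], smoothed per the pipeline
#'   convention ([moving_average()]).
#' @param threshold evidence threshold on BF10 (10 = strong evidence).
#' @inheritParams bf_interval_ttest
#' @return A `bf_timecourse`: tibble with `time`, `mean_accuracy`,
#'   `delta`, `t`, `bf10`, `exceeds`; attributes carry chance and
#'   threshold.
#' @export
bf_timecourse <- function(tc, threshold = 10, r = 0.707,
                          null_excl = c(-0.5, 0.5)) {
  stopifnot(inherits(tc, "accuracy_timecourse"))
  n_t <- ncol(tc$accuracy)
  bf <- delta <- tstat <- rep(NA_real_, n_t)
  degenerate <- FALSE
  for (t in seq_len(n_t)) {
    res <- tryCatch(
      bf_interval_ttest(tc$accuracy[, t], tc$chance, r, null_excl),
      error = function(e) NULL)
    if (is.null(res)) {
      degenerate <- TRUE
    } else {
      bf[t] <- res$bf10
      delta[t] <- res$delta
      tstat[t] <- res$t
    }
  }
  if (degenerate) {
    warn("Degenerate timepoint(s) produced NA Bayes factors.")
  }
  out <- tibble::tibble(
    time = tc$times, mean_accuracy = colMeans(tc$accuracy),
    delta = delta, t = tstat, bf10 = bf,
    exceeds = !is.na(bf) & bf > threshold)
  structure(out, chance = tc$chance, threshold = threshold, r = r,
            null_excl = null_excl, sfreq = tc$sfreq,
            class = c("bf_timecourse", class(out)))
}
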