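#' Pipeline run configuration
#'
#' Collects everything one end-to-end run needs: the two experiment
#' designs, signal/noise specifications for the synthetic generator (or
#' paths to existing epoch bundles), the preprocessing parameters, the
#' contrasts to decode, the statistical settings and the master seed.
#' Validation happens here, before any computation.
#'
#' @param design_a,design_b [design_spec()]s for the two experiments.
#' @param signal a [signal_spec()].
#' @param noise a [noise_spec()].
#' @param contrasts character vector: `"4class"` and/or pair labels of
#'   the form `"angry_vs_neutral"`.
#' @param preprocess a [preprocess_config()].
#' @param bundles optional named list (`a`, `b`) of bundle directories
#'   to load instead of simulating.
#' @param searchlight contrasts to run the searchlight + onset stage
#'   for: `TRUE` (all), `FALSE` (none), or a character vector of
#'   contrast labels.
#' @param n_perm cluster permutation count.
#' @param alpha cluster significance level.
#' @param bf_threshold BF10 evidence threshold.
#' @param r Cauchy prior scale.
#' @param null_excl excluded standardised-effect interval.
#' @param smooth_span_s accuracy smoothing span, seconds.
#' @param seed master seed for all stochastic stages.
#' @return An object of class `run_config`.
#' @export
run_config <- function(design_a = real_faces_design(),
                       design_b = emoji_faces_design(),
                       signal = signal_spec(), noise = noise_spec(),
                       contrasts = c("4class", "angry_vs_neutral"),
                       preprocess = preprocess_config(),
                       bundles = NULL, searchlight = TRUE,
                       n_perm = 10000, alpha = 0.05, bf_threshold = 10,
                       r = 0.707, null_excl = c(-0.5, 0.5),
                       smooth_span_s = 0.035, seed = 1) {
  stopifnot(inherits(design_a, "design_spec"),
            inherits(design_b, "design_spec"),
            inherits(signal, "signal_spec"), inherits(noise, "noise_spec"),
            inherits(preprocess, "preprocess_config"))
  parsed <- lapply(contrasts, parse_contrast)
  names(parsed) <- contrasts
  if (is.character(searchlight)) {
    bad <- setdiff(searchlight, contrasts)
    if (length(bad) > 0L) {
      abort(sprintf("Searchlight contrast(s) not in `contrasts`: %s.",
                    paste(bad, collapse = ", ")))
    }
  }
  assert_scalar_number(n_perm, "n_perm", lower = 1)
  assert_scalar_number(seed, "seed", lower = 0, upper = 2^31 - 1)
  structure(list(design_a = design_a, design_b = design_b,
                 signal = signal, noise = noise, contrasts = parsed,
                 preprocess = preprocess, bundles = bundles,
                 searchlight = if (isTRUE(searchlight)) contrasts else
                   if (isFALSE(searchlight)) character(0) else searchlight,
                 n_perm = as.integer(n_perm),
                 alpha = alpha, bf_threshold = bf_threshold, r = r,
                 null_excl = null_excl, smooth_span_s = smooth_span_s,
                 seed = as.integer(seed)),
            class = "run_config")
}

parse_contrast <- function(label) {
  if (identical(label, "4class")) return(EXPRESSIONS)
  parts <- strsplit(label, "_vs_", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !all(parts %in% EXPRESSIONS) ||
      parts[1] == parts[2]) {
    abort(sprintf(
      "Unknown contrast '%s'; use '4class' or '<a>_vs_<b>' with distinct expression labels.",
      label))
  }
  sort(parts)
}

write_pipeline_tsv <- function(df, path) {
  readr::write_tsv(df, path, progress = FALSE)
  basename(path)
}

#' Run the complete analysis pipeline
#'
#' Simulates (or loads) the two experiments, preprocesses them to
#' pseudo-trials, decodes every configured contrast under the
#' within-experiment nested scheme for both datasets and the
#' cross-dataset scheme in both directions, smooths the accuracies,
#' runs cluster permutation and Bayes-factor statistics, optionally the
#' searchlight and whole-scalp onset estimation, and writes
#' machine-readable results: per-contrast accuracy and statistics TSVs,
#' a cluster table JSON, an onset TSV and a `report.json` with the full
#' configuration echo, seeds, package version, configuration hash and
#' fold audit summary. Deterministic given the configuration.
#'
#' @param config a [run_config()].
#' @param out_dir output directory, created if missing.
#' @param mon montage, default [biosemi64_montage()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the report (as written) and the
#'   result objects.
#' @export
run_full_pipeline <- function(config, out_dir, mon = biosemi64_montage(),
                              quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  say("stage: data")
  if (!is.null(config$bundles)) {
    raw_a <- read_epochs(config$bundles$a)
    raw_b <- read_epochs(config$bundles$b)
  } else {
    pair <- generate_experiment_pair(config$design_a, config$design_b,
                                     config$signal, config$noise, mon,
                                     rng_seed = config$seed)
    raw_a <- pair$a
    raw_b <- pair$b
  }

  say("stage: preprocess")
  pp <- config$preprocess
  pp$rng_seed <- substream_seed(config$seed, "binning")
  ep_a <- preprocess(raw_a, pp)
  ep_b <- preprocess(raw_b, pp)
  rm(raw_a, raw_b)

  plans <- list(
    within_a = list(train = ep_a, test = NULL,
                    plan = plan_within_folds(
                      ep_a, sex_balance = !is.null(config$design_a$stimulus_sex))),
    within_b = list(train = ep_b, test = NULL,
                    plan = plan_within_folds(
                      ep_b, sex_balance = !is.null(config$design_b$stimulus_sex))),
    cross_a_to_b = list(train = ep_a, test = ep_b,
                        plan = plan_cross_folds(ep_a, ep_b)),
    cross_b_to_a = list(train = ep_b, test = ep_a,
                        plan = plan_cross_folds(ep_b, ep_a)))

  adj <- build_adjacency(mon)
  files <- character(0)
  acc_rows <- list()
  stat_rows <- list()
  cluster_tables <- list()
  onset_rows <- list()
  scalp_rows <- list()

  for (contrast in names(config$contrasts)) {
    classes <- config$contrasts[[contrast]]
    for (scheme in names(plans)) {
      say("stage: decode %s / %s", contrast, scheme)
      pl <- plans[[scheme]]
      tc <- decode_timecourse(pl$train, pl$plan, classes = classes,
                              channel_scope = "all",
                              test_epochs = pl$test)
      tc_s <- moving_average(tc, config$smooth_span_s)
      cl <- cluster_perm_1d(tc_s, n_perm = config$n_perm,
                            alpha = config$alpha,
                            rng_seed = substream_seed(
                              config$seed, paste0("perm_", contrast, "_",
                                                  scheme)))
      bf <- bf_timecourse(tc_s, threshold = config$bf_threshold,
                          r = config$r, null_excl = config$null_excl)
      d <- vapply(seq_len(ncol(tc_s$accuracy)), function(t) {
        tryCatch(cohens_d_one_sample(tc_s$accuracy[, t], tc$chance),
                 error = function(e) NA_real_)
      }, numeric(1))
      cluster_id <- rep(NA_integer_, length(tc$times))
      for (i in seq_len(nrow(cl$clusters))) {
        cluster_id[cl$clusters$timepoints[[i]]] <- cl$clusters$id[i]
      }
      acc_rows[[paste(contrast, scheme)]] <-
        tidy(tc_s) |>
        dplyr::mutate(contrast = contrast, scheme_dir = scheme)
      stat_rows[[paste(contrast, scheme)]] <- tibble::tibble(
        contrast = contrast, scheme_dir = scheme, time = tc$times,
        mean_accuracy = colMeans(tc_s$accuracy), cohens_d = d,
        t = bf$t, bf10 = bf$bf10, bf_exceeds = bf$exceeds,
        cluster_mask = cl$mask, cluster_id = cluster_id)
      cluster_tables[[paste(contrast, scheme, sep = "/")]] <-
        cl$clusters[, c("id", "sign", "t_start", "t_end", "n_points",
                        "mass", "p")]
      if (contrast %in% config$searchlight) {
        say("stage: searchlight %s / %s", contrast, scheme)
        sl <- searchlight_decode(pl$train, pl$plan, classes = classes,
                                 adjacency = adj, test_epochs = pl$test)
        avg <- moving_average(average_over_sensors(sl),
                              config$smooth_span_s)
        rep_i <- estimate_onset_peak(avg, threshold = config$bf_threshold,
                                     contrast = contrast, r = config$r,
                                     null_excl = config$null_excl)
        rep_i$scheme_dir <- scheme
        onset_rows[[paste(contrast, scheme)]] <- rep_i
        scalp_rows[[paste(contrast, scheme)]] <-
          scalp_map_bins(sl, bin_s = 0.05) |>
          dplyr::mutate(contrast = contrast, scheme_dir = scheme)
      }
    }
  }

  say("stage: write")
  files <- c(files, write_pipeline_tsv(
    dplyr::bind_rows(acc_rows), file.path(out_dir, "accuracy.tsv")))
  files <- c(files, write_pipeline_tsv(
    dplyr::bind_rows(stat_rows), file.path(out_dir, "stats.tsv")))
  jsonlite::write_json(cluster_tables,
                       file.path(out_dir, "clusters.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, "clusters.json")
  if (length(onset_rows) > 0) {
    onsets <- dplyr::bind_rows(onset_rows) |>
      dplyr::mutate(onset_ms = 1000 * .data$onset_s,
                    peak_ms = 1000 * .data$peak_s) |>
      dplyr::select("contrast", "scheme_dir", "onset_ms", "peak_ms",
                    "peak_bf", "peak_accuracy", "defined")
    files <- c(files, write_pipeline_tsv(
      onsets, file.path(out_dir, "onsets.tsv")))
    files <- c(files, write_pipeline_tsv(
      dplyr::bind_rows(scalp_rows), file.path(out_dir, "scalp_maps.tsv")))
  } else {
    onsets <- NULL
  }

  report <- list(
    package = "emodecode",
    version = as.character(utils::packageVersion("emodecode")),
    config_hash = rlang::hash(config),
    seed = config$seed,
    contrasts = names(config$contrasts),
    schemes = names(plans),
    n_perm = config$n_perm,
    alpha = config$alpha,
    bf_threshold = config$bf_threshold,
    datasets = list(
      a = list(id = config$design_a$dataset_id,
               participants = config$design_a$n_participants,
               pseudotrials = nrow(ep_a$trials)),
      b = list(id = config$design_b$dataset_id,
               participants = config$design_b$n_participants,
               pseudotrials = nrow(ep_b$trials))),
    fold_audit = lapply(plans, function(pl) {
      aud <- audit_fold_plan(pl$plan, pl$train,
                             pl$test %||% pl$train)
      list(scheme = attr(pl$plan, "scheme"), folds = nrow(aud),
           leak_free = all(aud$leak_free))
    }),
    files = files)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(report = report, onsets = onsets, out_dir = out_dir))
}

#' Scalp-map summary of a searchlight result
#'
#' Averages searchlight accuracies over units and over consecutive
#' time bins (50 ms by default), the format used for scalp-map
#' visualisation.
#'
#' @param sl a [searchlight_result()].
#' @param bin_s bin width in seconds.
#' @return A tibble with `channel`, `bin_start`, `bin_end`,
#'   `mean_accuracy`.
#' @export
scalp_map_bins <- function(sl, bin_s = 0.05) {
  stopifnot(inherits(sl, "searchlight_result"))
  unit_mean <- apply(sl$accuracy, c(2, 3), mean) # channels x time
  edges <- seq(sl$times[1], max(sl$times) + bin_s, by = bin_s)
  bin <- findInterval(sl$times, edges, rightmost.closed = FALSE)
  purrr::map_dfr(sort(unique(bin)), function(b) {
    sel <- bin == b
    tibble::tibble(channel = sl$channels,
                   bin_start = edges[b], bin_end = edges[b] + bin_s,
                   mean_accuracy = rowMeans(
                     unit_mean[, sel, drop = FALSE]))
  })
}
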