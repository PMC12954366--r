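#' Derive a reproducible sub-seed for a named random stream
#'
#' All stochastic components of the package (class templates, stimulus
#' effects, participant gains, sensor noise, pseudo-trial binning,
#' permutations) draw from independently seeded streams derived from one
#' master seed plus a stream name. Perturbing one stream (e.g. the noise)
#' leaves all others untouched, which makes partial re-randomisation in
#' tests reproducible.
#'
#' @param seed integer master seed.
#' @param name character stream name.
#' @return An integer seed below 2^31, deterministic in `(seed, name)`.
#' @export
#' @examples
#' substream_seed(1, "noise")
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483647 # 2^31 - 1, keeps everything in exact double range
  h <- seed %% m
  for (k in utf8ToInt(name)) {
    h <- (h * 131 + k) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a temporarily seeded RNG, restoring global state.
with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  expr
}

# Shared argument checks ------------------------------------------------

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}
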