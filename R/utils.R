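# Internal helpers shared across the package.

# Deterministic substream seeds: every stochastic stage draws from its own
# seed derived from the run's master seed, so stages can be re-run
# independently yet reproducibly. Kept below 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(seed, stream) {
  offsets <- c(
    tissue = 101L, events = 211L, render = 307L, noise = 401L,
    apical = 503L, bootstrap = 601L
  )
  if (!stream %in% names(offsets)) {
    abort(paste0("unknown seed substream: ", stream), class = "ipan_config_error")
  }
  (as.integer(seed) %% 2000000L) * 1000L + offsets[[stream]]
}

# Evaluate expr with a local RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_config <- function(msg) abort(msg, class = "ipan_config_error")
stop_format <- function(msg) abort(msg, class = "ipan_format_error")
stop_channel <- function(msg) abort(msg, class = "ipan_channel_error")
stop_geometry <- function(msg) abort(msg, class = "ipan_geometry_error")

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_scalar_positive <- function(x, name) {
  if (!is_scalar_number(x) || x <= 0) {
    stop_config(paste0("`", name, "` must be a single positive number"))
  }
  invisible(x)
}
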