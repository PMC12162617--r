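# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package functions never
#' disturb the caller's random-number stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive reproducible sub-seeds from one pipeline seed. All derived seeds are
# kept strictly below 2^31 so they remain representable as R integers.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_settledown <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "settledown_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop_settledown(
      sprintf("`%s` must be a single number in [%s, %s]", name, min, max),
      "settledown_config_error"
    )
  }
  invisible(x)
}

# Format a POSIXct as ISO-8601 local clock time (no timezone arithmetic).
format_ts <- function(x) format(x, "%Y-%m-%d %H:%M:%S", tz = "UTC")

parse_ts <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M:%S",
                                   "%Y-%m-%d %H:%M"))
  out
}
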