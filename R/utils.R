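# Internal helpers: seed plumbing shared by every stochastic entry point.
#
# All randomness flows from one master seed.  Sub-streams are derived by
# hashing the master seed together with a stream label (integers), so that
# each lesion / observation / perturbation draws from its own reproducible
# stream and modules can be exercised in isolation without consuming a
# global RNG sequence.

#' Derive a reproducible sub-stream seed from a master seed
#'
#' Hashes a master seed together with one or more integer stream labels
#' into a new seed in `[1, 2^31 - 2]`. The scheme is a multiplicative
#' linear-congruential mix; it is stable across platforms and R versions.
#'
#' @param seed Integer master seed.
#' @param ... Integer stream labels (e.g. patient index, lesion index,
#'   time-point index).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(42, 1, 3)
derive_seed <- function(seed, ...) {
  keys <- c(seed, unlist(list(...)))
  h <- 0
  m <- 2147483647  # 2^31 - 1, prime
  for (k in keys) {
    h <- (h * 48271 + (as.numeric(k) %% m) + 1) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

# Evaluate `expr` under `set.seed(seed)` and restore the caller's RNG state.
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

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ranobm <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "ranobm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
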