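# Internal helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Wrap angles into [0, 360).
wrap_deg <- function(x) ((x %% 360) + 360) %% 360

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so that
#' seeded generator calls do not disturb an enclosing simulation stream.
#' With `seed = NULL` the current stream is used unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("rng seed must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic sub-seed derivation; keeps values in (0, 2^31 - 1).
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 104729 * as.numeric(index)) %% 2147483647) + 1L
}

# Truncated-normal draws via the inverse-CDF map (no rejection loops, so the
# number of uniforms consumed is deterministic).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (all(sd == 0)) return(rep_len(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

stop_config <- function(...) stop(paste0("configuration error: ", ...), call. = FALSE)

is_point <- function(p) is.numeric(p) && length(p) == 2L && all(is.finite(p))
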