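# Seed derivation and scoped RNG streams.
#
# One master seed spawns named sub-streams (establishment sample, demand,
# absence, availability) so that scenarios sharing a master seed see common
# random numbers: demand and absence draws are identical across staffing
# plans and availability scenarios, and only the fill behaviour differs.

# purpose constants for sub-stream derivation
.PURPOSE <- c(
  hospital = 11L,
  demand = 23L,
  absence = 37L,
  availability = 53L,
  establishment = 71L
)

#' Derive a sub-stream seed from a master seed and stream labels
#'
#' Mixes a master seed with one or more integer labels into a new seed in
#' `[0, 2^31 - 2]` using a multiplicative-congruential mixer whose
#' intermediate products stay exactly representable in doubles. Used
#' internally to give every (purpose, unit, day) combination its own
#' reproducible stream.
#'
#' @param ... integers (master seed first, then stream labels).
#' @return A single integer seed.
#' @export
#' @examples
#' mix_seed(1, 23, 5)
mix_seed <- function(...) {
  ids <- c(...)
  if (length(ids) == 0L || any(!is.finite(ids))) {
    stop("mix_seed() needs at least one finite integer argument")
  }
  h <- 104729
  for (v in ids) {
    v <- as.numeric(v) %% 2147483647
    # h < 2^31 and 69069 < 2^17, so h * 69069 < 2^48: exact in a double
    h <- (h * 69069 + v + 1) %% 2147483647
  }
  as.integer(h)
}

# stable integer hash of a character id (for per-unit streams)
hash_id <- function(x) {
  vapply(
    as.character(x),
    function(s) mix_seed(7919L, utf8ToInt(s)),
    integer(1),
    USE.NAMES = FALSE
  )
}

# evaluate expr under a given seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# condition helpers: configuration errors are signalled with their own class
stop_config <- function(...) {
  stop(structure(
    class = c("wardflex_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_input <- function(...) {
  stop(structure(
    class = c("wardflex_input_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
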