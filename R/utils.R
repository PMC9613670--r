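#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library code never perturbs the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stream seed derivation: splits one run seed into
# independent substreams keyed by a string (e.g. epoch id), so epoch order
# never changes any epoch's draws. Plain 32-bit integer hashing; the result
# is always a valid seed in [0, 2^31 - 2].
derive_seed <- function(seed, key) {
  bytes <- utf8ToInt(paste0("s", key))
  h <- as.numeric(seed) %% 2147483647
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

stop_nmmap <- function(class, msg, ...) {
  stop(structure(class = c(class, "nmmap_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# shorthand validators used across modules
assert_that <- function(ok, class, msg, ...) {
  if (!isTRUE(ok)) stop_nmmap(class, msg, ...)
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
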