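# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so package functions are deterministic without
#' clobbering the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

#' Derive a stage-specific seed from a run seed
#'
#' Stable integer hash of (seed, stage label), kept in 1..2^31-2 so it is a
#' valid argument to [set.seed()]. Used so that one pipeline seed fans out to
#' independent, rerunnable per-stage streams.
#'
#' @param seed Integer run seed.
#' @param stage Character stage label, e.g. `"mda_drugs"`.
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(1L, "mda_drugs")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(stage)) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dtifuse <- function(msg, class) {
  stop(structure(class = c(class, "dtifuse_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Min-max scale a matrix to [0, 1]; a constant matrix maps to all zeros.
minmax_scale <- function(m) {
  rng <- range(m)
  if (rng[2] - rng[1] == 0) {
    m[] <- 0
    return(m)
  }
  (m - rng[1]) / (rng[2] - rng[1])
}
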