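#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds with `seed`, evaluates `expr`, and
#' restores the previous state on exit, so library code never perturbs the
#' user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from a master seed without collisions between
# stages: stage names hash to fixed offsets, runs count upward. Values kept
# well below .Machine$integer.max.
derive_seed <- function(master, stage, index = 0L) {
  stopifnot(length(master) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 131 + index) %% 2147483587) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# user-facing argument/precondition errors get a dedicated condition class so
# the CLI can map them to exit code 1 (internal faults exit 2)
stop_bad_arg <- function(msg) {
  stop(structure(class = c("nocistate_user_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# closed-interval index lookup on an integer-ms time axis
ms_index <- function(time_ms, lo, hi) which(time_ms >= lo & time_ms <= hi)
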