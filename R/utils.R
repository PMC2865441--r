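#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the current stream" (no restore).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible per-stage seed from a single pipeline seed.
# Kept strictly below 2^31 so it is always a valid R integer.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(cases = 101L, risks = 211L, panel = 307L,
               responses = 401L, thresholds = 503L, population = 601L)
  if (!stage %in% names(offsets)) stop("unknown pipeline stage: ", stage)
  as.integer((as.double(seed) * 7919 + offsets[[stage]]) %% 2147483647)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_prob <- function(x, name) {
  bad <- which(!is.finite(x) | x <= 0 | x >= 1)
  if (length(bad))
    stopf("%s must lie strictly in (0, 1); offending index: %d (value %s)",
          name, bad[1], format(x[bad[1]]))
  invisible(x)
}

logistic <- function(x) 1 / (1 + exp(-x))
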