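# Internal helpers shared across modules.

# Evaluate `code` under `set.seed(seed)` without clobbering the caller's RNG
# stream. `seed = NULL` leaves the current stream untouched (and advances it).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage seed fan-out from one user seed; keeps results
# reproducible when stages are rerun in isolation. Stays below 2^31.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) + 9973 * as.double(k)) %% 2147483647)
}

stop_if_not_prob <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) & is.finite(x) &
    (if (open) x > 0 & x < 1 else x >= 0 & x <= 1)
  if (!all(ok)) {
    stop(sprintf("`%s` must be in %s, got %s", name,
                 if (open) "(0, 1)" else "[0, 1]",
                 paste(format(x[!ok]), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
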