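# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_scalar <- function(x, name, lower = -Inf, strict = TRUE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop(name, " must be a finite numeric scalar")
  if (strict && x <= lower) stop(name, " must be > ", lower)
  if (!strict && x < lower) stop(name, " must be >= ", lower)
  invisible(as.numeric(x))
}
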