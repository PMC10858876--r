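# Internal helpers: seed management, argument checking.

#' Evaluate an expression under a fixed RNG seed, restoring the caller's stream
#'
#' All generators in the package are pure functions of (config, seed): they
#' seed a local RNG stream and restore the global one on exit, so calling a
#' generator never perturbs user-level randomness.
#'
#' @param seed integer scalar.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-session seed from a master seed
#'
#' Deterministic integer mix so cohort sessions are mutually independent yet
#' reproducible from the single master seed. Kept below 2^31 - 1.
#' @noRd
derive_seed <- function(master_seed, index) {
  m <- as.numeric(master_seed) %% 2147483647
  # LCG-style mix; coefficients are the classic MINSTD multiplier.
  s <- (m * 48271 + as.numeric(index) * 2246822519) %% 2147483647
  as.integer(s)
}

# single positive finite numeric
check_scalar <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("configuration error: `%s` must be a single finite number", name),
         call. = FALSE)
  }
  if ((strict_min && x <= min) || (!strict_min && x < min) || x > max) {
    stop(sprintf("configuration error: `%s` = %g is outside its valid range", name, x),
         call. = FALSE)
  }
  invisible(x)
}

# Index vector of samples whose time t0 + (i-1)/fs lies in [start, end).
# Half-open windows throughout the package.
window_idx <- function(t0, fs, n, start, end) {
  i0 <- ceiling((start - t0) * fs - 1e-9) + 1
  i1 <- floor((end - t0) * fs + 1 - 1e-9)
  i0 <- max(1L, as.integer(i0))
  i1 <- min(as.integer(n), as.integer(i1))
  if (i1 < i0) integer(0) else seq.int(i0, i1)
}
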