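#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the global RNG state, seeds it, evaluates `code`, and restores the
#' previous state on exit. All stochastic operations in the package route
#' their `seed` argument through this helper so that they are pure functions
#' of their inputs and never disturb the caller's random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

# 2-D summed-area table; S[i+1, j+1] = sum of m[1:i, 1:j].
integral_image <- function(m) {
  s <- apply(m, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  rbind(0, cbind(0, s))
}

# Sum of m over half-open 0-based window [r, r+h) x [c, c+w), vectorised over
# equal-length vectors r, c. `S` is integral_image(m).
window_sum <- function(S, r, c, h, w) {
  S[cbind(r + h + 1L, c + w + 1L)] - S[cbind(r + 1L, c + w + 1L)] -
    S[cbind(r + h + 1L, c + 1L)] + S[cbind(r + 1L, c + 1L)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
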