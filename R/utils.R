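## Small internal helpers shared across the package.

#' Run code with a temporarily fixed RNG state
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded helpers do not disturb the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## open (full) convolution of two score-weight vectors, O(n1*n2);
## score ranges are tiny (<= ~60) so no FFT needed
conv_score <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

## numerically safe log of a positive vector that carries a log-scale
logsum_scaled <- function(v, ls) log(v) + ls

## Gauss-Hermite nodes/weights for N(0,1) expectation via Golub-Welsch.
## Returns nodes x and weights w such that E[f(Z)] ~= sum(w * f(x)).
gauss_hermite_norm <- function(n = 41L) {
  i <- seq_len(n - 1L)
  off <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- off
  J[cbind(i + 1L, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- e$vectors[1L, ]^2
  ord <- order(x)
  list(x = sqrt(2) * x[ord], w = w[ord])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## deterministic signature of a model spec (for oscillation detection)
spec_signature <- function(items, spec) {
  ld <- vapply(spec$ld, function(e) paste(sort(e), collapse = "~"), "")
  df <- vapply(spec$dif, function(d) paste(d, collapse = ":"), "")
  paste(paste(sort(items), collapse = ","),
        paste(sort(ld), collapse = ";"),
        paste(sort(df), collapse = ";"), sep = "|")
}
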