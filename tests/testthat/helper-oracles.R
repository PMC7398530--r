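## Brute-force oracles and small fixtures shared across the test files.
## Every oracle enumerates the full pattern space directly and never reuses
## the package's ESF/convolution machinery.

## all response patterns for items with maxima m (0-based categories)
all_patterns <- function(m) {
  as.matrix(expand.grid(lapply(m, function(mm) 0:mm)))
}

## brute-force ESF coefficients gamma_r from per-item threshold vectors
bf_esf <- function(tau) {
  m <- vapply(tau, length, 1L)
  pat <- all_patterns(m)
  lw <- vapply(seq_along(tau), function(i) {
    beta <- c(0, -cumsum(tau[[i]]))
    beta[pat[, i] + 1L]
  }, numeric(nrow(pat)))
  w <- exp(rowSums(lw))
  as.numeric(tapply(w, rowSums(pat), sum))
}

## brute-force conditional pattern probability P(X = x | S = r)
bf_cond_prob <- function(x, tau) {
  m <- vapply(tau, length, 1L)
  pat <- all_patterns(m)
  lw <- vapply(seq_along(tau), function(i) {
    beta <- c(0, -cumsum(tau[[i]]))
    beta[pat[, i] + 1L]
  }, numeric(nrow(pat)))
  w <- exp(rowSums(lw))
  r <- sum(x)
  idx <- which(apply(pat, 1L, function(p) all(p == x)))
  w[idx] / sum(w[rowSums(pat) == r])
}

## brute-force gamma by pair counting
bf_gamma <- function(x, y) {
  C <- 0; D <- 0
  n <- length(x)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- (x[i] - x[j]) * (y[i] - y[j])
    if (d > 0) C <- C + 1 else if (d < 0) D <- D + 1
  }
  (C - D) / (C + D)
}

## a small centred six-item threshold set used throughout
toy_tau6 <- function() {
  tau <- list(I1 = c(-1, 0, 1), I2 = c(-0.5, 0.2, 0.8), I3 = c(0, 0, 0.2),
              I4 = c(-0.8, 0.1, 0.7), I5 = c(-0.2, 0.1, 0.3),
              I6 = c(0.4, -0.3, 0.2))
  lapply(tau, function(t) t - mean(unlist(tau)))
}

quickfit <- list(se = FALSE)
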