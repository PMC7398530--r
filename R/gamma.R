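## Goodman-Kruskal gamma and stratified (partial) gamma for ordinal tables.
## No pre-installed package provides these, and they are central machinery
## here, so they are implemented from the concordance counts directly.

## concordant/discordant partner counts per cell of a (possibly weighted)
## two-way table
concordance_counts <- function(N) {
  R <- nrow(N); C <- ncol(N)
  P <- matrix(0, R + 1L, C + 1L)
  for (i in seq_len(R)) for (j in seq_len(C))
    P[i + 1L, j + 1L] <- N[i, j] + P[i, j + 1L] + P[i + 1L, j] - P[i, j]
  tot <- P[R + 1L, C + 1L]
  con <- dis <- matrix(0, R, C)
  for (i in seq_len(R)) for (j in seq_len(C)) {
    bl <- P[i, j]                                   # k < i, l < j
    ar <- tot - P[i + 1L, C + 1L] - P[R + 1L, j + 1L] + P[i + 1L, j + 1L]
    br <- P[i, C + 1L] - P[i, j + 1L]               # k < i, l > j
    al <- P[R + 1L, j] - P[i + 1L, j]               # k > i, l < j
    con[i, j] <- bl + ar
    dis[i, j] <- br + al
  }
  list(con = con, dis = dis)
}

#' Goodman-Kruskal gamma rank correlation
#'
#' Computes gamma for two ordinal variables (or a pre-tabulated, possibly
#' weighted, two-way table), with the asymptotic standard errors under the
#' alternative (`ase1`) and under independence (`ase0`, used for testing).
#'
#' @param x,y ordinal vectors, or `x` a two-way table of (possibly
#'   non-integer) non-negative weights with `y` missing.
#' @return A list with `gamma`, `ase1`, `ase0`, `z` (gamma / ase0), `P`,
#'   `Q` (twice the concordant/discordant pair counts) and `n`.
#' @export
gk_gamma <- function(x, y = NULL) {
  N <- if (is.null(y)) as.matrix(x) else unclass(table(x, y))
  n <- sum(N)
  cd <- concordance_counts(N)
  P <- sum(N * cd$con); Q <- sum(N * cd$dis)
  if (P + Q <= 0)
    return(list(gamma = NA_real_, ase1 = NA_real_, ase0 = NA_real_,
                z = NA_real_, P = P, Q = Q, n = n))
  g <- (P - Q) / (P + Q)
  ase1 <- 4 * sqrt(sum(N * (Q * cd$con - P * cd$dis)^2)) / (P + Q)^2
  v0 <- sum(N * (cd$con - cd$dis)^2) - (P - Q)^2 / n
  ase0 <- if (v0 > 0) 2 * sqrt(v0) / (P + Q) else NA_real_
  list(gamma = g, ase1 = ase1, ase0 = ase0,
       z = if (!is.na(ase0) && ase0 > 0) g / ase0 else NA_real_,
       P = P, Q = Q, n = n)
}

#' Partial (stratified) Goodman-Kruskal gamma
#'
#' Computes gamma within strata of a conditioning variable (here typically a
#' restscore), pools the stratum pair counts into an overall partial gamma,
#' and tests the null of conditional independence by inverse-variance
#' weighting of the stratum gammas (null variances; degenerate strata are
#' dropped).
#'
#' @param x,y ordinal vectors.
#' @param strata conditioning variable (coerced to factor).
#' @return A list with `gamma` (pooled partial gamma), `se`, `z`, `p`
#'   (two-sided normal), and `n_strata` (informative strata used).  All
#'   `NA` with `n_strata = 0` if every stratum is degenerate.
#' @export
partial_gamma <- function(x, y, strata) {
  f <- as.factor(strata)
  Psum <- 0; Qsum <- 0
  wsum <- 0; wg <- 0
  used <- 0L
  for (lev in levels(f)) {
    sel <- f == lev
    if (sum(sel) < 2L) next
    g <- gk_gamma(x[sel], y[sel])
    if (is.na(g$gamma) || is.na(g$ase0) || g$ase0 <= 0) next
    Psum <- Psum + g$P; Qsum <- Qsum + g$Q
    w <- 1 / g$ase0^2
    wsum <- wsum + w
    wg <- wg + w * g$gamma
    used <- used + 1L
  }
  if (used == 0L || Psum + Qsum <= 0)
    return(list(gamma = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
                n_strata = 0L))
  z <- wg / sqrt(wsum)
  list(gamma = (Psum - Qsum) / (Psum + Qsum), se = 1 / sqrt(wsum), z = z,
       p = 2 * stats::pnorm(-abs(z)), n_strata = used)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment of a family of p-values (wrapper around
#' [stats::p.adjust()] with input validation).
#'
#' @param p numeric vector of raw p-values in `[0, 1]`; `NA`s are kept.
#' @return Adjusted p-values, monotone and bounded by 1.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) stop("empty p-value family")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
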