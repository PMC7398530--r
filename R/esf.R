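## Elementary symmetric function machinery for conditional likelihoods.
##
## Each (generalized) item contributes a vector of category log-weights
## beta_{x}, x = 0..m (beta_0 = 0 for plain items).  The ESF coefficients
## gamma_r are the score-r coefficients of the product polynomial
## prod_i sum_x exp(beta_{ix}) z^x, computed by sequential convolution with
## per-item rescaling for numerical stability.

## internal: convolve a list of log-weight vectors into (gamma, logscale)
esf_scaled <- function(log_weights) {
  stopifnot(length(log_weights) >= 1L)
  ls <- 0
  gam <- 1
  for (lw in log_weights) {
    mx <- max(lw)
    gam <- conv_score(gam, exp(lw - mx))
    ls <- ls + mx
    gmx <- max(gam)
    if (!is.finite(gmx) || gmx <= 0)
      stop("elementary symmetric function underflow/overflow despite rescaling")
    if (gmx > 1e100 || gmx < 1e-100) {
      gam <- gam / gmx
      ls <- ls + log(gmx)
    }
  }
  list(gamma = gam, logscale = ls)
}

#' Elementary symmetric functions of a polytomous Rasch model
#'
#' Computes the coefficients \eqn{\gamma_r}, r = 0..max score, of the
#' conditional-likelihood normalising polynomial for a set of (generalized)
#' items, by sequential polynomial convolution with numerical rescaling.
#'
#' @param tau list of per-item threshold vectors \eqn{\tau_{i,1..m_i}}
#'   (logits); item i has category log-weights
#'   \eqn{\beta_{ix} = -\sum_{k \le x} \tau_{ik}}, \eqn{\beta_{i0} = 0}.
#'   Alternatively, entries may be full log-weight vectors including the 0
#'   category, marked by `weights = TRUE`.
#' @param log return log gamma instead of gamma.
#' @param weights if `TRUE`, `tau` entries are log-weight vectors
#'   \eqn{(\beta_{i0}, ..., \beta_{im_i})} rather than thresholds.
#' @return Numeric vector \eqn{(\gamma_0, ..., \gamma_R)}; every attainable
#'   score has \eqn{\gamma_r > 0}.
#' @examples
#' esf(list(0))            # one dichotomous item, tau = 0: (1, 1)
#' esf(list(0, 0, 0))      # binomial coefficients (1, 3, 3, 1)
#' @export
esf <- function(tau, log = FALSE, weights = FALSE) {
  if (!length(tau)) stop("at least one item is required")
  lw <- lapply(tau, function(t) if (weights) t else c(0, -cumsum(t)))
  g <- esf_scaled(lw)
  if (log) logsum_scaled(g$gamma, g$logscale) else g$gamma * exp(g$logscale)
}

#' Conditional probability of a response vector given its total score
#'
#' Under the polytomous Rasch model the total score is sufficient for the
#' latent trait, so the conditional probability of a response pattern given
#' its score is free of the person parameter:
#' \eqn{P(X = x | S = r) = \exp(\sum_i \beta_{i,x_i}) / \gamma_r}.
#'
#' @param x integer response vector (0-based categories).
#' @param r total score; must equal `sum(x)`.
#' @param tau list of per-item threshold vectors.
#' @return The conditional probability.
#' @export
conditional_prob <- function(x, r, tau) {
  if (sum(x) != r) stop("sum(x) must equal r")
  m <- vapply(tau, length, 1L)
  if (r < 0 || r > sum(m)) stop("score r is unattainable")
  lw <- lapply(tau, function(t) c(0, -cumsum(t)))
  num <- sum(vapply(seq_along(x), function(i) lw[[i]][x[i] + 1L], 0))
  g <- esf_scaled(lw)
  exp(num - (log(g$gamma[r + 1L]) + g$logscale))
}
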