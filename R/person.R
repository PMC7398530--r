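## Person parameter estimation: score <-> theta tables, information, SEM.

## absolute component log-weights for group g at the fitted parameters
group_logw <- function(fit, g = 1L) {
  lapply(fit$model$components, function(comp)
    list(lw = as.vector(comp$A[[g]] %*% fit$coefficients), score = comp$score))
}

## mean and variance of the total score at theta (vectorised over theta)
escore_moments <- function(logw, theta) {
  E <- numeric(length(theta)); V <- numeric(length(theta))
  for (cw in logw) {
    for (ti in seq_along(theta)) {
      z <- cw$lw + theta[ti] * cw$score
      z <- exp(z - max(z))
      pz <- z / sum(z)
      mu <- sum(pz * cw$score)
      E[ti] <- E[ti] + mu
      V[ti] <- V[ti] + sum(pz * (cw$score - mu)^2)
    }
  }
  list(mean = E, var = V)
}

solve_theta <- function(logw, r, lower = -40, upper = 40) {
  f <- function(th) escore_moments(logw, th)$mean - r
  ## E[S|theta] can saturate inside the interval when an interaction or DIF
  ## parameter diverges (zero-frequency cell in a subgroup): clamp rather
  ## than fail, the value is display-only at such boundaries
  if (f(lower) >= 0) return(lower)
  if (f(upper) <= 0) return(upper)
  stats::uniroot(f, c(lower, upper), tol = 1e-9)$root
}

#' Score-to-theta conversion table with measurement precision
#'
#' For every attainable total score the maximum-likelihood person location
#' \eqn{\hat\theta(r)} solves \eqn{E[S|\theta] = r}; its standard error of
#' measurement is \eqn{1/\sqrt{I(\hat\theta)}} with \eqn{I(\theta) =
#' Var(S|\theta)} the test information.  Extreme scores have no finite ML
#' estimate and are tabulated, for display only, at \eqn{r \pm 0.3} score
#' units; they never enter estimation.
#'
#' @param fit a fitted [gllrm] object.
#' @param group group index (row of `fit$model$groups`) whose parameters to
#'   use; irrelevant for models without DIF terms.
#' @param extreme_delta displacement used for the extreme-score
#'   extrapolation (default 0.3).
#' @return A data frame with columns `score`, `theta`, `sem`, `info`,
#'   `extreme`.
#' @export
score_table <- function(fit, group = 1L, extreme_delta = 0.3) {
  stopifnot(inherits(fit, "gllrm"))
  logw <- group_logw(fit, group)
  R <- fit$model$max_score
  theta <- numeric(R + 1L)
  for (r in seq_len(R - 1L)) theta[r + 1L] <- solve_theta(logw, r)
  theta[1L] <- solve_theta(logw, extreme_delta)
  theta[R + 1L] <- solve_theta(logw, R - extreme_delta)
  mom <- escore_moments(logw, theta)
  info <- mom$var
  data.frame(score = 0:R, theta = theta, sem = 1 / sqrt(info), info = info,
             extreme = c(TRUE, rep(FALSE, R - 1L), TRUE))
}

## test information over a theta grid
info_curve <- function(fit, group = 1L, theta = seq(-6, 6, length.out = 121L)) {
  logw <- group_logw(fit, group)
  data.frame(theta = theta, info = escore_moments(logw, theta)$var)
}

## map each person's group to a row of the groups grid
person_groups <- function(fit) fit$group
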