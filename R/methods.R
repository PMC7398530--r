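## S3 methods for fitted gllrm objects.

#' @export
print.gllrm <- function(x, ...) {
  if (spec_is_empty(x$spec)) cat("Polytomous Rasch model (CML)\n")
  else cat("Graphical log-linear Rasch model (CML)\n")
  cat("items:", paste(x$item_ids, collapse = ", "), "\n")
  if (length(x$spec$ld))
    cat("LD edges:", paste(vapply(x$spec$ld, paste, "", collapse = "~"),
                           collapse = ", "), "\n")
  if (length(x$spec$dif))
    cat("DIF terms:", paste(vapply(x$spec$dif, paste, "", collapse = ":"),
                            collapse = ", "), "\n")
  cat("persons:", x$n, "(", x$n_used, "non-extreme used,", x$n_extreme,
      "extreme )\n")
  cat("conditional logLik:", format(x$logLik, digits = 7),
      " free parameters:", x$df, "\n")
  if (!x$converged)
    cat("WARNING: not converged (max |gradient| = ",
        format(x$gradient_norm, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' @export
coef.gllrm <- function(object, type = c("all", "tau", "lambda", "delta"), ...) {
  type <- match.arg(type)
  cf <- object$coefficients
  switch(type,
    all = cf,
    tau = tau_full(object),
    lambda = cf[grepl("^lam\\(", names(cf))],
    delta = cf[grepl("^dif\\(", names(cf))])
}

#' @export
logLik.gllrm <- function(object, ...) {
  structure(object$logLik, df = object$df, nobs = object$n_used,
            class = "logLik")
}

#' @export
vcov.gllrm <- function(object, ...) object$vcov

#' @export
summary.gllrm <- function(object, ...) {
  tau <- tau_full(object)
  Kf <- object$model$K - 1L
  se_tau <- c(object$se[seq_len(Kf)],
              if (!is.null(object$vcov))
                sqrt(max(0, sum(object$vcov[seq_len(Kf), seq_len(Kf)])))
              else NA_real_)
  thr <- data.frame(item = object$item_ids[object$model$tau_idx[, 1L]],
                    k = object$model$tau_idx[, 2L],
                    tau = unname(tau), se = unname(se_tau))
  other <- object$coefficients[-seq_len(Kf)]
  inter <- if (length(other))
    data.frame(term = names(other), estimate = unname(other),
               se = unname(object$se[-seq_len(Kf)]))
  else NULL
  out <- list(call = object$call, thresholds = thr, interactions = inter,
              logLik = object$logLik, df = object$df,
              n_used = object$n_used, n_extreme = object$n_extreme,
              converged = object$converged, spec = object$spec,
              collapse_log = object$collapse_log)
  class(out) <- "summary.gllrm"
  out
}

#' @export
print.summary.gllrm <- function(x, digits = 3, ...) {
  cat("Conditional maximum likelihood fit\n\n")
  cat("Item thresholds (sum-to-zero identification):\n")
  print(format(x$thresholds, digits = digits), row.names = FALSE)
  if (!is.null(x$interactions)) {
    cat("\nInteraction parameters (LD corner / DIF reference constraints):\n")
    print(format(x$interactions, digits = digits), row.names = FALSE)
  }
  if (length(x$collapse_log))
    cat("\nNote:", length(x$collapse_log),
        "zero-frequency categor(ies) merged before estimation\n")
  cat("\nconditional logLik ", format(x$logLik, digits = 7), " on ", x$df,
      " free parameters; n used = ", x$n_used, " (+", x$n_extreme,
      " extreme)\n", sep = "")
  if (!x$converged) cat("WARNING: fit did not converge\n")
  invisible(x)
}

#' Model predictions at given latent locations
#'
#' @param object a fitted [gllrm] object.
#' @param theta vector of latent locations.
#' @param group covariate group index (row of `object$model$groups`).
#' @param type `"expected"` for the expected total score, `"information"`
#'   for test information \eqn{Var(S|\theta)}, `"prob"` for per-item
#'   category probabilities (a list of matrices, one per theta).
#' @param ... unused.
#' @export
predict.gllrm <- function(object, theta = 0, group = 1L,
                          type = c("expected", "information", "prob"), ...) {
  type <- match.arg(type)
  logw <- group_logw(object, group)
  if (type == "expected") return(escore_moments(logw, theta)$mean)
  if (type == "information") return(escore_moments(logw, theta)$var)
  comps <- object$model$components
  lapply(theta, function(th) {
    P <- matrix(0, length(object$item_ids), max(object$m) + 1L,
                dimnames = list(object$item_ids, 0:max(object$m)))
    for (ci in seq_along(comps)) {
      comp <- comps[[ci]]
      z <- logw[[ci]]$lw + th * comp$score
      pz <- exp(z - max(z)); pz <- pz / sum(pz)
      for (p in seq_along(comp$members)) {
        i <- comp$members[p]
        for (x in 0:object$m[i])
          P[i, x + 1L] <- sum(pz[comp$combos[, p] == x])
      }
    }
    P
  })
}

#' Residuals of a fitted model
#'
#' Standardised item-total residuals: for each item, the observed item total
#' among non-extreme persons minus its conditional expectation given the
#' observed scores, divided by the conditional standard deviation.
#'
#' @param object a fitted [gllrm] object.
#' @param ... unused.
#' @export
residuals.gllrm <- function(object, ...) {
  em <- item_expectations(object)
  (em$obs - em$expected) / sqrt(pmax(em$var, .Machine$double.eps))
}

## conditional mean/variance of each item total given observed scores
item_expectations <- function(fit) {
  I <- length(fit$item_ids)
  obs <- colSums(fit$responses[fit$include, , drop = FALSE])
  expd <- numeric(I); va <- numeric(I)
  for (g in sort(unique(fit$group))) {
    sel <- fit$include & fit$group == g
    if (!any(sel)) next
    sc <- table(factor(fit$score[sel], levels = 0:fit$model$max_score))
    cm <- cond_item_moments(fit, g)
    ns <- as.numeric(sc)
    expd <- expd + as.vector(cm$mean %*% ns)
    va <- va + as.vector(cm$var %*% ns)
  }
  list(obs = obs, expected = expd, var = va)
}

## P-derived per-item conditional mean/variance given total score, group g:
## matrices I x (R+1)
cond_item_moments <- function(fit, g) {
  comps <- fit$model$components
  R <- fit$model$max_score
  I <- length(fit$item_ids)
  M <- matrix(0, I, R + 1L); V <- matrix(0, I, R + 1L)
  pc <- comp_conditionals(fit, g)
  for (ci in seq_along(comps)) {
    comp <- comps[[ci]]
    Pk <- pc[[ci]] # ncombo x (R+1): P(combo | S = r)
    for (p in seq_along(comp$members)) {
      i <- comp$members[p]
      x <- comp$combos[, p]
      M[i, ] <- colSums(Pk * x)
      V[i, ] <- colSums(Pk * x^2) - M[i, ]^2
    }
  }
  list(mean = M, var = V)
}

## conditional combo distributions per component given each total score
comp_conditionals <- function(fit, g) {
  comps <- fit$model$components
  C <- length(comps)
  p <- fit$coefficients
  ucs <- lapply(comps, comp_u, g = g, p = p)
  prefix <- vector("list", C + 1L); suffix <- vector("list", C + 1L)
  prefix[[1L]] <- 1; suffix[[C + 1L]] <- 1
  for (ci in seq_len(C)) prefix[[ci + 1L]] <- conv_score(prefix[[ci]], ucs[[ci]]$u)
  for (ci in rev(seq_len(C))) suffix[[ci]] <- conv_score(ucs[[ci]]$u, suffix[[ci + 1L]])
  gam <- prefix[[C + 1L]]
  R <- length(gam) - 1L
  out <- vector("list", C)
  for (ci in seq_len(C)) {
    comp <- comps[[ci]]
    gmc <- conv_score(prefix[[ci]], suffix[[ci + 1L]])
    Pk <- matrix(0, nrow(comp$combos), R + 1L)
    for (r in 0:R) {
      if (gam[r + 1L] <= 0) next
      d <- r - comp$score
      ok <- d >= 0L & d < length(gmc)
      Pk[ok, r + 1L] <- ucs[[ci]]$w[ok] * gmc[d[ok] + 1L] / gam[r + 1L]
    }
    out[[ci]] <- Pk
  }
  out
}

#' Person-item map and information plot
#'
#' Plots the test information curve with the fitted item threshold
#' locations (rug) and a histogram of estimated person locations.
#'
#' @param x a fitted [gllrm] object.
#' @param group covariate group index.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gllrm <- function(x, group = 1L, ...) {
  ic <- info_curve(x, group)
  st <- score_table(x, group)
  th_pers <- st$theta[match(x$score[x$include], st$score)]
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(ic$theta, ic$info, type = "l", xlab = "", ylab = "test information",
                 main = "Targeting", ...)
  graphics::rug(tau_full(x))
  graphics::hist(th_pers, breaks = 20, xlim = range(ic$theta),
                 main = "", xlab = "theta", ylab = "persons")
  invisible(x)
}
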