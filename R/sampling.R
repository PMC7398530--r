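## Exact samplers for (G)LLRM response patterns, shared by the synthetic-data
## generator, the parametric bootstrap and the simulate() method.
##
## A "sampler component" is list(members, combos, score, lw): the generalized
## item's member column indices, its category-combination matrix, the combo
## scores and the absolute log-weights (for one covariate group).

## sampler components from a fitted model for one group
fit_sampler <- function(fit, g = 1L) {
  lapply(fit$model$components, function(comp)
    list(members = comp$members, combos = comp$combos, score = comp$score,
         lw = as.vector(comp$A[[g]] %*% fit$coefficients)))
}

## draw one response matrix given person locations theta (unconditional)
rpatterns_theta <- function(scomps, theta, nitems) {
  n <- length(theta)
  out <- matrix(0L, n, nitems)
  for (sc in scomps) {
    z <- sc$lw + outer(sc$score, theta) # ncombo x n log-weights
    z <- exp(sweep(z, 2L, apply(z, 2L, max)))
    cum <- apply(z, 2L, cumsum)
    tot <- cum[nrow(cum), ]
    u <- stats::runif(n) * tot
    k <- 1L + colSums(cum < rep(u, each = nrow(cum)))
    out[, sc$members] <- sc$combos[k, , drop = FALSE]
  }
  out
}

## draw one response matrix with fixed total scores (conditional sampler):
## components are visited sequentially and each combo is drawn from its
## conditional distribution given the remaining score
rpatterns_score <- function(scomps, scores, nitems) {
  n <- length(scores)
  C <- length(scomps)
  out <- matrix(0L, n, nitems)
  ## scaled linear weights and suffix gammas
  ws <- lapply(scomps, function(sc) exp(sc$lw - max(sc$lw)))
  suf <- vector("list", C + 1L)
  suf[[C + 1L]] <- 1
  for (ci in rev(seq_len(C))) {
    u <- as.vector(rowsum(ws[[ci]], factor(scomps[[ci]]$score,
                                           levels = 0:max(scomps[[ci]]$score))))
    suf[[ci]] <- conv_score(u, suf[[ci + 1L]])
  }
  rem <- as.integer(scores)
  for (ci in seq_len(C)) {
    sc <- scomps[[ci]]
    maxrem <- length(suf[[ci]]) - 1L
    ncombo <- nrow(sc$combos)
    ## P[k, r+1] = w_k * suf_{c+1}[r - s_k] / suf_c[r]
    P <- matrix(0, ncombo, maxrem + 1L)
    nxt <- suf[[ci + 1L]]
    for (k in seq_len(ncombo)) {
      rr <- sc$score[k]:(sc$score[k] + length(nxt) - 1L)
      rr <- rr[rr <= maxrem]
      P[k, rr + 1L] <- ws[[ci]][k] * nxt[rr - sc$score[k] + 1L]
    }
    cum <- apply(P, 2L, cumsum)
    cumsel <- cum[, rem + 1L, drop = FALSE]
    tot <- cumsel[ncombo, ]
    u <- stats::runif(n) * tot
    k <- 1L + colSums(cumsel < rep(u, each = ncombo))
    out[, sc$members] <- sc$combos[k, , drop = FALSE]
    rem <- rem - sc$score[k]
  }
  stopifnot(all(rem == 0L))
  out
}

#' Simulate response data from a fitted model
#'
#' Draws replicate response matrices from the fitted (G)LLRM, either
#' conditionally on each person's observed total score (the parametric
#' bootstrap used by the fit diagnostics; score sufficiency makes this
#' distribution free of the person parameters) or at supplied person
#' locations.
#'
#' @param object a fitted [gllrm] object.
#' @param nsim number of replicate datasets.
#' @param seed optional RNG seed.
#' @param theta optional vector of person locations; when supplied the
#'   replicates are drawn unconditionally at these locations (using each
#'   person's covariate group), otherwise conditionally on observed scores.
#' @param ... unused.
#' @return A list of `nsim` integer response matrices.
#' @export
simulate.gllrm <- function(object, nsim = 1L, seed = NULL, theta = NULL, ...) {
  n <- nrow(object$responses)
  I <- length(object$item_ids)
  groups <- object$group
  with_seed(seed, {
    lapply(seq_len(nsim), function(s) {
      out <- matrix(0L, n, I, dimnames = list(NULL, object$item_ids))
      for (g in sort(unique(groups))) {
        sel <- groups == g
        sg <- fit_sampler(object, g)
        out[sel, ] <- if (is.null(theta))
          rpatterns_score(sg, object$score[sel], I)
        else rpatterns_theta(sg, theta[sel], I)
      }
      out
    })
  })
}
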