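## Conditional maximum likelihood fitting of Rasch models and GLLRMs.

## ---------------------------------------------------------------------------
## Likelihood internals.  The conditional log-likelihood over non-extreme
## persons is  cll(p) = t_obs' p - sum_{g,r} n_{g,r} log gamma_g(r; p),
## where gamma_g is the ESF (convolution over generalized items) of group g
## and t_obs the observed sufficient statistics.  The model is a canonical
## exponential family in p, so cll is concave.

build_cll <- function(model, resp, group, score, include) {
  G <- model$G
  comps <- model$components
  R <- model$max_score
  n_gr <- matrix(0, G, R + 1L)
  for (g in seq_len(G)) {
    sel <- include & group == g
    if (any(sel)) n_gr[g, ] <- tabulate(score[sel] + 1L, R + 1L)
  }
  used_g <- which(rowSums(n_gr) > 0)
  ## observed combo counts per (component, group), and t_obs
  t_obs <- numeric(model$npar)
  obs_counts <- vector("list", length(comps))
  for (ci in seq_along(comps)) {
    idx <- combo_index(comps[[ci]], resp)
    cnt <- matrix(0, nrow(comps[[ci]]$combos), G)
    for (g in used_g) {
      sel <- include & group == g
      if (any(sel)) cnt[, g] <- tabulate(idx[sel], nrow(cnt))
    }
    obs_counts[[ci]] <- cnt
    for (g in used_g)
      t_obs <- t_obs + drop(crossprod(comps[[ci]]$A[[g]], cnt[, g]))
  }

  cll <- function(p) {
    val <- sum(t_obs * p)
    for (g in used_g) {
      ls <- 0
      gam <- 1
      for (comp in comps) {
        uc <- comp_u(comp, g, p)
        gam <- conv_score(gam, uc$u)
        ls <- ls + uc$logscale
      }
      r_idx <- which(n_gr[g, ] > 0)
      val <- val - sum(n_gr[g, r_idx] * (log(gam[r_idx]) + ls))
    }
    val
  }

  grad <- function(p) {
    gr <- t_obs
    C <- length(comps)
    for (g in used_g) {
      ucs <- lapply(comps, comp_u, g = g, p = p)
      prefix <- vector("list", C + 1L)
      suffix <- vector("list", C + 1L)
      prefix[[1L]] <- 1
      for (ci in seq_len(C)) prefix[[ci + 1L]] <- conv_score(prefix[[ci]], ucs[[ci]]$u)
      suffix[[C + 1L]] <- 1
      for (ci in rev(seq_len(C))) suffix[[ci]] <- conv_score(ucs[[ci]]$u, suffix[[ci + 1L]])
      gam <- prefix[[C + 1L]]
      ratio <- numeric(length(gam))
      r_idx <- which(n_gr[g, ] > 0)
      ratio[r_idx] <- n_gr[g, r_idx] / gam[r_idx]
      for (ci in seq_len(C)) {
        gmc <- conv_score(prefix[[ci]], suffix[[ci + 1L]]) # gamma without comp ci
        Sc <- comps[[ci]]$max_score
        h <- numeric(Sc + 1L)
        for (s in 0:Sc) {
          rr <- r_idx[r_idx - s >= 1L & r_idx - s <= length(gmc)]
          if (length(rr)) h[s + 1L] <- sum(ratio[rr] * gmc[rr - s])
        }
        e <- ucs[[ci]]$w * h[comps[[ci]]$score + 1L]
        gr <- gr - drop(crossprod(comps[[ci]]$A[[g]], e))
      }
    }
    gr
  }

  list(cll = cll, grad = grad, n_gr = n_gr, t_obs = t_obs, used_g = used_g)
}

## numeric Hessian of the gradient (central differences)
num_hessian <- function(grad, p, h = 1e-5) {
  n <- length(p)
  H <- matrix(0, n, n)
  for (j in seq_len(n)) {
    hj <- h * (1 + abs(p[j]))
    pp <- p; pp[j] <- pp[j] + hj
    pm <- p; pm[j] <- pm[j] - hj
    H[, j] <- (grad(pp) - grad(pm)) / (2 * hj)
  }
  (H + t(H)) / 2
}

## collapse zero-frequency categories (adjacent-lower merge), iterating with
## extreme-score recomputation until stable
collapse_zero_categories <- function(resp, m) {
  log <- list()
  repeat {
    mx <- sum(m)
    s <- rowSums(resp)
    include <- s > 0L & s < mx
    changed <- FALSE
    for (j in seq_along(m)) {
      cnt <- tabulate(resp[include, j] + 1L, m[j] + 1L)
      z <- which(cnt == 0L)
      if (!length(z)) next
      if (m[j] < 2L)
        stop("item ", names(m)[j], " has a single observed category among ",
             "non-extreme persons; it cannot be estimated")
      k <- z[1L] - 1L # 0-based empty category
      map <- 0:m[j]
      if (k == 0L) map[map >= 1L] <- map[map >= 1L] - 1L else map[map >= k] <- map[map >= k] - 1L
      resp[, j] <- map[resp[, j] + 1L]
      m[j] <- m[j] - 1L
      log <- c(log, list(list(op = "collapse", item = names(m)[j],
                              category = k, map = map)))
      changed <- TRUE
    }
    if (!changed) break
  }
  list(resp = resp, m = m, log = log)
}

#' Fit a polytomous Rasch model or graphical log-linear Rasch model
#'
#' Estimates item thresholds (and, under a non-empty [gllrm_spec], uniform
#' local-dependence and uniform DIF interaction parameters) by conditional
#' maximum likelihood: persons with extreme (minimum or maximum attainable)
#' scores carry no information and are excluded, the total score is
#' conditioned out via elementary symmetric functions computed over
#' generalized items, and with DIF terms the likelihood conditions on the
#' score within each covariate-level group, with all non-DIF parameters
#' shared across groups.
#'
#' Identification: the grand sum of thresholds is fixed to zero, each LD
#' block carries a corner constraint (interactions involving category 0
#' vanish), and DIF offsets are zero in the reference (first) level.  The
#' log-weights are linear in the parameters, so the conditional likelihood
#' is a concave canonical exponential family; a BFGS pass is followed by
#' Newton polishing of the gradient.  Zero-frequency categories are merged
#' with the adjacent lower category before estimation and logged.
#'
#' @param responses a [resp_matrix] (or integer matrix) of coded responses.
#' @param spec a [gllrm_spec]; the default empty spec fits the Rasch model.
#' @param covariates data frame of person covariates (required when `spec`
#'   has DIF terms; stored for diagnostics either way).
#' @param start optional start values for the free parameter vector.
#' @param control list: `maxit` (500), `gtol` (1e-8, per-person gradient
#'   tolerance), `cap` (4096, generalized-item combination cap), `se`
#'   (compute observed-information standard errors, default TRUE).
#' @return An object of class `gllrm` with components including
#'   `coefficients` (named: thresholds `tau`, LD blocks `lam`, DIF offsets
#'   `dif`), `se`, `vcov`, `logLik` (conditional), `df` (free parameters),
#'   `converged`, `iterations`, `gradient_norm`, `n_used`, `n_extreme`,
#'   and the post-collapse data used for fitting.
#' @seealso [rasch_cml()], [score_table()], [andersen_clr()],
#'   [item_restscore()], [kelderman_lr()]
#' @export
gllrm <- function(responses, spec = gllrm_spec(), covariates = NULL,
                  start = NULL, control = list()) {
  ctrl <- modifyList(list(maxit = 500L, gtol = 1e-8, cap = 4096L, se = TRUE,
                          newton = 25L), control)
  rm_ <- as_resp_matrix(responses)
  resp <- rm_$responses
  m <- rm_$max_cat
  if (nrow(resp) < 2L) stop("at least 2 persons are required")

  cz <- collapse_zero_categories(resp, m)
  resp <- cz$resp; m <- cz$m
  mx <- sum(m)
  score <- as.integer(rowSums(resp))
  include <- score > 0L & score < mx
  if (sum(include) < 2L) stop("fewer than 2 non-extreme persons")

  model <- build_model(m, spec, covariates, cap = ctrl$cap)
  group <- model$person_group %||% rep(1L, nrow(resp))
  if (length(model$dif_covs)) {
    for (v in model$dif_covs) {
      lev_n <- table(factor(covariates[[v]], levels = model$cov_levels[[v]])[include])
      if (any(lev_n == 0L))
        stop("DIF covariate ", v, " has level(s) with no non-extreme persons")
    }
  }

  lik <- build_cll(model, resp, group, score, include)

  ## start values: thresholds from adjacent-category counts, interactions 0;
  ## a *named* start vector is matched by parameter name (warm start from a
  ## related fit), absent parameters starting at 0
  if (!is.null(start) && !is.null(names(start))) {
    v <- numeric(model$npar)
    hit <- match(model$par_names, names(start))
    v[!is.na(hit)] <- start[hit[!is.na(hit)]]
    start <- v
  }
  if (is.null(start)) {
    start <- numeric(model$npar)
    tau0 <- numeric(model$K)
    pos <- 0L
    for (j in seq_along(m)) {
      cnt <- tabulate(resp[include, j] + 1L, m[j] + 1L) + 0.5
      tau0[pos + seq_len(m[j])] <- log(cnt[-length(cnt)] / cnt[-1L])
      pos <- pos + m[j]
    }
    tau0 <- tau0 - mean(tau0)
    start[seq_len(model$K - 1L)] <- tau0[seq_len(model$K - 1L)]
  }

  negf <- function(p) -lik$cll(p)
  negg <- function(p) -lik$grad(p)
  opt <- stats::optim(start, negf, negg, method = "BFGS",
                      control = list(maxit = ctrl$maxit, reltol = 1e-12))
  p <- opt$par
  iter <- opt$counts[["function"]]
  gtol_abs <- ctrl$gtol * max(1, sum(include))
  g <- lik$grad(p)
  H <- NULL
  for (it in seq_len(ctrl$newton)) {
    if (max(abs(g)) <= gtol_abs) break
    H <- num_hessian(lik$grad, p)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step))
      step <- tryCatch(solve(H - diag(1e-8, nrow(H)), g), error = function(e) NULL)
    if (is.null(step)) break
    ## trust-region style cap: flat plateau directions (boundary estimates
    ## of interaction parameters) must not send the polish off to infinity
    smax <- max(abs(step))
    if (smax > 2) step <- step * (2 / smax)
    f0 <- lik$cll(p)
    alpha <- 1
    repeat {
      pn <- p - alpha * step
      if (lik$cll(pn) >= f0 - 1e-10) break
      alpha <- alpha / 2
      if (alpha < 1e-6) { pn <- p; break }
    }
    p <- pn
    g <- lik$grad(p)
    iter <- iter + 1L
  }
  gnorm <- max(abs(g))
  converged <- gnorm <= max(gtol_abs, 1e-6)

  se <- rep(NA_real_, model$npar)
  V <- NULL
  if (ctrl$se) {
    if (is.null(H)) H <- num_hessian(lik$grad, p)
    V <- tryCatch(solve(-H), error = function(e) {
      ev <- eigen(-H, symmetric = TRUE)
      pos <- ev$values > max(ev$values) * 1e-10
      ev$vectors[, pos, drop = FALSE] %*%
        (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
    })
    dg <- diag(V)
    se <- ifelse(dg > 0, sqrt(pmax(dg, 0)), NA_real_)
  }

  names(p) <- model$par_names
  if (!is.null(V)) dimnames(V) <- list(model$par_names, model$par_names)
  names(se) <- model$par_names

  fit <- structure(list(
    coefficients = p, se = se, vcov = V,
    logLik = lik$cll(p), df = model$npar,
    converged = converged, iterations = iter, gradient_norm = gnorm,
    n = nrow(resp), n_used = sum(include), n_extreme = sum(!include),
    spec = spec, m = m, item_ids = model$item_ids,
    model = model, responses = resp, covariates = covariates,
    group = group, score = score, include = include,
    collapse_log = cz$log, call = match.call()),
    class = "gllrm")
  fit
}

#' Fit a polytomous Rasch model by conditional maximum likelihood
#'
#' Convenience wrapper for [gllrm()] with an empty interaction
#' specification (the partial-credit parameterisation
#' \eqn{P(X_i = x | \theta) \propto \exp(x\theta - \sum_{k \le x} \tau_{ik})}).
#'
#' @inheritParams gllrm
#' @return A fitted `gllrm` object.
#' @export
rasch_cml <- function(responses, covariates = NULL, start = NULL,
                      control = list()) {
  gllrm(responses, gllrm_spec(), covariates = covariates, start = start,
        control = control)
}

## full tau vector (including the constrained last entry) from a fit
tau_full <- function(fit) {
  K <- fit$model$K
  tf <- fit$coefficients[seq_len(K - 1L)]
  tau <- c(tf, -sum(tf))
  names(tau) <- paste0("tau(", fit$item_ids[fit$model$tau_idx[, 1L]], ":",
                       fit$model$tau_idx[, 2L], ")")
  tau
}

## tau as a list of per-item threshold vectors
tau_list <- function(fit) {
  tau <- tau_full(fit)
  split(unname(tau), rep(seq_along(fit$m), fit$m))
}
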