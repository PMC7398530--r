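## Fit and invariance tests: Andersen CLR, item-restscore fit, conditional
## partial-gamma screens for LD and DIF, Kelderman confirmatory LR tests and
## the Monte-Carlo unidimensionality test.

test_result <- function(name, statistic, df = NA_real_, p = NA_real_,
                        ...) {
  structure(c(list(name = name, statistic = statistic, df = df, p = p),
              list(...)), class = "gllrm_test")
}

#' @export
print.gllrm_test <- function(x, ...) {
  cat(x$name, "\n")
  cat("  statistic =", format(x$statistic, digits = 5))
  if (!is.na(x$df)) cat(", df =", x$df)
  if (!is.na(x$p)) cat(", p =", format.pval(x$p, digits = 3))
  cat("\n")
  if (!is.null(x$note) && nzchar(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Andersen conditional likelihood ratio test
#'
#' Compares conditional likelihoods fitted separately in person groups
#' against the pooled fit: grouping by score level tests item homogeneity
#' (equal parameters in low and high scorers), grouping by a covariate tests
#' absence of DIF.  The statistic is
#' \eqn{CLR = 2(\sum_g \ell_g - \ell_{pooled})} referred to a chi-square
#' with df equal to the number of extra free parameters of the group-wise
#' fits.  When grouping by a covariate that already carries DIF terms in
#' the working model, those terms are dropped from the group-wise fits
#' (each group is a single level) and the df bookkeeping accounts for it.
#'
#' @param fit a fitted [gllrm] object (the working model).
#' @param by `"score"` for the homogeneity test (median split of
#'   non-extreme scores, ties to the lower group) or the name of a
#'   covariate column for a test of no DIF.
#' @return A `gllrm_test` with the CLR, df, p, and per-group fits.  If a
#'   group fit does not converge the test is reported unavailable (`NA`
#'   statistic), never fabricated.
#' @export
andersen_clr <- function(fit, by = "score") {
  stopifnot(inherits(fit, "gllrm"))
  resp <- resp_matrix(fit$responses, base = 0L, max_cat = fit$m)
  if (identical(by, "score")) {
    s <- fit$score[fit$include]
    med <- stats::median(s)
    grp <- ifelse(fit$score <= med, 1L, 2L)
    grp[!fit$include] <- NA_integer_
    if (length(unique(stats::na.omit(grp))) < 2L)
      return(test_result(paste0("Andersen CLR (", by, ")"), NA_real_,
                         note = "degenerate score split"))
    labels <- c("low", "high")
    gspec <- fit$spec
  } else {
    v <- fit$covariates[[by]]
    if (is.null(v)) stop("unknown covariate: ", by)
    f <- droplevels(as.factor(v))
    grp <- as.integer(f)
    labels <- levels(f)
    gspec <- gllrm_spec(fit$spec$ld,
                        Filter(function(d) d[2L] != by, fit$spec$dif))
  }
  fits <- list()
  cll_g <- 0; df_g <- 0L
  for (g in sort(unique(stats::na.omit(grp)))) {
    sel <- which(!is.na(grp) & grp == g)
    sub <- resp_subset(resp, persons = sel)
    cv <- if (!is.null(fit$covariates)) fit$covariates[sel, , drop = FALSE] else NULL
    fg <- tryCatch(gllrm(sub, gspec, covariates = cv,
                         start = fit$coefficients,
                         control = list(se = FALSE)),
                   error = function(e) e)
    if (inherits(fg, "error") || !fg$converged)
      return(test_result(paste0("Andersen CLR (", by, ")"), NA_real_,
                         note = paste0("group fit unavailable (",
                                       if (inherits(fg, "error")) conditionMessage(fg)
                                       else "non-convergence", ")")))
    if (fg$n_used < fg$df)
      return(test_result(paste0("Andersen CLR (", by, ")"), NA_real_,
                         note = "group smaller than its free parameter count"))
    fits[[length(fits) + 1L]] <- fg
    cll_g <- cll_g + fg$logLik
    df_g <- df_g + fg$df
  }
  clr <- 2 * (cll_g - fit$logLik)
  ## df from the working model's free-parameter count, (G - 1) x p for the
  ## homogeneity split; group fits that hit category boundaries (collapsed
  ## cells) span fewer directions, making the reference conservative there
  G <- length(fits)
  p_group <- free_param_count(fit$m, gspec,
                              cov_levels = fit$model$cov_levels)$total
  df <- G * p_group - fit$df
  test_result(paste0("Andersen CLR (", by, ")"),
              statistic = max(0, clr), df = df,
              p = stats::pchisq(max(0, clr), df, lower.tail = FALSE),
              groups = labels, group_fits = fits)
}

#' Item-restscore fit statistics
#'
#' For each item, compares the observed Goodman-Kruskal gamma between the
#' item score and its restscore (total of all other items) with the value
#' expected under the fitted model, using the observed score margin; the
#' discrepancy is referred to a parametric-bootstrap reference distribution
#' (replicates drawn conditionally on the observed scores).  Per-item
#' p-values form one Benjamini-Hochberg family.
#'
#' @param fit a fitted [gllrm] object.
#' @param B bootstrap replicates (default 400).
#' @param seed RNG seed for the bootstrap.
#' @return A data frame with one row per item: `observed`, `expected`,
#'   `se`, `z`, `p`, `p_adj`.
#' @export
item_restscore <- function(fit, B = 400L, seed = NULL) {
  I <- length(fit$item_ids)
  R <- fit$model$max_score
  obs <- numeric(I); expd <- numeric(I)
  untestable <- logical(I)
  for (i in seq_len(I)) {
    rest <- fit$score - fit$responses[, i]
    if (length(unique(rest)) < 2L || length(unique(fit$responses[, i])) < 2L) {
      untestable[i] <- TRUE
      obs[i] <- NA_real_
      next
    }
    obs[i] <- gk_gamma(fit$responses[, i], rest)$gamma
  }
  ## model-implied joint of (item, restscore) at the observed score margin
  for (i in seq_len(I)) {
    if (untestable[i]) { expd[i] <- NA_real_; next }
    TT <- matrix(0, fit$m[i] + 1L, R + 1L) # x by restscore
    for (g in sort(unique(fit$group))) {
      sel <- fit$group == g
      if (!any(sel)) next
      ns <- tabulate(fit$score[sel] + 1L, R + 1L)
      pc <- comp_conditionals(fit, g)
      ci <- which(vapply(fit$model$components,
                         function(cmp) i %in% cmp$members, TRUE))
      comp <- fit$model$components[[ci]]
      pos <- match(i, comp$members)
      Pk <- pc[[ci]]
      for (s in which(ns > 0) - 1L) {
        px <- rowsum(Pk[, s + 1L], comp$combos[, pos])[, 1L]
        xs <- sort(unique(comp$combos[, pos]))
        for (xi in seq_along(xs)) {
          r <- s - xs[xi]
          if (r >= 0 && r <= R)
            TT[xs[xi] + 1L, r + 1L] <- TT[xs[xi] + 1L, r + 1L] + ns[s + 1L] * px[xi]
        }
      }
    }
    expd[i] <- gk_gamma(TT)$gamma
  }
  ## parametric bootstrap (conditional on scores), one replicate set for all
  ## items
  boots <- matrix(NA_real_, B, I)
  reps <- simulate(fit, nsim = B, seed = seed)
  for (b in seq_len(B)) {
    rb <- reps[[b]]
    sb <- rowSums(rb)
    for (i in seq_len(I)) {
      if (untestable[i]) next
      boots[b, i] <- gk_gamma(rb[, i], sb - rb[, i])$gamma
    }
  }
  se <- apply(boots, 2L, stats::sd, na.rm = TRUE)
  z <- (obs - expd) / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(item = fit$item_ids, observed = obs, expected = expd,
             se = se, z = z, p = p, p_adj = bh_adjust(p),
             row.names = NULL)
}

## --- model-based conditional association screens ---------------------------
## Observed stratified (partial) gamma compared with its expectation under
## the working model, so structure the model already carries (including
## mixture-induced association in DIF-adjusted models) is not re-flagged.

## per-group machinery reused across a scan
scan_context <- function(fit) {
  lapply(sort(unique(fit$group)), function(g) {
    comps <- fit$model$components
    ucs <- lapply(comps, comp_u, g = g, p = fit$coefficients)
    C <- length(comps)
    prefix <- vector("list", C + 1L); suffix <- vector("list", C + 1L)
    prefix[[1L]] <- 1; suffix[[C + 1L]] <- 1
    for (ci in seq_len(C)) prefix[[ci + 1L]] <- conv_score(prefix[[ci]], ucs[[ci]]$u)
    for (ci in rev(seq_len(C))) suffix[[ci]] <- conv_score(ucs[[ci]]$u, suffix[[ci + 1L]])
    list(g = g, ucs = ucs, prefix = prefix, suffix = suffix,
         gam = prefix[[C + 1L]], pc = comp_conditionals(fit, g),
         n_s = tabulate(fit$score[fit$group == g] + 1L,
                        fit$model$max_score + 1L))
  })
}

## P(X_i = a, X_j = b | S = s) for all s, one group: array (mi+1, mj+1, R+1)
pair_cond <- function(fit, ctx, i, j) {
  comps <- fit$model$components
  R <- fit$model$max_score
  mi <- fit$m[i]; mj <- fit$m[j]
  ci <- which(vapply(comps, function(cp) i %in% cp$members, TRUE))
  cj <- which(vapply(comps, function(cp) j %in% cp$members, TRUE))
  out <- array(0, c(mi + 1L, mj + 1L, R + 1L))
  if (ci == cj) {
    comp <- comps[[ci]]
    a <- comp$combos[, match(i, comp$members)]
    b <- comp$combos[, match(j, comp$members)]
    grp <- a + (mi + 1L) * b
    SM <- rowsum(ctx$pc[[ci]], grp) # cells x (R+1)
    ug <- sort(unique(grp))
    for (t in seq_along(ug)) {
      aa <- ug[t] %% (mi + 1L); bb <- ug[t] %/% (mi + 1L)
      out[aa + 1L, bb + 1L, ] <- SM[t, ]
    }
    return(out)
  }
  ## different components: item-by-score weight profiles and leave-two-out ESF
  comp_i <- comps[[ci]]; comp_j <- comps[[cj]]
  wi <- ctx$ucs[[ci]]$w; wj <- ctx$ucs[[cj]]$w
  ai <- comp_i$combos[, match(i, comp_i$members)]
  aj <- comp_j$combos[, match(j, comp_j$members)]
  Wi <- matrix(0, mi + 1L, comp_i$max_score + 1L)
  for (k in seq_along(wi)) Wi[ai[k] + 1L, comp_i$score[k] + 1L] <-
    Wi[ai[k] + 1L, comp_i$score[k] + 1L] + wi[k]
  Wj <- matrix(0, mj + 1L, comp_j$max_score + 1L)
  for (k in seq_along(wj)) Wj[aj[k] + 1L, comp_j$score[k] + 1L] <-
    Wj[aj[k] + 1L, comp_j$score[k] + 1L] + wj[k]
  rest <- setdiff(seq_along(comps), c(ci, cj))
  g2 <- 1
  for (cc in rest) g2 <- conv_score(g2, ctx$ucs[[cc]]$u)
  gam <- ctx$gam
  for (s in 0:R) {
    if (gam[s + 1L] <= 0) next
    M <- matrix(0, mi + 1L, mj + 1L)
    for (t in 0:(ncol(Wi) - 1L)) for (u in 0:(ncol(Wj) - 1L)) {
      d <- s - t - u
      if (d < 0L || d >= length(g2)) next
      if (g2[d + 1L] <= 0) next
      M <- M + outer(Wi[, t + 1L], Wj[, u + 1L]) * g2[d + 1L]
    }
    out[, , s + 1L] <- M / gam[s + 1L]
  }
  out
}

## P(X_i = a | S = s): matrix (mi+1) x (R+1), one group
item_cond <- function(fit, ctx, i) {
  comps <- fit$model$components
  ci <- which(vapply(comps, function(cp) i %in% cp$members, TRUE))
  comp <- comps[[ci]]
  a <- comp$combos[, match(i, comp$members)]
  rowsum(ctx$pc[[ci]], group = a)
}

## compare observed stratified association with its model expectation:
## obs_tabs/exp_tabs are lists of per-stratum two-way tables.  The statistic
## pools the per-stratum concordant-discordant pair-count differences
## (observed minus model-expected, rescaled to the stratum size) over their
## null variances, Mantel fashion, which stays calibrated with many small
## strata; the reported gammas pool the pair counts Davis fashion.
gamma_departure <- function(obs_tabs, exp_tabs) {
  num <- 0; den <- 0
  Pb <- 0; Qb <- 0; Pe <- 0; Qe <- 0
  used <- 0L
  for (h in seq_along(obs_tabs)) {
    No <- obs_tabs[[h]]
    nh <- sum(No)
    if (nh < 2) next
    go <- gk_gamma(No)
    if (is.na(go$gamma) || is.na(go$ase0) || go$ase0 <= 0) next
    ge <- gk_gamma(exp_tabs[[h]] * nh / max(sum(exp_tabs[[h]]), 1e-12))
    if (is.na(ge$gamma)) next
    ## null variance of (P - Q): ase0 = 2 sqrt(v0) / (P + Q)
    v0 <- (go$ase0 * (go$P + go$Q) / 2)^2
    num <- num + (go$P - go$Q) - (ge$P - ge$Q)
    den <- den + 4 * v0
    Pb <- Pb + go$P; Qb <- Qb + go$Q
    Pe <- Pe + ge$P; Qe <- Qe + ge$Q
    used <- used + 1L
  }
  if (!used || den <= 0)
    return(list(obs = NA_real_, exp = NA_real_, departure = NA_real_,
                z = NA_real_, p = NA_real_, n_strata = 0L))
  z <- num / sqrt(den)
  obs <- if (Pb + Qb > 0) (Pb - Qb) / (Pb + Qb) else NA_real_
  expg <- if (Pe + Qe > 0) (Pe - Qe) / (Pe + Qe) else NA_real_
  list(obs = obs, exp = expg,
       departure = if (!is.na(obs) && !is.na(expg)) obs - expg else NA_real_,
       z = z, p = 2 * stats::pnorm(-abs(z)), n_strata = used)
}

#' Conditional partial-gamma screens for local dependence and DIF
#'
#' `scan_ld()` screens every item pair for local dependence via stratified
#' Goodman-Kruskal gammas given the restscore of the response-side item
#' (the total minus that item), given which the item is exactly
#' independent of the remaining responses under a model without LD on the
#' pair.  `scan_dif()` screens every (item, covariate) pair for DIF given
#' the total score, given which an item is exactly independent of any
#' exogenous variable under a no-DIF model, whatever the latent
#' distributions of the covariate groups.  Each observed stratified gamma
#' is compared with
#' its expectation under the working model (computed analytically from the
#' conditional pattern distributions given the total score, at the observed
#' score margin), so association that the fitted model already accounts for
#' is not flagged again; under the plain Rasch model the expected
#' conditional association is zero and the screen reduces to the classical
#' partial-gamma test.  Stratum results are pooled by inverse-variance
#' weighting; each scan is one Benjamini-Hochberg family.
#'
#' @param fit a fitted [gllrm] object.
#' @param covariates character vector of covariate column names to screen
#'   for DIF.
#' @return A data frame with one row per pair/term: observed and expected
#'   pooled gamma, the weighted departure `gamma`, `z`, `p`, `p_adj`, and
#'   whether the term is already in the fitted specification.
#' @export
scan_ld <- function(fit) {
  I <- length(fit$item_ids)
  R <- fit$model$max_score
  in_spec <- vapply(fit$spec$ld, paste, "", collapse = "~")
  ctxs <- scan_context(fit)
  rows <- list()
  for (i in seq_len(I - 1L)) for (j in (i + 1L):I) {
    mi <- fit$m[i]; mj <- fit$m[j]
    ## strata: restscore excluding the response-side item j
    rest <- fit$score - fit$responses[, j]
    strata <- sort(unique(rest))
    obs_tabs <- lapply(strata, function(r) {
      sel <- rest == r
      tab <- matrix(0, mi + 1L, mj + 1L)
      tt <- table(factor(fit$responses[sel, i], levels = 0:mi),
                  factor(fit$responses[sel, j], levels = 0:mj))
      tab + unclass(tt)
    })
    exp_tabs <- lapply(strata, function(r) matrix(0, mi + 1L, mj + 1L))
    for (ctx in ctxs) {
      pcp <- pair_cond(fit, ctx, i, j)
      for (hi in seq_along(strata)) {
        r <- strata[hi]
        for (b in 0:mj) {
          s <- r + b
          if (s < 0L || s > R || ctx$n_s[s + 1L] == 0L) next
          exp_tabs[[hi]][, b + 1L] <- exp_tabs[[hi]][, b + 1L] +
            ctx$n_s[s + 1L] * pcp[, b + 1L, s + 1L]
        }
      }
    }
    gd <- gamma_departure(obs_tabs, exp_tabs)
    lab <- paste(sort(c(fit$item_ids[i], fit$item_ids[j])), collapse = "~")
    rows[[length(rows) + 1L]] <- data.frame(
      item1 = fit$item_ids[i], item2 = fit$item_ids[j],
      obs_gamma = gd$obs, exp_gamma = gd$exp, gamma = gd$departure,
      z = gd$z, p = gd$p, in_spec = lab %in% in_spec)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out
}

#' @rdname scan_ld
#' @export
scan_dif <- function(fit, covariates) {
  in_spec <- vapply(fit$spec$dif, paste, "", collapse = ":")
  R <- fit$model$max_score
  ctxs <- scan_context(fit)
  rows <- list()
  for (v in covariates) {
    y <- fit$covariates[[v]]
    if (is.null(y)) stop("unknown covariate: ", v)
    yf <- droplevels(as.factor(y))
    L <- nlevels(yf)
    for (i in seq_along(fit$item_ids)) {
      mi <- fit$m[i]
      ## strata: the total score itself — given it, an item is exactly
      ## independent of any exogenous variable under a no-DIF model,
      ## whatever the latent distributions of the covariate levels
      strata <- sort(unique(fit$score))
      obs_tabs <- lapply(strata, function(s) {
        sel <- fit$score == s
        unclass(table(factor(fit$responses[sel, i], levels = 0:mi), yf[sel]))
      })
      exp_tabs <- lapply(strata, function(s) matrix(0, mi + 1L, L))
      for (ctx in ctxs) {
        sel_g <- fit$group == ctx$g
        icp <- item_cond(fit, ctx, i) # (mi+1) x (R+1)
        ## level-specific score counts within this model group
        for (l in seq_len(L)) {
          sel <- sel_g & as.integer(yf) == l
          if (!any(sel)) next
          n_ls <- tabulate(fit$score[sel] + 1L, R + 1L)
          for (hi in seq_along(strata)) {
            s <- strata[hi]
            if (n_ls[s + 1L] == 0L) next
            exp_tabs[[hi]][, l] <- exp_tabs[[hi]][, l] +
              n_ls[s + 1L] * icp[, s + 1L]
          }
        }
      }
      gd <- gamma_departure(obs_tabs, exp_tabs)
      rows[[length(rows) + 1L]] <- data.frame(
        item = fit$item_ids[i], covariate = v,
        obs_gamma = gd$obs, exp_gamma = gd$exp, gamma = gd$departure,
        z = gd$z, p = gd$p,
        in_spec = paste(fit$item_ids[i], v, sep = ":") %in% in_spec)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Kelderman confirmatory likelihood ratio test
#'
#' Tests whether the interaction terms distinguishing a full from a nested
#' reduced model are needed: \eqn{2(\ell_{full} - \ell_{reduced})} on df
#' equal to the difference in free parameters.  The reduced model is
#' refitted on the full fit's (post-collapse) data so the likelihoods are
#' comparable.
#'
#' @param fit a fitted [gllrm] object (the full model).
#' @param reduced a [gllrm_spec] nested in `fit$spec`, or the label of a
#'   single term to drop (e.g. `"INQ1~INQ2"` or `"INQ2:age_group"`).
#' @return A `gllrm_test`.
#' @export
kelderman_lr <- function(fit, reduced) {
  if (is.character(reduced)) reduced <- spec_drop(fit$spec, reduced)
  full_lab <- spec_term_labels(fit$spec)
  red_lab <- spec_term_labels(reduced)
  if (!all(red_lab %in% full_lab))
    stop("reduced specification is not nested in the fitted one")
  dropped <- setdiff(full_lab, red_lab)
  if (!length(dropped))
    return(test_result("Kelderman LR", 0, df = 0, p = 1))
  rfit <- gllrm(resp_matrix(fit$responses, base = 0L, max_cat = fit$m),
                reduced, covariates = fit$covariates,
                start = fit$coefficients,
                control = list(se = FALSE))
  if (!rfit$converged)
    return(test_result("Kelderman LR", NA_real_,
                       note = "reduced fit did not converge"))
  stat <- max(0, 2 * (fit$logLik - rfit$logLik))
  df <- fit$df - rfit$df
  test_result(paste0("Kelderman LR (", paste(dropped, collapse = ", "), ")"),
              statistic = stat, df = df,
              p = stats::pchisq(stat, df, lower.tail = FALSE),
              dropped = dropped)
}

#' Monte-Carlo test of unidimensionality
#'
#' Splits the scale into two item subsets and compares the observed
#' Goodman-Kruskal gamma between the two subscores with its distribution
#' under the fitted unidimensional model, simulated at the estimated person
#' locations.  The one-sided exact p-value is the fraction of simulated
#' gammas at or below the observed one (a subscore correlation below the
#' unidimensional expectation indicates a second dimension).
#'
#' @param fit a fitted [gllrm] object on the full scale.
#' @param first,second item ids of the two subsets (must partition the
#'   scale).
#' @param M number of Monte-Carlo samples (default 1000; a warning is
#'   issued below 100).
#' @param seed RNG seed.
#' @return A `gllrm_test` with observed gamma as the statistic, plus
#'   `expected`, `sd`, `p` (exact, one-sided) and `p_asymp`.
#' @export
unidimensionality_test <- function(fit, first, second, M = 1000L, seed = NULL) {
  if (!setequal(c(first, second), fit$item_ids) || length(intersect(first, second)))
    stop("`first` and `second` must partition the scale items")
  if (M < 100L) warning("M < 100 Monte-Carlo samples gives a coarse p-value")
  i1 <- match(first, fit$item_ids); i2 <- match(second, fit$item_ids)
  a <- rowSums(fit$responses[, i1, drop = FALSE])
  b <- rowSums(fit$responses[, i2, drop = FALSE])
  if (length(unique(a)) < 2L || length(unique(b)) < 2L)
    stop("degenerate subscore: split cannot be tested")
  obs <- gk_gamma(a, b)$gamma
  ## estimated person locations (extremes via display extrapolation)
  theta <- numeric(fit$n)
  for (g in sort(unique(fit$group))) {
    st <- score_table(fit, g)
    sel <- fit$group == g
    theta[sel] <- st$theta[match(fit$score[sel], st$score)]
  }
  sims <- with_seed(seed, {
    vapply(seq_len(M), function(s) {
      out <- matrix(0L, fit$n, length(fit$item_ids))
      for (g in sort(unique(fit$group))) {
        sel <- fit$group == g
        out[sel, ] <- rpatterns_theta(fit_sampler(fit, g), theta[sel],
                                      length(fit$item_ids))
      }
      gk_gamma(rowSums(out[, i1, drop = FALSE]),
               rowSums(out[, i2, drop = FALSE]))$gamma
    }, 0)
  })
  mu <- mean(sims); sdev <- stats::sd(sims)
  test_result("Unidimensionality (subscore gamma)",
              statistic = obs, df = NA_real_,
              p = (1 + sum(sims <= obs)) / (M + 1),
              expected = mu, sd = sdev,
              p_asymp = stats::pnorm((obs - mu) / sdev),
              M = M, split = list(first = first, second = second))
}
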