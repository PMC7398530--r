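## Measurement outputs: Monte-Carlo reliability, targeting indices,
## person-item map data and DIF-equated scores.

## fit a latent normal per group by matching the first two moments of the
## observed score distribution (Gauss-Hermite quadrature); extreme scores
## are kept here — they carry no conditional information about item
## parameters but plenty about where the population sits
latent_normal <- function(fit, g, gh = gauss_hermite_norm(41L)) {
  logw <- group_logw(fit, g)
  sel <- fit$group == g
  s <- fit$score[sel]
  target <- c(mean(s), stats::var(s))
  if (!is.finite(target[2L]) || target[2L] <= 0) return(c(mean = 0, sd = 0))
  obj <- function(par) {
    mu <- par[1L]; sig <- exp(par[2L])
    mom <- escore_moments(logw, mu + sig * gh$x)
    m1 <- sum(gh$w * mom$mean)
    m2 <- sum(gh$w * (mom$var + mom$mean^2)) - m1^2
    (m1 - target[1L])^2 + (sqrt(max(m2, 0)) - sqrt(target[2L]))^2
  }
  o <- stats::optim(c(stats::median(score_table(fit, g)$theta), 0), obj,
                    method = "Nelder-Mead",
                    control = list(maxit = 400, reltol = 1e-10))
  c(mean = o$par[1L], sd = exp(o$par[2L]))
}

#' Monte-Carlo reliability of the sum score
#'
#' Estimates reliability as the ratio of true-score variance to total score
#' variance, \eqn{Var(E[S|\theta]) / Var(S)}, by simulating person
#' locations from a latent normal whose mean and standard deviation are
#' fitted to the first two moments of the observed score distribution
#' (extreme scores included: they are uninformative about item parameters
#' but informative about the population location).  At the simulated locations the total-score variance is
#' assembled from the analytic conditional moments,
#' \eqn{Var(S) = Var(E[S|\theta]) + E[Var(S|\theta)]}, which estimates the
#' same ratio as drawing responses but without the response-sampling
#' noise.
#'
#' @param fit a fitted [gllrm] object.
#' @param M number of simulated persons (default 1000).
#' @param seed RNG seed.
#' @param by_group also report per covariate group (default when the model
#'   has DIF terms).
#' @return A list with `reliability` (overall, weighted by group size),
#'   `by_group`, and the fitted latent moments.  Zero-information scales
#'   return reliability 0 with a warning.
#' @export
mc_reliability <- function(fit, M = 1000L, seed = NULL, by_group = NULL) {
  if (M < 100L) stop("M must be at least 100")
  groups <- sort(unique(fit$group))
  by_group <- by_group %||% (length(groups) > 1L)
  rel <- numeric(length(groups)); wt <- numeric(length(groups))
  lat <- matrix(0, length(groups), 2L,
                dimnames = list(NULL, c("mean", "sd")))
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    wt[gi] <- sum(fit$group == g)
    ln <- latent_normal(fit, g)
    lat[gi, ] <- ln
    if (ln[["sd"]] <= 1e-8) {
      warning("degenerate latent variance in group ", g, "; reliability 0")
      rel[gi] <- 0
      next
    }
    logw <- group_logw(fit, g)
    rel[gi] <- with_seed(if (is.null(seed)) NULL else seed + gi - 1L, {
      th <- stats::rnorm(M, ln[["mean"]], ln[["sd"]])
      mom <- escore_moments(logw, th)
      ## Var(S) = Var(E[S|theta]) + E[Var(S|theta)]: using the analytic
      ## conditional moments at the simulated locations removes the
      ## response-sampling noise from the ratio
      v <- stats::var(mom$mean) + mean(mom$var)
      if (v <= 0) 0 else min(1, stats::var(mom$mean) / v)
    })
  }
  list(reliability = sum(rel * wt) / sum(wt),
       by_group = if (by_group) stats::setNames(rel, rownames_groups(fit, groups)),
       latent = lat, M = M)
}

rownames_groups <- function(fit, groups) {
  if (!nrow(fit$model$groups) || !ncol(fit$model$groups))
    return(as.character(groups))
  apply(fit$model$groups[groups, , drop = FALSE], 1L, paste, collapse = "/")
}

#' Targeting of a scale to a person population
#'
#' Numerical targeting summary: the test information target index (mean
#' test information at the estimated person locations divided by the
#' maximum test information over the latent continuum) and the RMSE target
#' index (minimum standard error of measurement divided by the mean SEM at
#' the person locations), both close to 1 for a well-targeted scale;
#' the target of the observed score (the score whose location maximises
#' information) with its SEM; and floor/ceiling percentages.  Computed per
#' covariate group and overall, with item-map data (information curve,
#' threshold locations, person location distribution) attached for
#' plotting.
#'
#' @param fit a fitted [gllrm] object.
#' @return An object of class `gllrm_targeting`: a data frame `indices`
#'   (one row per group and overall) plus `map` data.
#' @export
targeting <- function(fit) {
  groups <- sort(unique(fit$group))
  rows <- list(); maps <- list()
  all_info <- c(); all_sem <- c()
  floor_n <- 0L; ceil_n <- 0L
  for (g in groups) {
    st <- score_table(fit, g)
    ## information maximum searched over the whole attainable score range
    ## (the score table's theta span), so boundary parameter estimates
    ## cannot hide the peak outside a fixed window
    lo <- min(st$theta) - 2; hi <- max(st$theta) + 2
    ic <- info_curve(fit, g, theta = seq(lo, hi, length.out = 321L))
    sel <- fit$group == g
    th <- st$theta[match(fit$score[sel], st$score)]
    info_p <- escore_moments(group_logw(fit, g), th)$var
    sem_p <- 1 / sqrt(info_p)
    imax <- max(ic$info, info_p)
    nonext <- !st$extreme
    target_row <- st[which.max(st$info * nonext), ]
    fl <- sum(fit$score[sel] == 0L); ce <- sum(fit$score[sel] == fit$model$max_score)
    floor_n <- floor_n + fl; ceil_n <- ceil_n + ce
    all_info <- c(all_info, info_p); all_sem <- c(all_sem, sem_p)
    rows[[length(rows) + 1L]] <- data.frame(
      group = rownames_groups(fit, g), n = sum(sel),
      info_target_index = mean(info_p) / imax,
      rmse_target_index = min(sem_p) / mean(sem_p),
      target_score = target_row$score, sem_at_target = target_row$sem,
      floor_pct = 100 * fl / sum(sel), ceiling_pct = 100 * ce / sum(sel))
    maps[[length(maps) + 1L]] <- list(group = g, info = ic,
                                      thresholds = tau_full(fit),
                                      person_theta = th, score_table = st)
  }
  imax_all <- max(vapply(maps, function(m) max(m$info$info), 0), all_info)
  overall <- data.frame(
    group = "overall", n = fit$n,
    info_target_index = mean(all_info) / imax_all,
    rmse_target_index = min(all_sem) / mean(all_sem),
    target_score = rows[[1L]]$target_score,
    sem_at_target = rows[[1L]]$sem_at_target,
    floor_pct = 100 * floor_n / fit$n, ceiling_pct = 100 * ceil_n / fit$n)
  structure(list(indices = rbind(do.call(rbind, rows), overall), map = maps),
            class = "gllrm_targeting")
}

#' @export
print.gllrm_targeting <- function(x, digits = 3, ...) {
  cat("Targeting summary\n")
  print(format(x$indices, digits = digits), row.names = FALSE)
  invisible(x)
}

#' DIF-equated scores
#'
#' Translates raw scores of each focal level of a DIF covariate onto the
#' reference level's scale: a focal raw score is mapped to its estimated
#' location under the focal parameters and then to the expected score under
#' the reference parameters.  Group score means are reported with and
#' without the DIF adjustment.  Without DIF terms on the covariate the
#' equating is the identity map.
#'
#' @param fit a fitted [gllrm] object.
#' @param covariate name of the DIF covariate to equate across.
#' @param reference reference level (default: the covariate's first level).
#' @return An object of class `gllrm_equating` with the score translation
#'   `table` (per focal level), `max_abs_diff`, and group `means`
#'   (unadjusted and adjusted).
#' @export
equate_scores <- function(fit, covariate, reference = NULL) {
  lv <- fit$model$cov_levels[[covariate]]
  has_dif <- any(vapply(fit$spec$dif, function(d) d[2L] == covariate, TRUE))
  R <- fit$model$max_score
  if (is.null(lv)) { # covariate carries no DIF terms: identity equating
    lv <- levels(droplevels(as.factor(fit$covariates[[covariate]])))
    has_dif <- FALSE
  }
  reference <- reference %||% lv[1L]
  grid <- fit$model$groups
  ## group index for a given level of `covariate`, other DIF covariates at
  ## their reference levels
  level_group <- function(l) {
    if (!nrow(grid) || !ncol(grid)) return(1L)
    sel <- rep(TRUE, nrow(grid))
    for (v in colnames(grid))
      sel <- sel & grid[[v]] == (if (v == covariate) l else fit$model$cov_levels[[v]][1L])
    w <- which(sel)
    if (!length(w)) stop("no fitted group for level ", l)
    w[1L]
  }
  tabs <- list()
  cov_f <- as.factor(fit$covariates[[covariate]])
  means <- data.frame(level = lv, mean_raw = NA_real_, mean_equated = NA_real_)
  ref_logw <- if (has_dif) group_logw(fit, level_group(reference))
  for (l in lv) {
    sel <- cov_f == l
    means$mean_raw[means$level == l] <- mean(fit$score[sel])
    if (!has_dif || l == reference) {
      tab <- data.frame(level = l, score = 0:R, theta = NA_real_,
                        equated = 0:R, diff = 0)
      means$mean_equated[means$level == l] <- means$mean_raw[means$level == l]
    } else {
      st <- score_table(fit, level_group(l))
      eq <- escore_moments(ref_logw, st$theta)$mean
      eq <- pmin(pmax(eq, 0), R)
      tab <- data.frame(level = l, score = 0:R, theta = st$theta,
                        equated = eq, diff = eq - (0:R))
      means$mean_equated[means$level == l] <- mean(eq[match(fit$score[sel], st$score)])
    }
    tabs[[l]] <- tab
  }
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL
  focal <- tab[tab$level != reference, ]
  structure(list(table = tab, covariate = covariate, reference = reference,
                 max_abs_diff = if (nrow(focal)) max(abs(focal$diff)) else 0,
                 diff_range = if (has_dif)
                   range(abs(focal$diff[!focal$score %in% c(0L, R)])) else c(0, 0),
                 means = means, has_dif = has_dif),
            class = "gllrm_equating")
}

#' @export
print.gllrm_equating <- function(x, digits = 3, ...) {
  cat("Score equating across", x$covariate, "(reference:", x$reference, ")\n")
  if (!x$has_dif) {
    cat("no DIF terms on this covariate: identity equating\n")
  } else {
    cat("largest |equated - raw| =", format(x$max_abs_diff, digits = digits), "\n")
    cat("group means (raw / DIF-adjusted):\n")
    print(format(x$means, digits = digits), row.names = FALSE)
  }
  invisible(x)
}
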