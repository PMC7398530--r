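## Synthetic questionnaire data: exact sampling from Rasch models and
## GLLRMs with configurable LD, DIF, floor effects and demographic
## structure, plus the standard two-sample fixture used for end-to-end
## testing.

## normalise a planted lambda specification to a full block matrix:
## a scalar c is the linear-by-linear block lambda[x, y] = c * x * y
lambda_block <- function(lambda, mi, mj) {
  if (is.matrix(lambda)) {
    stopifnot(nrow(lambda) == mi, ncol(lambda) == mj)
    return(lambda)
  }
  outer(seq_len(mi), seq_len(mj)) * lambda
}

## normalise a planted delta: scalar d applies to every threshold
delta_vec <- function(delta, m) {
  if (length(delta) == 1L) rep(delta, m) else {
    stopifnot(length(delta) == m); delta
  }
}

#' Simulate responses from a (graphical log-linear) Rasch model
#'
#' Draws ordinal responses exactly: person locations are drawn from a
#' normal (or supplied), and for each generalized item (LD-connected
#' component) a category combination is drawn from its full conditional
#' distribution given the location, by enumeration over the component's
#' category space.  Items listed in `theta_item` use person-specific
#' alternative locations (e.g. a second dimension or an item with a
#' discrimination mismatch); such items must not carry LD edges.
#'
#' @param n number of persons (ignored when `theta` is supplied).
#' @param tau list of per-item threshold vectors (names are item ids).
#' @param ld list of planted LD edges: each `list(items = c(i, j),
#'   lambda = ...)` with `lambda` a full matrix or a scalar
#'   linear-by-linear coefficient.
#' @param dif list of planted DIF terms: each `list(item =, covariate =,
#'   delta = ...)` where `delta` is a named list mapping non-reference
#'   covariate levels to a scalar (all thresholds) or per-threshold vector
#'   added to the item's thresholds for that level.
#' @param covariates data frame of person covariates (required with DIF).
#' @param theta optional person locations; otherwise `rnorm(n, theta_mean,
#'   theta_sd)`.
#' @param theta_mean,theta_sd latent normal parameters.
#' @param theta_item named list: item id -> person-location vector used for
#'   that item instead of `theta`.
#' @param seed RNG seed.
#' @return A list with `responses` (a 0-based [resp_matrix]), `theta`,
#'   `covariates`, and the planted `truth` record.
#' @export
simulate_responses <- function(n, tau, ld = list(), dif = list(),
                               covariates = NULL, theta = NULL,
                               theta_mean = 0, theta_sd = 1,
                               theta_item = list(), seed = NULL) {
  item_ids <- names(tau) %||% paste0("I", seq_along(tau))
  names(tau) <- item_ids
  m <- vapply(tau, length, 1L)
  with_seed(seed, {
    if (is.null(theta)) theta <- stats::rnorm(n, theta_mean, theta_sd)
    n <- length(theta)

    spec <- gllrm_spec(lapply(ld, `[[`, "items"),
                       lapply(dif, function(d) c(d$item, d$covariate)))
    gen <- build_generalized_items(spec, item_ids)
    for (id in names(theta_item)) {
      comp_of <- gen[[which(vapply(gen, function(g) id %in% g, TRUE))]]
      if (length(comp_of) > 1L)
        stop("theta_item override requires item ", id, " to have no LD edges")
    }

    ## person groups over DIF covariate levels
    dif_covs <- unique(vapply(dif, `[[`, "", "covariate"))
    if (length(dif_covs)) {
      stopifnot(!is.null(covariates))
      fs <- lapply(dif_covs, function(v) droplevels(as.factor(covariates[[v]])))
      names(fs) <- dif_covs
      gf <- if (length(fs) == 1L) fs[[1L]] else interaction(fs, drop = TRUE)
      glev <- levels(gf)
      pg <- as.integer(gf)
    } else {
      gf <- NULL; glev <- "all"; pg <- rep(1L, n)
    }

    out <- matrix(0L, n, length(item_ids), dimnames = list(NULL, item_ids))
    for (gidx in seq_along(glev)) {
      sel <- pg == gidx
      if (!any(sel)) next
      ## per-item thresholds for this group (base + DIF offsets)
      tau_g <- tau
      for (d in dif) {
        lv <- if (length(dif_covs) == 1L) glev[gidx] else
          strsplit(glev[gidx], ".", fixed = TRUE)[[1L]][match(d$covariate, dif_covs)]
        if (!is.null(d$delta[[lv]]))
          tau_g[[d$item]] <- tau_g[[d$item]] + delta_vec(d$delta[[lv]], m[[d$item]])
      }
      scomps <- lapply(gen, function(members) {
        midx <- match(members, item_ids)
        combos <- as.matrix(expand.grid(lapply(m[midx], function(mm) 0:mm)))
        dimnames(combos) <- NULL
        storage.mode(combos) <- "integer"
        lw <- numeric(nrow(combos))
        for (p in seq_along(midx)) {
          beta <- c(0, -cumsum(tau_g[[midx[p]]]))
          lw <- lw + beta[combos[, p] + 1L]
        }
        for (e in ld) {
          if (!all(e$items %in% members)) next
          i <- match(e$items[1L], members); j <- match(e$items[2L], members)
          blk <- lambda_block(e$lambda, m[[e$items[1L]]], m[[e$items[2L]]])
          xi <- combos[, i]; xj <- combos[, j]
          s2 <- xi >= 1L & xj >= 1L
          lw[s2] <- lw[s2] + blk[cbind(xi[s2], xj[s2])]
        }
        list(members = midx, combos = combos, score = as.integer(rowSums(combos)),
             lw = lw)
      })
      singles <- vapply(scomps, function(sc) length(sc$members) == 1L, TRUE)
      for (ci in seq_along(scomps)) {
        sc <- scomps[[ci]]
        id <- item_ids[sc$members[1L]]
        th <- if (singles[ci] && !is.null(theta_item[[id]]))
          theta_item[[id]][sel] else theta[sel]
        drawn <- rpatterns_theta(list(sc), th, length(item_ids))
        out[sel, sc$members] <- drawn[, sc$members, drop = FALSE]
      }
    }
    list(responses = resp_matrix(out, base = 0L, max_cat = m),
         theta = theta, covariates = covariates,
         truth = list(tau = tau, ld = ld, dif = dif,
                      theta_mean = theta_mean, theta_sd = theta_sd))
  })
}

#' Score structure recovery against a planted ground truth
#'
#' Compares a selected model specification with the generator's planted LD
#' and DIF structure.  Planted LD edges are credited when present.  DIF is
#' scored up to the anchoring equivalence of conditional estimation: only
#' DIF *contrasts* between items are identified (adding a constant shift to
#' every item of a covariate group is absorbed by the group's latent
#' location), so a planted pattern "offset \eqn{d} on items S" is the same
#' conditional model as "offset \eqn{-d} on the complementary items".  For
#' each covariate the recovered DIF item set is therefore matched against
#' every equivalent representation of the planted offsets, and the best
#' match is credited, scaled to the number of planted terms.
#'
#' @param truth a per-subscale ground-truth record as produced by
#'   [inq_fixture()] (elements `ld`, `dif`, `dif_delta`, `items`).
#' @param spec the selected [gllrm_spec].
#' @param items the item ids retained by the search.
#' @return A list with `recovered` (equivalent planted terms found),
#'   `planted` (total planted terms), `fraction`, and `extra` (selected
#'   terms not matching any planted structure).
#' @export
structure_recovery <- function(truth, spec, items = truth$items) {
  found_ld <- vapply(spec$ld, paste, "", collapse = "~")
  ld_hits <- sum(truth$ld %in% found_ld)
  rec <- ld_hits
  planted <- length(truth$ld)
  matched_dif <- character(0)
  for (v in names(truth$dif_delta)) {
    d_pl <- truth$dif_delta[[v]]
    d <- stats::setNames(rep(0, length(items)), items)
    keep <- names(d_pl)[names(d_pl) %in% items]
    d[keep] <- d_pl[keep]
    n_pl <- sum(vapply(strsplit(truth$dif, ":", fixed = TRUE),
                       function(x) x[2L] == v, TRUE))
    planted <- planted + n_pl
    R <- vapply(Filter(function(t) t[2L] == v, spec$dif), `[`, "", 1L)
    best <- 0
    for (cc in unique(c(d, 0))) {
      S <- names(d)[d != cc]
      if (!length(S)) next
      best <- max(best, length(intersect(S, R)) / length(S))
    }
    rec <- rec + best * n_pl
    if (best > 0) matched_dif <- c(matched_dif, paste(R, v, sep = ":"))
  }
  sel <- spec_term_labels(spec)
  extra <- setdiff(sel, c(truth$ld, truth$dif, matched_dif))
  list(recovered = rec, planted = planted,
       fraction = if (planted > 0) rec / planted else NA_real_,
       extra = extra)
}

## expand analysis-scale categories (0-based, m = 3) to raw 1..7
## questionnaire coding: the merged-category preimages of the 1223344 map
## are sampled uniformly, then reverse keys are applied inversely
expand_raw <- function(resp0, recode = c(1, 2, 2, 3, 3, 4, 4),
                       reverse = character()) {
  x <- resp0$responses
  raw <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  pre <- split(seq_along(recode), recode)
  for (v in sort(unique(as.vector(x)))) {
    idx <- which(x == v)
    opts <- pre[[as.character(v + 1L)]]
    raw[idx] <- if (length(opts) == 1L) opts else
      opts[sample.int(length(opts), length(idx), replace = TRUE)]
  }
  rev_idx <- match(reverse, colnames(raw))
  if (length(rev_idx)) raw[, rev_idx] <- 8L - raw[, rev_idx]
  resp_matrix(raw, base = 1L, max_cat = 6L)
}

## demographic generators for the two study-like samples
gp_covariates <- function(n) {
  bins <- list(14:34, 35:49, 50:63, 64:90)
  pr <- c(0.260, 0.244, 0.260, 0.236)
  b <- sample.int(4L, n, replace = TRUE, prob = pr)
  age <- vapply(b, function(k) sample(bins[[k]], 1L), 1L)
  data.frame(gender = factor(sample(c("female", "male"), n, replace = TRUE,
                                    prob = c(0.555, 0.445)),
                             levels = c("female", "male")),
             age = age)
}

clin_covariates <- function(n) {
  bins <- list(18:26, 27:36, 37:48, 49:75)
  pr <- c(47, 48, 43, 44) / 182
  b <- sample.int(4L, n, replace = TRUE, prob = pr)
  age <- vapply(b, function(k) sample(bins[[k]], 1L), 1L)
  data.frame(gender = factor(sample(c("female", "male"), n, replace = TRUE,
                                    prob = c(97, 88) / 185),
                             levels = c("female", "male")),
             age = age)
}

#' The standard synthetic two-sample questionnaire fixture
#'
#' Generates a general-population-like sample and a clinical-like sample of
#' a 15-item, two-subscale questionnaire in raw 1..7 coding, with the full
#' obstacle course the analysis pipeline must navigate: a severe floor on
#' the 6-item PB subscale in the general population (latent mean 3 logits
#' below the mean threshold), planted LD edges and sample-DIF on both
#' subscales, a second dimension behind three negatively worded TB items,
#' and one non-scalable (low-discrimination) TB item.  The planted
#' structure is returned as a ground-truth record for automated scoring of
#' structure recovery.
#'
#' @param seed RNG seed.
#' @param n_gp,n_clinical sample sizes (defaults 2508 and 185).
#' @return A list with `gp` and `clinical` (each `responses` in raw 1..7
#'   coding plus `covariates` with `gender`, `age`), the `scales`
#'   ([scale_spec]s for PB and TB), and the `truth` record.
#' @export
inq_fixture <- function(seed = 1L, n_gp = 2508L, n_clinical = 185L) {
  pb_ids <- paste0("INQ", 1:6)
  tb_ids <- paste0("INQ", 7:15)
  tb_reverse <- paste0("INQ", c(7, 8, 10, 13, 14, 15))
  recode <- c(1, 2, 2, 3, 3, 4, 4)
  off <- c(0.3, 0, -0.1) # mildly reversed thresholds, as raw INQ items show
  center <- function(tau) lapply(tau, function(t) t - mean(unlist(tau)))
  pb_tau <- center(lapply(seq(-0.7, 0.7, length.out = 6), function(l) l + off))
  names(pb_tau) <- pb_ids
  tb_tau <- center(lapply(seq(-0.8, 0.8, length.out = 9), function(l) l + off))
  names(tb_tau) <- tb_ids

  pb_ld <- list(list(items = c("INQ1", "INQ2"), lambda = 0.8),
                list(items = c("INQ4", "INQ5"), lambda = 0.8))
  pb_dif_items <- c("INQ1", "INQ2", "INQ4", "INQ5")
  tb_ld <- list(list(items = c("INQ7", "INQ8"), lambda = 0.8),
                list(items = c("INQ13", "INQ14"), lambda = 0.8))
  tb_dif <- c(INQ7 = -0.5, INQ8 = +0.5, INQ13 = -0.5, INQ15 = -0.5)

  with_seed(seed, {
    gp_cov <- gp_covariates(n_gp)
    cl_cov <- clin_covariates(n_clinical)

    gen_sample <- function(n, cov, pb_shift, tb_shift, th_pb, th_tb, sd_pb, sd_tb) {
      ptau <- pb_tau
      for (id in names(pb_shift)) ptau[[id]] <- ptau[[id]] + pb_shift[[id]]
      ttau <- tb_tau
      for (id in names(tb_shift)) ttau[[id]] <- ttau[[id]] + tb_shift[[id]]
      th <- stats::rnorm(n, th_pb, sd_pb)
      pb <- simulate_responses(n, ptau, ld = pb_ld, theta = th)
      th_t <- stats::rnorm(n, th_tb, sd_tb)
      rho <- 0.5
      th2 <- th_tb + rho * (th_t - th_tb) + sqrt(1 - rho^2) * stats::rnorm(n, 0, sd_tb)
      th10 <- th_tb + 0.3 * (th_t - th_tb)
      tb <- simulate_responses(n, ttau, ld = tb_ld, theta = th_t,
                               theta_item = list(INQ9 = th2, INQ11 = th2,
                                                 INQ12 = th2, INQ10 = th10))
      raw <- cbind(expand_raw(pb$responses)$responses + 1L,
                   expand_raw(tb$responses, reverse = tb_reverse)$responses + 1L)
      list(responses = resp_matrix(raw, base = 1L, max_cat = 6L),
           covariates = cov, theta_pb = th, theta_tb = th_t)
    }

    ## the general-population latent mean sits 3 logits below the mean PB
    ## threshold (0 after centring): the severe-floor regime
    gp <- gen_sample(n_gp, gp_cov, pb_shift = list(), tb_shift = list(),
                     th_pb = -3, th_tb = -1.6, sd_pb = 0.65, sd_tb = 1.2)
    ## clinical sample is the DIF focal group: shifted thresholds
    cl_pb_shift <- stats::setNames(as.list(rep(-0.5, 4)), pb_dif_items)
    cl <- gen_sample(n_clinical, cl_cov, pb_shift = cl_pb_shift,
                     tb_shift = as.list(tb_dif),
                     th_pb = -0.3, th_tb = 0, sd_pb = 1.0, sd_tb = 1.2)

    truth <- list(
      pb = list(ld = c("INQ1~INQ2", "INQ4~INQ5"),
                dif = paste0(pb_dif_items, ":sample"),
                dif_delta = list(sample = stats::setNames(rep(-0.5, 4), pb_dif_items)),
                items = pb_ids, lambda = 0.8),
      tb = list(ld = c("INQ7~INQ8", "INQ13~INQ14"),
                dif = paste0(names(tb_dif), ":sample"),
                dif_delta = list(sample = tb_dif),
                items = tb_ids, lambda = 0.8,
                second_dimension = c("INQ9", "INQ11", "INQ12"),
                nonscalable = "INQ10"))

    list(gp = gp[c("responses", "covariates")],
         clinical = cl[c("responses", "covariates")],
         scales = list(
           pb = scale_spec("PB", pb_ids, recode = recode),
           tb = scale_spec("TB", tb_ids, reverse = tb_reverse, recode = recode),
           tb_raw = scale_spec("TB", tb_ids, reverse = tb_reverse)),
         truth = truth)
  })
}
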