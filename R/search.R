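## The iterative model-search strategy: start from the Rasch model, add the
## single most significant LD or DIF term per cycle, confirm terms with
## Kelderman tests, eliminate persistently misfitting items, and either
## reach a final model or declare that none could be reached.

#' Iterative search for a fitting Rasch model or GLLRM
#'
#' Implements the stepwise analysis strategy: fit the current model; run the
#' homogeneity and no-DIF Andersen tests and the conditional partial-gamma
#' screens for LD and DIF; add the single most significant
#' (Benjamini-Hochberg adjusted) departure as an interaction term and
#' refit.  When no candidate remains, item fit is checked via the
#' item-restscore statistics: a model passing all tests has its terms
#' confirmed by Kelderman likelihood ratio tests (non-significant terms are
#' pruned) and is returned as final; otherwise the most problematic item
#' (largest absolute observed-expected restscore gamma among significantly
#' misfitting items) is eliminated and a new cycle starts.  On repeated
#' convergence failure, exhausted options or revisited specifications the
#' search stops with the best model so far, declared non-final.
#'
#' @param responses a [resp_matrix] of coded subscale responses.
#' @param covariates data frame of person covariates.
#' @param dif_covariates covariate names screened for DIF.
#' @param spec starting [gllrm_spec] (default: none, i.e. the Rasch model).
#' @param alpha significance level applied to adjusted p-values (default
#'   0.05).
#' @param max_iter maximum number of search cycles (default 12).
#' @param boot bootstrap replicates for item-restscore fit (default 200).
#' @param cap generalized-item combination cap; candidates whose addition
#'   would exceed it are skipped (mirroring the convergence pathologies
#'   large LD components produce).
#' @param min_items minimum number of items to retain (default 3).
#' @param seed RNG seed (bootstrap).
#' @param verbose print progress.
#' @return An object of class `gllrm_search`: `fit` (final or best), `spec`,
#'   `items`, `status` (`"final"` or `"non-final"`), `dropped_items`,
#'   `confirmatory` (Kelderman tests of the retained terms), `tests` (last
#'   round of global tests, screens and item fit) and the iteration `log`.
#' @export
model_search <- function(responses, covariates = NULL,
                         dif_covariates = character(),
                         spec = gllrm_spec(), alpha = 0.05, max_iter = 12L,
                         boot = 200L, cap = 4096L, min_items = 3L,
                         seed = NULL, verbose = FALSE) {
  responses <- as_resp_matrix(responses)
  items <- responses$item_ids
  dropped_items <- character()
  seen <- character()
  log <- list()
  best <- NULL
  nonconv <- 0L
  say <- function(...) if (verbose) cat(..., "\n")

  add_log <- function(action, detail) {
    log[[length(log) + 1L]] <<- list(iteration = length(log) + 1L,
                                     items = items,
                                     spec = spec_term_labels(spec),
                                     action = action, detail = detail)
  }

  for (it in seq_len(max_iter)) {
    seen <- c(seen, spec_signature(items, spec))
    fit <- tryCatch(gllrm(resp_subset(responses, items = items), spec,
                          covariates = covariates,
                          control = list(se = FALSE, cap = cap)),
                    error = function(e) e)
    failed <- inherits(fit, "error") || !fit$converged
    if (!failed) best <- fit
    if (failed) {
      nonconv <- nonconv + 1L
      msg <- if (inherits(fit, "error")) conditionMessage(fit) else "non-convergence"
      say("iteration", it, ": fit failed:", msg)
      add_log("fit-failed", msg)
      if (nonconv >= 2L || is.null(best)) {
        return(search_result(best, spec, items, "non-final", dropped_items,
                             NULL, NULL, log,
                             note = "repeated convergence failure"))
      }
      ## try eliminating the most problematic item of the last good fit
      irs <- item_restscore(best, B = boot, seed = seed)
      worst <- irs$item[which.max(abs(irs$observed - irs$expected))]
      items <- setdiff(items, worst)
      dropped_items <- c(dropped_items, worst)
      spec <- spec_restrict(spec, items)
      add_log("drop-item", worst)
      if (length(items) < min_items)
        return(search_result(best, spec, items, "non-final", dropped_items,
                             NULL, NULL, log, note = "too few items left"))
      next
    }

    ## confirmatory sweep: drop the least-supported term, one per cycle, so
    ## terms admitted under an earlier (worse) working model are re-examined
    labs <- spec_term_labels(spec)
    if (length(labs) >= 2L) {
      kl <- lapply(labs, function(lb) kelderman_lr(fit, lb))
      ps <- vapply(kl, function(t) if (is.na(t$p)) -Inf else t$p, 0)
      worst <- which.max(ps)
      if (length(worst) && ps[worst] >= alpha) {
        say("iteration", it, ": prune", labs[worst],
            "(confirmatory p =", format(ps[worst], digits = 3), ")")
        add_log("prune-term", labs[worst])
        spec <- spec_drop(spec, labs[worst])
        fit <- gllrm(resp_subset(responses, items = items), spec,
                     covariates = covariates, start = fit$coefficients,
                     control = list(se = FALSE, cap = cap))
        best <- fit
      }
    }

    hom <- andersen_clr(fit, "score")
    difclr <- lapply(dif_covariates, function(v) andersen_clr(fit, v))
    names(difclr) <- dif_covariates
    ld <- scan_ld(fit)
    dsc <- if (length(dif_covariates)) scan_dif(fit, dif_covariates) else NULL

    ## candidate departures, most significant first
    cand <- list()
    lds <- ld[!ld$in_spec & !is.na(ld$p_adj) & ld$p_adj < alpha, , drop = FALSE]
    for (k in seq_len(nrow(lds)))
      cand[[length(cand) + 1L]] <- list(
        type = "ld", items = c(lds$item1[k], lds$item2[k]),
        p = lds$p_adj[k], g = abs(lds$gamma[k]),
        label = paste(sort(c(lds$item1[k], lds$item2[k])), collapse = "~"))
    if (!is.null(dsc)) {
      dss <- dsc[!dsc$in_spec & !is.na(dsc$p_adj) & dsc$p_adj < alpha, , drop = FALSE]
      for (k in seq_len(nrow(dss)))
        cand[[length(cand) + 1L]] <- list(
          type = "dif", item = dss$item[k], covariate = dss$covariate[k],
          p = dss$p_adj[k], g = abs(dss$gamma[k]),
          label = paste(dss$item[k], dss$covariate[k], sep = ":"))
    }
    if (length(cand)) {
      ord <- order(vapply(cand, `[[`, 0, "p"), -vapply(cand, `[[`, 0, "g"),
                   vapply(cand, `[[`, "", "label"))
      cand <- cand[ord]
    }
    accepted <- FALSE
    dropped_nonscalable <- FALSE
    for (cn in cand) {
      new_spec <- spec_add(spec, cn)
      if (spec_signature(items, new_spec) %in% seen) next
      ## an item demanding LD with more than `max_item_edges` partners is
      ## not locally dependent but non-scalable: eliminate it instead
      if (cn$type == "ld") {
        deg <- table(unlist(new_spec$ld))
        if (any(deg > 3L)) {
          worst <- names(deg)[which.max(deg)]
          items <- setdiff(items, worst)
          dropped_items <- c(dropped_items, worst)
          spec <- spec_restrict(spec, items)
          say("iteration", it, ": item", worst,
              "accumulates LD with most of the scale; eliminated as non-scalable")
          add_log("drop-item", worst)
          dropped_nonscalable <- TRUE
          break
        }
      }
      ## component-size cap
      gen <- build_generalized_items(new_spec, items)
      sizes <- vapply(gen, function(g) prod(responses$max_cat[g] + 1), 0)
      if (any(sizes > cap)) next
      ## never let every item carry DIF on the same covariate (the group
      ## location would become unidentified)
      if (cn$type == "dif") {
        nd <- sum(vapply(new_spec$dif, function(d) d[2L] == cn$covariate, TRUE))
        if (nd >= length(items)) next
      }
      spec <- new_spec
      accepted <- TRUE
      say("iteration", it, ": add", cn$label, "(p_adj =", format(cn$p, digits = 3), ")")
      add_log("add-term", cn$label)
      break
    }
    if (dropped_nonscalable) {
      if (length(items) < min_items)
        return(search_result(fit, spec, items, "non-final", dropped_items,
                             NULL, NULL, log, note = "too few items left"))
      next
    }
    if (accepted) next

    ## LR-guided forward sweep: when the gamma screens propose nothing
    ## (their strata can be nearly uninformative in strongly separated
    ## mixed samples), every absent LD edge and DIF term is evaluated
    ## directly by conditional likelihood ratio under the working model,
    ## one Benjamini-Hochberg family per sweep
    sweep <- lr_forward_sweep(responses, covariates, items, spec,
                              dif_covariates, fit, seen, cap)
    if (length(sweep$p)) {
      ## one FDR family per test type, as in the reported tables
      is_ld_cand <- grepl("~", sweep$labels, fixed = TRUE)
      padj <- sweep$p
      if (any(is_ld_cand)) padj[is_ld_cand] <- bh_adjust(sweep$p[is_ld_cand])
      if (any(!is_ld_cand)) padj[!is_ld_cand] <- bh_adjust(sweep$p[!is_ld_cand])
      bi <- order(padj, sweep$p)[1L]
      if (padj[bi] < alpha) {
        spec <- sweep$specs[[bi]]
        accepted <- TRUE
        say("iteration", it, ": add", sweep$labels[bi],
            "(LR p_adj =", format(padj[bi], digits = 3), ")")
        add_log("add-term", sweep$labels[bi])
      }
    }
    if (accepted) next

    ## no admissible candidate: check item fit and global tests
    irs <- item_restscore(fit, B = boot, seed = seed)
    misfit <- irs[!is.na(irs$p_adj) & irs$p_adj < alpha, , drop = FALSE]
    global_ok <- (is.na(hom$p) || hom$p >= alpha) &&
      all(vapply(difclr, function(t) is.na(t$p) || t$p >= alpha, TRUE))
    if (!nrow(misfit) && global_ok) {
      pruned <- prune_terms(fit, alpha)
      add_log("final", paste(spec_term_labels(pruned$fit$spec), collapse = ", "))
      tests <- list(homogeneity = andersen_clr(pruned$fit, "score"),
                    dif_clr = lapply(stats::setNames(dif_covariates, dif_covariates),
                                     function(v) andersen_clr(pruned$fit, v)),
                    ld_scan = scan_ld(pruned$fit),
                    dif_scan = if (length(dif_covariates))
                      scan_dif(pruned$fit, dif_covariates),
                    item_fit = irs)
      return(search_result(pruned$fit, pruned$fit$spec, items, "final",
                           dropped_items, pruned$confirmatory, tests, log))
    }
    if (nrow(misfit)) {
      worst <- misfit$item[which.max(abs(misfit$observed - misfit$expected))]
      items <- setdiff(items, worst)
      dropped_items <- c(dropped_items, worst)
      spec <- spec_restrict(spec, items)
      say("iteration", it, ": eliminate misfitting item", worst)
      add_log("drop-item", worst)
      if (length(items) < min_items)
        return(search_result(fit, spec, items, "non-final", dropped_items,
                             NULL, NULL, log, note = "too few items left"))
      next
    }
    ## global misfit with no remaining candidate
    add_log("stop", "global misfit without admissible candidate terms")
    return(search_result(fit, spec, items, "non-final", dropped_items, NULL,
                         list(homogeneity = hom, dif_clr = difclr,
                              ld_scan = ld, dif_scan = dsc, item_fit = irs),
                         log, note = "no final model could be reached"))
  }
  add_log("stop", "iteration limit reached")
  search_result(best, spec, items, "non-final", dropped_items, NULL, NULL,
                log, note = "no final model could be reached (iteration limit)")
}

## one LR evaluation per absent candidate term under the working model
lr_forward_sweep <- function(responses, covariates, items, spec,
                             dif_covariates, fit, seen, cap) {
  labels <- character(0); ps <- numeric(0); specs <- list()
  consider <- function(term, lab) {
    new_spec <- spec_add(spec, term)
    if (spec_signature(items, new_spec) %in% seen) return()
    gen <- build_generalized_items(new_spec, items)
    sizes <- vapply(gen, function(g) prod(responses$max_cat[g] + 1), 0)
    if (any(sizes > cap)) return()
    if (term$type == "dif") {
      nd <- sum(vapply(new_spec$dif, function(d) d[2L] == term$covariate, TRUE))
      if (nd >= length(items)) return()
    }
    cf <- tryCatch(gllrm(resp_subset(responses, items = items), new_spec,
                         covariates = covariates, start = fit$coefficients,
                         control = list(se = FALSE, cap = cap)),
                   error = function(e) e)
    if (inherits(cf, "error") || !cf$converged) return()
    stat <- max(0, 2 * (cf$logLik - fit$logLik))
    pv <- stats::pchisq(stat, cf$df - fit$df, lower.tail = FALSE)
    labels <<- c(labels, lab); ps <<- c(ps, pv)
    specs[[length(specs) + 1L]] <<- new_spec
  }
  in_ld <- vapply(spec$ld, paste, "", collapse = "~")
  for (a in seq_along(items)) for (b in seq_len(length(items))) {
    if (b <= a) next
    lab <- paste(sort(c(items[a], items[b])), collapse = "~")
    if (lab %in% in_ld) next
    consider(list(type = "ld", items = c(items[a], items[b])), lab)
  }
  in_dif <- spec_term_labels(spec)
  for (v in dif_covariates) for (i in items) {
    lab <- paste(i, v, sep = ":")
    if (lab %in% in_dif) next
    consider(list(type = "dif", item = i, covariate = v), lab)
  }
  list(labels = labels, p = ps, specs = specs)
}

## confirmatory pruning: refit without each term; drop the least needed
## until all retained terms are significant
prune_terms <- function(fit, alpha) {
  confirm <- NULL
  repeat {
    labs <- spec_term_labels(fit$spec)
    if (!length(labs)) break
    tests <- lapply(labs, function(lb) kelderman_lr(fit, lb))
    confirm <- data.frame(
      term = labs,
      statistic = vapply(tests, function(t) t$statistic, 0),
      df = vapply(tests, function(t) t$df, 0),
      p = vapply(tests, function(t) t$p, 0))
    worst <- which.max(confirm$p)
    if (!length(worst) || is.na(confirm$p[worst]) || confirm$p[worst] < alpha) break
    fit <- gllrm(resp_matrix(fit$responses, base = 0L, max_cat = fit$m),
                 spec_drop(fit$spec, confirm$term[worst]),
                 covariates = fit$covariates, control = list(se = FALSE))
  }
  list(fit = fit, confirmatory = confirm)
}

search_result <- function(fit, spec, items, status, dropped_items,
                          confirmatory, tests, log, note = NULL) {
  structure(list(fit = fit, spec = spec, items = items, status = status,
                 dropped_items = dropped_items, confirmatory = confirmatory,
                 tests = tests, log = log, note = note),
            class = "gllrm_search")
}

#' @export
print.gllrm_search <- function(x, ...) {
  cat("Model search:", x$status, "\n")
  if (!is.null(x$note)) cat("  ", x$note, "\n")
  cat("items:", paste(x$items, collapse = ", "), "\n")
  if (length(x$dropped_items))
    cat("eliminated items:", paste(x$dropped_items, collapse = ", "), "\n")
  if (!is.null(x$fit)) print(x$fit$spec)
  invisible(x)
}
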