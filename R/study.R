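## Orchestration of the full multi-sample item analysis: subscale coding,
## the unidimensionality preliminary, clinical-first item exclusions, the
## matched mixed samples, one model search per analysis line, and the
## measurement outputs, collected into a reportable bundle.

study_defaults <- function() {
  list(alpha = 0.05, seed = 1L, M_unidim = 1000L, M_rel = 1000L,
       boot = 200L, max_iter = 12L, cap = 4096L,
       pb_lines = c("clinical", "gp", "mixed1"),
       tb_lines = c("clinical", "gp", "mixed1", "mixed2"))
}

#' Run the full item-analysis study
#'
#' Executes the complete analysis strategy on a two-sample dataset: codes
#' both subscales (reverse keys and category merging), tests TB
#' unidimensionality in the clinical sample (excluding the negatively
#' worded subset if rejected), lets the clinical TB search eliminate
#' non-scalable items for all samples, builds the age- and gender-matched
#' mixed samples (excluding general-population extremes on the respective
#' subscale), runs one model search per analysis line (PB: clinical,
#' general population, mixed1; TB: those plus mixed2), and computes
#' reliability, targeting and DIF-equated scores where the fitted models
#' admit them.
#'
#' @param data list with `gp` and `clinical`, each holding `responses`
#'   (raw 1..7 [resp_matrix]) and `covariates` (data frame with `gender`
#'   and integer `age`).
#' @param scales list with [scale_spec]s `pb` and `tb` (the TB spec carries
#'   the reverse keys and the category recoding).
#' @param config list overriding [study_defaults()]: `alpha`, `seed`,
#'   Monte-Carlo sizes `M_unidim` and `M_rel`, bootstrap size `boot`,
#'   search settings, and which lines to run.
#' @return An object of class `gllrm_study`: per-line results (`lines`),
#'   tidy `tables`, the unidimensionality test, item exclusions and the
#'   effective config.
#' @export
run_study <- function(data, scales, config = list()) {
  cfg <- utils::modifyList(study_defaults(), config)
  for (s in c("gp", "clinical")) {
    cv <- data[[s]]$covariates
    cv$gender <- factor(cv$gender)
    cv$age_group <- age_groups(cv$age)
    data[[s]]$covariates <- cv
  }
  tb_raw_spec <- scale_spec(scales$tb$name, scales$tb$items,
                            reverse = scales$tb$reverse, recode = NULL,
                            max_cat = scales$tb$max_cat)
  coded <- list(
    pb = lapply(data, function(d) apply_coding(d$responses, scales$pb)),
    tb = lapply(data, function(d) apply_coding(d$responses, scales$tb)),
    tb7 = lapply(data, function(d) apply_coding(d$responses, tb_raw_spec)))

  ## --- TB preliminaries: unidimensionality in the clinical (target) sample
  tb7_fit <- gllrm(coded$tb7$clinical, control = list(se = FALSE))
  pos <- scales$tb$reverse
  neg <- setdiff(scales$tb$items, pos)
  uni <- unidimensionality_test(tb7_fit, first = pos, second = neg,
                                M = cfg$M_unidim, seed = cfg$seed)
  tb_items <- scales$tb$items
  excluded_neg <- character()
  if (!is.na(uni$p) && uni$p < cfg$alpha) {
    excluded_neg <- neg
    tb_items <- setdiff(tb_items, neg)
  }

  ## --- clinical TB search fixes the item set for all TB lines
  cl_tb <- model_search(resp_subset(coded$tb$clinical, items = tb_items),
                        covariates = data$clinical$covariates,
                        dif_covariates = c("gender", "age_group"),
                        alpha = cfg$alpha, max_iter = cfg$max_iter,
                        boot = cfg$boot, cap = cfg$cap, seed = cfg$seed)
  tb_items <- cl_tb$items

  ## --- matched mixed samples (PB extremes for mixed1, TB for mixed2)
  mk_mixed <- function(scale_coded, items, seed) {
    build_mixed_sample(list(responses = scale_coded$gp,
                            covariates = data$gp$covariates),
                       list(responses = scale_coded$clinical,
                            covariates = data$clinical$covariates),
                       items = items, seed = seed)
  }
  mixed1 <- mk_mixed(coded$pb, scales$pb$items, cfg$seed)
  mixed2 <- mk_mixed(coded$tb, tb_items, cfg$seed + 1L)

  line_data <- function(scale, sample) {
    if (sample %in% c("gp", "clinical")) {
      list(responses = coded[[scale]][[sample]],
           covariates = data[[sample]]$covariates,
           dif_covariates = c("gender", "age_group"))
    } else {
      mx <- if (sample == "mixed1") mixed1 else mixed2
      sc <- coded[[scale]]
      resp <- sc$gp
      resp$responses <- rbind(sc$gp$responses[mx$gp_rows, , drop = FALSE],
                              sc$clinical$responses)
      list(responses = resp, covariates = mx$covariates,
           dif_covariates = c("gender", "age_group", "sample"))
    }
  }

  lines <- list()
  run_line <- function(scale, sample, items, reuse = NULL) {
    ld <- line_data(scale, sample)
    resp <- resp_subset(ld$responses, items = items)
    rm_fit <- gllrm(resp, covariates = ld$covariates,
                    control = list(se = FALSE, cap = cfg$cap))
    rm_tests <- global_tests(rm_fit, ld$dif_covariates)
    sr <- reuse %||% model_search(resp, covariates = ld$covariates,
                                  dif_covariates = ld$dif_covariates,
                                  alpha = cfg$alpha, max_iter = cfg$max_iter,
                                  boot = cfg$boot, cap = cfg$cap,
                                  seed = cfg$seed)
    final_tests <- if (!is.null(sr$tests)) {
      c(list(homogeneity = sr$tests$homogeneity), sr$tests$dif_clr)
    } else if (!is.null(sr$fit)) {
      global_tests(sr$fit, ld$dif_covariates)
    }
    item_fit <- if (!is.null(sr$tests$item_fit)) sr$tests$item_fit
                else if (!is.null(sr$fit))
                  item_restscore(sr$fit, B = cfg$boot, seed = cfg$seed)
    meas <- line_measurement(sr, cfg)
    list(scale = toupper(scale), sample = sample, n = nrow(resp$responses),
         items = if (!is.null(sr$items)) sr$items else items,
         rm = list(fit = rm_fit, tests = rm_tests),
         search = sr, final_tests = final_tests, item_fit = item_fit,
         reliability = meas$reliability, targeting = meas$targeting,
         equating = meas$equating)
  }

  for (sm in cfg$pb_lines)
    lines[[paste0("PB-", sm)]] <- run_line("pb", sm, scales$pb$items)
  for (sm in cfg$tb_lines)
    lines[[paste0("TB-", sm)]] <- run_line("tb", sm, tb_items,
                                           reuse = if (sm == "clinical") cl_tb)

  bundle <- list(config = cfg,
                 unidimensionality = uni,
                 excluded_items = list(
                   negatively_worded = excluded_neg,
                   search_eliminated = cl_tb$dropped_items),
                 mixed = list(mixed1 = mixed1[c("gp_rows", "match_log")],
                              mixed2 = mixed2[c("gp_rows", "match_log")]),
                 lines = lines)
  bundle$tables <- study_tables(bundle)
  class(bundle) <- "gllrm_study"
  bundle
}

## homogeneity + no-DIF CLRs for one fitted model
global_tests <- function(fit, dif_covariates) {
  out <- list(homogeneity = andersen_clr(fit, "score"))
  for (v in dif_covariates) out[[v]] <- andersen_clr(fit, v)
  out
}

line_measurement <- function(sr, cfg) {
  out <- list(reliability = NULL, targeting = NULL, equating = NULL)
  if (is.null(sr$fit)) return(out)
  has_sample_dif <- any(vapply(sr$fit$spec$dif, function(d) d[2L] == "sample", TRUE))
  if (sr$status == "final") {
    out$reliability <- mc_reliability(sr$fit, M = cfg$M_rel, seed = cfg$seed)
    out$targeting <- targeting(sr$fit)
  }
  if (has_sample_dif) {
    eq <- tryCatch(equate_scores(sr$fit, "sample"), error = function(e) NULL)
    if (!is.null(eq)) {
      eq$non_final <- sr$status != "final"
      out$equating <- eq
    }
  }
  out
}

## tidy tables in the shape of the study's report
study_tables <- function(bundle) {
  g <- list(); dterm <- list(); lterm <- list(); ifit <- list(); meas <- list()
  eq <- list(); eqm <- list()
  for (nm in names(bundle$lines)) {
    ln <- bundle$lines[[nm]]
    row_of <- function(model, label, t) {
      data.frame(line = nm, model = model, test = label,
                 statistic = if (is.null(t$statistic)) NA_real_ else t$statistic,
                 df = if (is.null(t$df)) NA_real_ else t$df,
                 p = if (is.null(t$p)) NA_real_ else t$p,
                 note = t$note %||% "")
    }
    for (lab in names(ln$rm$tests))
      g[[length(g) + 1L]] <- row_of("RM", lab, ln$rm$tests[[lab]])
    model_lab <- if (spec_is_empty(ln$search$spec)) "RM" else "GLLRM"
    if (!is.null(ln$final_tests) && !spec_is_empty(ln$search$spec))
      for (lab in names(ln$final_tests))
        g[[length(g) + 1L]] <- row_of(
          if (ln$search$status == "final") model_lab else paste0(model_lab, "*"),
          lab, ln$final_tests[[lab]])
    cf <- ln$search$confirmatory
    if (!is.null(cf) && nrow(cf)) {
      is_ld <- grepl("~", cf$term, fixed = TRUE)
      if (any(is_ld))
        lterm[[length(lterm) + 1L]] <- cbind(line = nm, cf[is_ld, , drop = FALSE])
      if (any(!is_ld))
        dterm[[length(dterm) + 1L]] <- cbind(line = nm, cf[!is_ld, , drop = FALSE])
    }
    if (!is.null(ln$item_fit))
      ifit[[length(ifit) + 1L]] <- cbind(line = nm, ln$item_fit)
    meas[[length(meas) + 1L]] <- data.frame(
      line = nm, status = ln$search$status, n = ln$n,
      items = paste(ln$items, collapse = ","),
      reliability = if (!is.null(ln$reliability)) ln$reliability$reliability else NA_real_,
      info_target_index = if (!is.null(ln$targeting))
        ln$targeting$indices$info_target_index[nrow(ln$targeting$indices)] else NA_real_,
      rmse_target_index = if (!is.null(ln$targeting))
        ln$targeting$indices$rmse_target_index[nrow(ln$targeting$indices)] else NA_real_,
      floor_pct = if (!is.null(ln$targeting))
        ln$targeting$indices$floor_pct[nrow(ln$targeting$indices)] else NA_real_,
      ceiling_pct = if (!is.null(ln$targeting))
        ln$targeting$indices$ceiling_pct[nrow(ln$targeting$indices)] else NA_real_)
    if (!is.null(ln$equating)) {
      eq[[length(eq) + 1L]] <- cbind(line = nm,
                                     non_final = ln$equating$non_final,
                                     ln$equating$table)
      eqm[[length(eqm) + 1L]] <- cbind(line = nm, ln$equating$means)
    }
  }
  u <- bundle$unidimensionality
  list(global = do.call(rbind, g),
       dif_terms = if (length(dterm)) do.call(rbind, dterm),
       ld_terms = if (length(lterm)) do.call(rbind, lterm),
       item_fit = if (length(ifit)) do.call(rbind, ifit),
       measurement = do.call(rbind, meas),
       equating = if (length(eq)) do.call(rbind, eq),
       equating_means = if (length(eqm)) do.call(rbind, eqm),
       unidimensionality = data.frame(
         observed_gamma = u$statistic, expected_gamma = u$expected,
         sd = u$sd, p_exact = u$p, p_asymp = u$p_asymp))
}

#' @export
print.gllrm_study <- function(x, ...) {
  cat("Item-analysis study:", length(x$lines), "analysis lines\n\n")
  u <- x$tables$unidimensionality
  cat("TB unidimensionality: observed gamma =", format(u$observed_gamma, digits = 3),
      "expected =", format(u$expected_gamma, digits = 3),
      "exact p =", format.pval(u$p_exact, digits = 3), "\n")
  if (length(x$excluded_items$negatively_worded))
    cat("excluded (second dimension):",
        paste(x$excluded_items$negatively_worded, collapse = ", "), "\n")
  if (length(x$excluded_items$search_eliminated))
    cat("excluded (clinical misfit):",
        paste(x$excluded_items$search_eliminated, collapse = ", "), "\n")
  cat("\nPer-line outcomes:\n")
  print(x$tables$measurement[, c("line", "status", "n", "reliability",
                                 "info_target_index", "floor_pct")],
        row.names = FALSE, digits = 3)
  invisible(x)
}
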