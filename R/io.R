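## Readers, writers and run configuration.  Data files carry 1-based
## questionnaire category codes; the 0-based internal coding never leaves
## the data model.

#' Read a person-by-item response table
#'
#' Reads a delimited text file whose header names the item and covariate
#' columns, validates that every response cell is an integer within the
#' declared category range, and returns the typed pair of response matrix
#' and covariate frame.
#'
#' @param path file path (CSV; `sep` may override the delimiter).
#' @param items item column names, in scale order.
#' @param covariates covariate column names to retain (default: every
#'   non-item column; unknown requested columns give a warning).
#' @param max_cat number of response categories (default 7; cells outside
#'   `1..max_cat` are rejected with their location).
#' @param sep field separator.
#' @return A list with `responses` (a [resp_matrix]) and `covariates`
#'   (data frame).
#' @export
read_responses <- function(path, items, covariates = NULL, max_cat = 7L,
                           sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(items, names(df))
  if (length(miss)) stop("missing item column(s): ", paste(miss, collapse = ", "))
  if (is.null(covariates)) {
    covariates <- setdiff(names(df), items)
  } else {
    unk <- setdiff(covariates, names(df))
    if (length(unk)) {
      warning("ignoring unknown covariate column(s): ",
              paste(unk, collapse = ", "))
      covariates <- setdiff(covariates, unk)
    }
  }
  X <- as.matrix(df[, items, drop = FALSE])
  if (!is.numeric(X)) {
    bad <- which(is.na(suppressWarnings(apply(X, 2L, as.numeric))), arr.ind = TRUE)[1L, ]
    stop("non-numeric response at row ", bad[1L], ", column ", items[bad[2L]])
  }
  for (j in seq_along(items)) {
    bad <- which(X[, j] != round(X[, j]) | X[, j] < 1 | X[, j] > max_cat)
    if (length(bad))
      stop("invalid response ", X[bad[1L], j], " at row ", bad[1L],
           ", column ", items[j], " (allowed: integers 1..", max_cat, ")")
  }
  list(responses = resp_matrix(X, item_ids = items, base = 1L,
                               max_cat = max_cat - 1L),
       covariates = df[, covariates, drop = FALSE])
}

#' Write a response table
#'
#' Writes responses (converted back to 1-based questionnaire codes) and
#' covariates as one delimited text file, the inverse of
#' [read_responses()].
#'
#' @param responses a [resp_matrix].
#' @param path output file path.
#' @param covariates optional covariate data frame (same person order).
#' @param sep field separator.
#' @export
write_responses <- function(responses, path, covariates = NULL, sep = ",") {
  stopifnot(inherits(responses, "resp_matrix"))
  df <- as.data.frame(responses$responses + 1L)
  names(df) <- responses$item_ids
  if (!is.null(covariates)) df <- cbind(df, covariates)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' Loads a structured plain-text (YAML) configuration driving a study run:
#' data paths, scale specifications, analysis lines, covariates, seeds,
#' Monte-Carlo sizes and significance level.  Scale entries (`items`,
#' `reverse`, `recode`, `max_cat`) are converted to [scale_spec] objects.
#'
#' @param path YAML file path.
#' @return A list; element `scales` holds [scale_spec]s.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$scales)) {
    cfg$scales <- lapply(stats::setNames(names(cfg$scales), names(cfg$scales)),
                         function(nm) {
      sc <- cfg$scales[[nm]]
      scale_spec(sc$name %||% toupper(nm), unlist(sc$items),
                 reverse = as.character(unlist(sc$reverse %||% character())),
                 recode = if (!is.null(sc$recode)) unlist(sc$recode),
                 max_cat = sc$max_cat %||% 7L)
    })
  }
  cfg
}

#' Write the study report
#'
#' Emits the tidy machine-readable tables of a study bundle (global tests,
#' confirmatory DIF/LD terms, item fit, measurement summary, equated
#' scores, unidimensionality) as tab-separated files with a stable column
#' order, plus a JSON run stamp with the effective configuration.
#' Re-writing the same bundle produces byte-identical files.
#'
#' @param bundle a `gllrm_study` object from [run_study()].
#' @param outdir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "gllrm_study"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  }
  paths <- character()
  emit <- function(tab, name) {
    p <- file.path(outdir, paste0(name, ".tsv"))
    if (is.null(tab)) tab <- data.frame()
    num <- vapply(tab, is.numeric, TRUE)
    tab[num] <- lapply(tab[num], function(x) formatC(x, digits = 6, format = "g"))
    utils::write.table(tab, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  tb <- bundle$tables
  emit(tb$global, "global_tests")
  emit(tb$dif_terms, "dif_terms")
  emit(tb$ld_terms, "ld_terms")
  emit(tb$item_fit, "item_fit")
  emit(tb$measurement, "measurement")
  emit(tb$equating, "equated_scores")
  emit(tb$equating_means, "equated_score_means")
  emit(tb$unidimensionality, "unidimensionality")
  stamp <- list(package = "gllrm",
                version = as.character(utils::packageVersion("gllrm")),
                seed = bundle$config$seed,
                alpha = bundle$config$alpha,
                excluded_items = bundle$excluded_items)
  pj <- file.path(outdir, "run_info.json")
  jsonlite::write_json(stamp, pj, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, pj)
  invisible(paths)
}
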