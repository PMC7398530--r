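## Response matrices, coding utilities, extreme scores, age grouping and
## matched mixed-sample construction.

#' Construct a response matrix
#'
#' Wraps an integer person-by-item matrix of ordinal responses.  Categories
#' are stored 0-based internally (0..m_i per item); questionnaire data coded
#' 1..k is rebased by setting `base = 1`.  Every applied transform (reverse
#' keying, category recoding, item drops) is appended to a coding log so the
#' preprocessing chain can be replayed.
#'
#' @param x integer matrix, persons in rows, items in columns.
#' @param item_ids item labels; defaults to column names or `I1..`.
#' @param base the code of the lowest category in `x` (1 for questionnaire
#'   coding, 0 for already rebased data).
#' @param max_cat per-item maximum category m_i on the 0-based scale;
#'   defaults to the observed column maxima.
#' @return An object of class `resp_matrix` with elements `responses`
#'   (0-based integer matrix), `item_ids`, `max_cat` and `coding_log`.
#' @export
resp_matrix <- function(x, item_ids = NULL, base = 1L, max_cat = NULL) {
  x <- as.matrix(x)
  if (is.null(item_ids)) item_ids <- colnames(x) %||% paste0("I", seq_len(ncol(x)))
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop("missing response at person ", bad[1L], ", item ", item_ids[bad[2L]],
         "; complete cases are required")
  }
  if (any(x != round(x))) {
    bad <- which(x != round(x), arr.ind = TRUE)[1L, ]
    stop("non-integer response at person ", bad[1L], ", item ", item_ids[bad[2L]])
  }
  storage.mode(x) <- "integer"
  x <- x - as.integer(base)
  if (is.null(max_cat)) max_cat <- apply(x, 2L, max)
  max_cat <- as.integer(rep_len(max_cat, ncol(x)))
  for (j in seq_len(ncol(x))) {
    if (any(x[, j] < 0L | x[, j] > max_cat[j])) {
      bad <- which(x[, j] < 0L | x[, j] > max_cat[j])[1L]
      stop("response out of range [", base, ", ", max_cat[j] + base,
           "] at person ", bad, ", item ", item_ids[j])
    }
  }
  colnames(x) <- item_ids
  names(max_cat) <- item_ids
  structure(list(responses = x, item_ids = item_ids, max_cat = max_cat,
                 coding_log = list()),
            class = "resp_matrix")
}

#' @export
print.resp_matrix <- function(x, ...) {
  cat("Response matrix:", nrow(x$responses), "persons x",
      length(x$item_ids), "items\n")
  cat("categories (0-based max):",
      paste0(x$item_ids, "=", x$max_cat, collapse = ", "), "\n")
  if (length(x$coding_log))
    cat("coding log:", length(x$coding_log), "transform(s)\n")
  invisible(x)
}

#' @export
dim.resp_matrix <- function(x) dim(x$responses)

## coerce a plain matrix: minimum observed value >= 1 is taken as 1-based
as_resp_matrix <- function(x, ...) {
  if (inherits(x, "resp_matrix")) return(x)
  base <- if (min(x) >= 1L) 1L else 0L
  resp_matrix(x, base = base, ...)
}

## subset persons and/or items, keeping metadata and log
resp_subset <- function(x, persons = NULL, items = NULL) {
  stopifnot(inherits(x, "resp_matrix"))
  r <- x$responses
  if (!is.null(persons)) r <- r[persons, , drop = FALSE]
  if (!is.null(items)) {
    idx <- match(items, x$item_ids)
    if (anyNA(idx)) stop("unknown item(s): ", paste(items[is.na(idx)], collapse = ", "))
    r <- r[, idx, drop = FALSE]
    out <- structure(list(responses = r, item_ids = x$item_ids[idx],
                          max_cat = x$max_cat[idx], coding_log = x$coding_log),
                     class = "resp_matrix")
    out$coding_log <- c(out$coding_log, list(list(op = "subset_items", items = items)))
    return(out)
  }
  x$responses <- r
  x
}

#' Define a subscale coding specification
#'
#' A scale specification names the member items of a subscale, which of them
#' are reverse keyed, and an optional category recoding (merging) map.
#'
#' @param name subscale name, e.g. `"PB"` or `"TB"`.
#' @param items member item ids in scale order.
#' @param reverse item ids that are reverse keyed (`x -> max + min - x`).
#' @param recode integer vector mapping original 1-based categories to merged
#'   1-based categories, e.g. `c(1, 2, 2, 3, 3, 4, 4)` merges seven response
#'   options into four.  Must be weakly monotone and surjective onto
#'   `1..max(recode)`.  `NULL` leaves categories unchanged.
#' @param max_cat number of original response categories (default 7).
#' @return An object of class `scale_spec`.
#' @export
scale_spec <- function(name, items, reverse = character(), recode = NULL,
                       max_cat = 7L) {
  if (!all(reverse %in% items)) stop("reverse-keyed items must be scale members")
  if (!is.null(recode)) {
    recode <- as.integer(recode)
    if (length(recode) != max_cat)
      stop("recode map must have one entry per original category")
    if (any(diff(recode) < 0L)) stop("recode map must be weakly monotone")
    if (!setequal(unique(recode), seq_len(max(recode))))
      stop("recode map must be surjective onto 1..max")
  }
  structure(list(name = name, items = items, reverse = reverse,
                 recode = recode, max_cat = as.integer(max_cat)),
            class = "scale_spec")
}

#' Apply a scale's coding to raw responses
#'
#' Selects the scale's member items, applies reverse keys
#' (`x -> max + min - x`, an involution), then applies the category recoding
#' map.  Reverse keys are always applied before recoding.  All transforms are
#' appended to the coding log.
#'
#' @param raw a [resp_matrix] holding raw questionnaire responses.
#' @param spec a [scale_spec].
#' @return A [resp_matrix] restricted to the scale items, coded 0..m'-1
#'   internally.
#' @export
apply_coding <- function(raw, spec) {
  stopifnot(inherits(raw, "resp_matrix"), inherits(spec, "scale_spec"))
  out <- resp_subset(raw, items = spec$items)
  m <- spec$max_cat - 1L # 0-based max of the raw scale
  if (any(out$max_cat != m)) {
    ## raw input must be on the declared category range
    for (j in seq_along(out$item_ids)) {
      bad <- which(out$responses[, j] > m)
      if (length(bad))
        stop("category outside declared range at person ", bad[1L],
             ", item ", out$item_ids[j])
    }
    out$max_cat[] <- m
  }
  if (length(spec$reverse)) {
    idx <- match(spec$reverse, out$item_ids)
    out$responses[, idx] <- m - out$responses[, idx]
    out$coding_log <- c(out$coding_log,
                        list(list(op = "reverse", items = spec$reverse, max = m)))
  }
  if (!is.null(spec$recode)) {
    map0 <- spec$recode - 1L # 0-based target categories
    out$responses[] <- map0[out$responses + 1L]
    out$max_cat[] <- max(map0)
    out$coding_log <- c(out$coding_log,
                        list(list(op = "recode", map = spec$recode)))
  }
  out
}

#' Replay a coding log
#'
#' Re-applies the ordered transforms recorded in a coding log to a raw
#' response matrix, reproducing the preprocessed matrix bit-exactly.
#'
#' @param raw the raw [resp_matrix].
#' @param log a coding log as stored in `resp_matrix$coding_log`.
#' @return The re-derived [resp_matrix].
#' @export
replay_coding <- function(raw, log) {
  out <- raw
  for (step in log) {
    out <- switch(step$op,
      subset_items = resp_subset(out, items = step$items),
      reverse = {
        idx <- match(step$items, out$item_ids)
        out$responses[, idx] <- step$max - out$responses[, idx]
        out$coding_log <- c(out$coding_log, list(step))
        out
      },
      recode = {
        map0 <- step$map - 1L
        out$responses[] <- map0[out$responses + 1L]
        out$max_cat[] <- max(map0)
        out$coding_log <- c(out$coding_log, list(step))
        out
      },
      collapse = {
        j <- match(step$item, out$item_ids)
        out$responses[, j] <- step$map[out$responses[, j] + 1L]
        out$max_cat[j] <- max(step$map)
        out$coding_log <- c(out$coding_log, list(step))
        out
      },
      stop("unknown coding op: ", step$op))
  }
  out
}

#' Total scores and extreme-score flags
#'
#' Computes per-person total scores over a set of items and flags persons at
#' the minimum or maximum attainable total.  Extreme scores carry no
#' information for conditional estimation and are excluded from fitting.
#'
#' @param data a [resp_matrix].
#' @param items item ids to sum over (default: all items).
#' @return A list with `score`, logical `extreme`, `min_score`, `max_score`.
#' @export
score_extremes <- function(data, items = data$item_ids) {
  stopifnot(inherits(data, "resp_matrix"))
  if (!length(items)) stop("empty item set")
  idx <- match(items, data$item_ids)
  if (anyNA(idx)) stop("unknown item(s): ", paste(items[is.na(idx)], collapse = ", "))
  s <- rowSums(data$responses[, idx, drop = FALSE])
  mx <- sum(data$max_cat[idx])
  list(score = as.integer(s), extreme = s == 0L | s == mx,
       min_score = 0L, max_score = as.integer(mx))
}

#' Quartile-based age grouping
#'
#' Categorises integer ages into `k` groups at the sample's empirical
#' quantile boundaries, with ties assigned to the lower group.  When two
#' samples have different age structures the grouping is computed separately
#' per sample.
#'
#' @param age integer ages.
#' @param k number of groups (default 4).
#' @param breaks optional externally supplied boundaries (length `k - 1`),
#'   e.g. to classify one sample at another sample's quartiles.
#' @return A factor with `k` ordered levels; the boundaries are attached as
#'   attribute `"breaks"`.
#' @export
age_groups <- function(age, k = 4L, breaks = NULL) {
  if (is.null(breaks))
    breaks <- unname(stats::quantile(age, probs = seq_len(k - 1L) / k, type = 2))
  g <- 1L + rowSums(outer(age, breaks, ">"))
  labs <- character(k)
  lo <- c(-Inf, floor(breaks) + 1L)
  hi <- c(floor(breaks), Inf)
  for (i in seq_len(k)) {
    labs[i] <- if (i == 1L) paste0("<=", hi[1L])
               else if (i == k) paste0(">=", lo[k]) else paste0(lo[i], "-", hi[i])
  }
  structure(factor(g, levels = seq_len(k), labels = labs), breaks = breaks)
}

#' Build an age- and gender-matched mixed sample
#'
#' Draws, for each clinical person, one general-population match on gender
#' and age group (at the clinical sample's age quartiles), excluding
#' general-population persons with extreme scores on the named subscale from
#' the sampling pool.  Sampling is without replacement, cell by cell, and
#' deterministic under a fixed seed.  Empty or insufficient matching cells
#' fall back to the nearest age group of the same gender; every fallback is
#' logged.
#'
#' @param gp,clinical lists with elements `responses` (a [resp_matrix] coded
#'   for the subscale) and `covariates` (data frame with `gender` and integer
#'   `age`).
#' @param items subscale item ids used to determine extreme scores.
#' @param seed RNG seed for the matched draw.
#' @return A list with combined `responses`, `covariates` (including a
#'   `sample` factor with levels `gp`, `clinical` and a clinical-quartile
#'   `age_group`), the drawn `gp_rows`, and a `match_log` of fallbacks.
#' @export
build_mixed_sample <- function(gp, clinical, items = NULL, seed = 1L) {
  rgp <- gp$responses; rcl <- clinical$responses
  items <- items %||% rgp$item_ids
  stopifnot(identical(rgp$item_ids, rcl$item_ids))
  breaks <- attr(age_groups(clinical$covariates$age), "breaks")
  ag_cl <- age_groups(clinical$covariates$age, breaks = breaks)
  ag_gp <- age_groups(gp$covariates$age, breaks = breaks)
  ext_gp <- score_extremes(rgp, items)$extreme
  gen_cl <- as.character(clinical$covariates$gender)
  gen_gp <- as.character(gp$covariates$gender)
  k <- nlevels(ag_cl)
  match_log <- list()
  chosen <- integer(0)
  with_seed(seed, {
    for (g in sort(unique(gen_cl))) {
      for (a in seq_len(k)) {
        need <- sum(gen_cl == g & as.integer(ag_cl) == a)
        if (!need) next
        pool <- which(!ext_gp & gen_gp == g & as.integer(ag_gp) == a)
        pool <- setdiff(pool, chosen)
        if (length(pool) >= need) {
          take <- if (length(pool) == 1L) pool else sample(pool, need)
        } else {
          take <- pool
          short <- need - length(pool)
          ## nearest-age-group fallback, same gender
          for (dist in seq_len(k - 1L)) {
            for (a2 in unique(c(a - dist, a + dist))) {
              if (short == 0L || a2 < 1L || a2 > k) next
              p2 <- setdiff(which(!ext_gp & gen_gp == g & as.integer(ag_gp) == a2),
                            c(chosen, take))
              if (length(p2)) {
                extra <- if (length(p2) == 1L) p2 else sample(p2, min(short, length(p2)))
                take <- c(take, extra)
                short <- short - length(extra)
                match_log <- c(match_log, list(list(
                  gender = g, age_group = a, fallback_group = a2, n = length(extra))))
              }
            }
            if (short == 0L) break
          }
          if (short > 0L)
            stop("cannot match ", short, " clinical person(s) in cell gender=", g,
                 ", age group ", a)
        }
        chosen <- c(chosen, take)
      }
    }
  })
  chosen <- sort(chosen)
  resp <- rgp
  resp$responses <- rbind(rgp$responses[chosen, , drop = FALSE], rcl$responses)
  covs <- rbind(
    data.frame(gender = gen_gp[chosen], age = gp$covariates$age[chosen],
               stringsAsFactors = FALSE),
    data.frame(gender = gen_cl, age = clinical$covariates$age,
               stringsAsFactors = FALSE))
  covs$sample <- factor(rep(c("gp", "clinical"), c(length(chosen), nrow(rcl$responses))),
                        levels = c("gp", "clinical"))
  covs$gender <- factor(covs$gender)
  covs$age_group <- age_groups(covs$age, breaks = breaks)
  list(responses = resp, covariates = covs, gp_rows = chosen, match_log = match_log)
}
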