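## Model specification and internal model structure for graphical log-linear
## Rasch models: LD edges, DIF terms, generalized items (LD-connected
## components), parameter layout and loading matrices.

#' Specify the interaction structure of a graphical log-linear Rasch model
#'
#' A GLLRM specification is the set of uniform local-dependence (LD) edges
#' between item pairs and the set of uniform DIF terms (item, covariate).
#' An empty specification is the plain Rasch model.
#'
#' @param ld list of length-2 vectors of item ids (unordered pairs).
#' @param dif list of length-2 vectors `c(item_id, covariate_name)`.
#' @return An object of class `gllrm_spec`.
#' @export
gllrm_spec <- function(ld = list(), dif = list()) {
  if (is.character(ld) && length(ld) == 2L) ld <- list(ld)
  if (is.character(dif) && length(dif) == 2L) dif <- list(dif)
  ld <- lapply(ld, function(e) {
    if (length(e) != 2L || e[1L] == e[2L]) stop("an LD edge is an unordered pair of two distinct items")
    sort(as.character(e))
  })
  if (anyDuplicated(vapply(ld, paste, "", collapse = "~")))
    stop("duplicated LD edge")
  dif <- lapply(dif, function(d) {
    if (length(d) != 2L) stop("a DIF term is a pair (item, covariate)")
    as.character(d)
  })
  if (anyDuplicated(vapply(dif, paste, "", collapse = ":")))
    stop("duplicated DIF term")
  structure(list(ld = ld, dif = dif), class = "gllrm_spec")
}

#' @export
print.gllrm_spec <- function(x, ...) {
  if (!length(x$ld) && !length(x$dif)) {
    cat("Rasch model (no LD or DIF terms)\n")
  } else {
    cat("GLLRM specification\n")
    if (length(x$ld))
      cat("  LD edges:", paste(vapply(x$ld, paste, "", collapse = " ~ "),
                               collapse = ", "), "\n")
    if (length(x$dif))
      cat("  DIF terms:", paste(vapply(x$dif, paste, "", collapse = " : "),
                                collapse = ", "), "\n")
  }
  invisible(x)
}

spec_is_empty <- function(spec) !length(spec$ld) && !length(spec$dif)

spec_covariates <- function(spec) unique(vapply(spec$dif, `[`, "", 2L))

## add/remove single terms (used by the model search)
spec_add <- function(spec, term) {
  if (term$type == "ld") gllrm_spec(c(spec$ld, list(term$items)), spec$dif)
  else gllrm_spec(spec$ld, c(spec$dif, list(c(term$item, term$covariate))))
}

spec_drop <- function(spec, label) {
  labs <- spec_term_labels(spec)
  keep <- labs != label
  if (all(keep)) stop("term not in spec: ", label)
  nld <- length(spec$ld)
  gllrm_spec(spec$ld[keep[seq_len(nld)]],
             spec$dif[keep[nld + seq_along(spec$dif)]])
}

spec_term_labels <- function(spec) {
  c(vapply(spec$ld, paste, "", collapse = "~"),
    vapply(spec$dif, paste, "", collapse = ":"))
}

## restrict a spec to a subset of items (terms on dropped items disappear)
spec_restrict <- function(spec, items) {
  gllrm_spec(Filter(function(e) all(e %in% items), spec$ld),
             Filter(function(d) d[1L] %in% items, spec$dif))
}

#' Partition items into generalized items
#'
#' The connected components of the LD graph form generalized items whose
#' category space is the cross-product of the member categories, scored by
#' the member sum.
#'
#' @param spec a [gllrm_spec].
#' @param item_ids item ids of the scale.
#' @return A list of character vectors, one per generalized item, in scale
#'   order of the first member.
#' @export
build_generalized_items <- function(spec, item_ids) {
  comp <- seq_along(item_ids)
  names(comp) <- item_ids
  for (e in spec$ld) {
    if (!all(e %in% item_ids)) stop("LD edge references unknown item: ",
                                    paste(e, collapse = "~"))
    a <- comp[[e[1L]]]; b <- comp[[e[2L]]]
    comp[comp == b] <- a
  }
  ids <- unique(comp)
  lapply(ids, function(i) item_ids[comp == i])
}

#' Free-parameter bookkeeping
#'
#' Counts the free parameters of a (G)LLRM under the package's
#' identification constraints: the base Rasch model has
#' \eqn{\sum_i m_i - 1} free thresholds (grand sum fixed to zero), each LD
#' edge adds \eqn{m_i \times m_j} interaction parameters (corner
#' constraint), and each DIF term adds \eqn{(G - 1) \times m_i} offsets
#' (reference level fixed).
#'
#' @param m named integer vector of per-item maximum categories.
#' @param spec a [gllrm_spec].
#' @param cov_levels named list (or vector) of covariate level counts.
#' @return A list with `total`, `tau`, and per-term counts `ld` and `dif`.
#' @export
free_param_count <- function(m, spec = gllrm_spec(), cov_levels = list()) {
  tau <- sum(m) - 1L
  ld <- vapply(spec$ld, function(e) as.integer(m[[e[1L]]] * m[[e[2L]]]), 1L)
  if (length(ld)) names(ld) <- vapply(spec$ld, paste, "", collapse = "~")
  dif <- vapply(spec$dif, function(d) {
    G <- if (is.list(cov_levels)) length(cov_levels[[d[2L]]]) else cov_levels[[d[2L]]]
    if (is.null(G) || !length(G)) stop("unknown covariate level count for ", d[2L])
    as.integer((G - 1L) * m[[d[1L]]])
  }, 1L)
  if (length(dif)) names(dif) <- vapply(spec$dif, paste, "", collapse = ":")
  list(total = tau + sum(ld) + sum(dif), tau = tau, ld = ld, dif = dif)
}

## ---------------------------------------------------------------------------
## Internal model structure: parameter layout and per-group loading matrices.
## Parameter vector (free): tau[1..K-1] (tau_K = -sum), then per-edge lambda
## blocks (x = 1..m_i, y = 1..m_j, column-major in y), then per DIF term
## delta blocks (levels 2..G, thresholds 1..m_i).

build_model <- function(m, spec, covariates = NULL, cap = 4096L) {
  item_ids <- names(m)
  dif_covs <- spec_covariates(spec)
  cov_levels <- list()
  if (length(dif_covs)) {
    if (is.null(covariates)) stop("DIF terms require covariates")
    for (v in dif_covs) {
      if (is.null(covariates[[v]])) stop("missing DIF covariate: ", v)
      f <- as.factor(covariates[[v]])
      f <- droplevels(f)
      if (nlevels(f) < 2L) stop("DIF covariate ", v, " has fewer than 2 levels")
      cov_levels[[v]] <- levels(f)
    }
  }
  ## person -> group index over the grid of DIF covariate level combinations
  if (length(dif_covs)) {
    fs <- lapply(dif_covs, function(v) factor(covariates[[v]], levels = cov_levels[[v]]))
    grid <- expand.grid(lapply(rev(cov_levels), function(l) l),
                        stringsAsFactors = FALSE)[, rev(seq_along(cov_levels)), drop = FALSE]
    colnames(grid) <- dif_covs
    key <- do.call(paste, c(grid, sep = "\r"))
    pkey <- do.call(paste, c(lapply(fs, as.character), sep = "\r"))
    person_group <- match(pkey, key)
    present <- sort(unique(person_group))
    grid <- grid[present, , drop = FALSE]
    person_group <- match(person_group, present)
    G <- nrow(grid)
  } else {
    person_group <- NULL # filled by caller (all 1)
    grid <- data.frame(row.names = 1L)
    G <- 1L
  }

  ## parameter layout
  K <- sum(m)
  tau_idx <- cbind(item = rep(seq_along(m), m),
                   k = unlist(lapply(m, seq_len), use.names = FALSE))
  par_names <- paste0("tau(", item_ids[tau_idx[, 1L]], ":", tau_idx[, 2L], ")")
  nfree_tau <- K - 1L
  lam_off <- integer(length(spec$ld))
  off <- nfree_tau
  lam_names <- character(0)
  for (e in seq_along(spec$ld)) {
    i <- spec$ld[[e]][1L]; j <- spec$ld[[e]][2L]
    lam_off[e] <- off
    mi <- m[[i]]; mj <- m[[j]]
    lam_names <- c(lam_names, paste0("lam(", i, "~", j, ")[",
                                     rep(seq_len(mi), mj), ",",
                                     rep(seq_len(mj), each = mi), "]"))
    off <- off + mi * mj
  }
  dif_off <- integer(length(spec$dif))
  dif_names <- character(0)
  for (t in seq_along(spec$dif)) {
    it <- spec$dif[[t]][1L]; v <- spec$dif[[t]][2L]
    dif_off[t] <- off
    mi <- m[[it]]; lv <- cov_levels[[v]]
    dif_names <- c(dif_names, paste0("dif(", it, ":", v, ")[",
                                     rep(lv[-1L], each = mi), ",",
                                     rep(seq_len(mi), length(lv) - 1L), "]"))
    off <- off + (length(lv) - 1L) * mi
  }
  npar <- off
  par_names_free <- c(paste0("tau(", item_ids[tau_idx[seq_len(K - 1L), 1L]], ":",
                             tau_idx[seq_len(K - 1L), 2L], ")"), lam_names, dif_names)

  ## generalized items
  gen <- build_generalized_items(spec, item_ids)
  components <- vector("list", length(gen))
  for (ci in seq_along(gen)) {
    members <- match(gen[[ci]], item_ids)
    sizes <- m[members] + 1L
    if (prod(sizes) > cap)
      stop("generalized item {", paste(gen[[ci]], collapse = ", "), "} has ",
           prod(sizes), " category combinations, exceeding the cap (", cap,
           "); reduce the LD component or raise `cap`")
    combos <- as.matrix(expand.grid(lapply(sizes, function(s) 0:(s - 1L))))
    dimnames(combos) <- NULL
    storage.mode(combos) <- "integer"
    score <- as.integer(rowSums(combos))
    strides <- cumprod(c(1L, sizes[-length(sizes)]))

    ## loading matrix shared across groups (tau + lambda), reduced tau basis
    ncombo <- nrow(combos)
    Atau <- matrix(0, ncombo, K)
    for (p in seq_along(members)) {
      gi <- members[p]
      cols <- which(tau_idx[, 1L] == gi)
      for (k in seq_len(m[gi]))
        Atau[combos[, p] >= k, cols[k]] <- -1
    }
    Ared <- Atau[, seq_len(K - 1L), drop = FALSE] - Atau[, K]
    A0 <- matrix(0, ncombo, npar)
    A0[, seq_len(K - 1L)] <- Ared
    for (e in seq_along(spec$ld)) {
      pr <- spec$ld[[e]]
      if (!all(pr %in% gen[[ci]])) next
      pi_ <- match(pr[1L], gen[[ci]]); pj <- match(pr[2L], gen[[ci]])
      xi <- combos[, pi_]; xj <- combos[, pj]
      sel <- xi >= 1L & xj >= 1L
      mi <- m[[pr[1L]]]
      cols <- lam_off[e] + (xj[sel] - 1L) * mi + xi[sel]
      A0[cbind(which(sel), cols)] <- 1
    }
    ## per-group matrices: add delta loadings
    A <- vector("list", G)
    for (g in seq_len(G)) {
      Ag <- A0
      for (t in seq_along(spec$dif)) {
        it <- spec$dif[[t]][1L]; v <- spec$dif[[t]][2L]
        if (!(it %in% gen[[ci]])) next
        lv <- cov_levels[[v]]
        l <- match(grid[g, v], lv)
        if (l == 1L) next
        p <- match(it, gen[[ci]])
        mi <- m[[it]]
        base <- dif_off[t] + (l - 2L) * mi
        for (k in seq_len(mi))
          Ag[combos[, p] >= k, base + k] <- Ag[combos[, p] >= k, base + k] - 1
      }
      A[[g]] <- Ag
    }
    components[[ci]] <- list(members = members, member_ids = gen[[ci]],
                             combos = combos, score = score,
                             score_fac = factor(score, levels = 0:sum(m[members])),
                             strides = strides, A = A,
                             max_score = sum(m[members]))
  }

  list(item_ids = item_ids, m = m, spec = spec, components = components,
       npar = npar, par_names = par_names_free, K = K, tau_idx = tau_idx,
       lam_off = lam_off, dif_off = dif_off,
       dif_covs = dif_covs, cov_levels = cov_levels, groups = grid, G = G,
       person_group = person_group, max_score = sum(m))
}

## combo row index of each person within component `comp`
combo_index <- function(comp, resp) {
  idx <- rep(1L, nrow(resp))
  for (p in seq_along(comp$members))
    idx <- idx + resp[, comp$members[p]] * comp$strides[p]
  idx
}

## component log-weights at parameter vector p for group g
comp_logw <- function(comp, g, p) as.vector(comp$A[[g]] %*% p)

## score-indexed weight vector (linear scale + logscale attr)
comp_u <- function(comp, g, p) {
  lw <- comp_logw(comp, g, p)
  mx <- max(lw)
  w <- exp(lw - mx)
  u <- as.vector(rowsum(w, comp$score_fac))
  list(u = u, w = w, logscale = mx)
}
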