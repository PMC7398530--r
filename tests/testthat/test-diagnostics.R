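test_that("chi-square tail areas reproduce published-style CLR p-values", {
  ## a CLR of 26.1 on 17 df is non-significant at about .073
  expect_equal(stats::pchisq(26.1, 17, lower.tail = FALSE), 0.073,
               tolerance = 5e-3)
})

test_that("Andersen CLR vanishes for two byte-identical groups", {
  sim <- simulate_responses(200, toy_tau6()[1:4], theta_sd = 1.2, seed = 81)
  dup <- resp_matrix(rbind(sim$responses$responses, sim$responses$responses),
                     base = 0L, max_cat = sim$responses$max_cat)
  cov <- data.frame(half = factor(rep(c("a", "b"), each = 200)))
  fit <- gllrm(dup, covariates = cov, control = quickfit)
  t <- andersen_clr(fit, "half")
  expect_lt(abs(t$statistic), 1e-3)
  expect_equal(t$df, 11L) # (2 - 1) x (4 items x 3 thresholds - 1)
})

test_that("Andersen df bookkeeping follows (groups - 1) x free parameters", {
  set.seed(82)
  sim <- simulate_responses(600, toy_tau6(), theta_sd = 1.4, seed = 82)
  cov <- data.frame(age4 = factor(sample(letters[1:4], 600, TRUE)),
                    bin = factor(sample(c("x", "y"), 600, TRUE)))
  fit <- gllrm(sim$responses, covariates = cov, control = quickfit)
  hom <- andersen_clr(fit, "score")
  expect_equal(hom$df, 17L)
  a4 <- andersen_clr(fit, "age4")
  expect_equal(a4$df, 3L * 17L) # 51
  b2 <- andersen_clr(fit, "bin")
  expect_equal(b2$df, 17L)
})

test_that("item-restscore expected gamma matches brute-force enumeration", {
  set.seed(83)
  tau <- list(A = c(-0.6, 0.4), B = c(0, 0.2), C = c(-0.3, 0.5))
  sim <- simulate_responses(250, tau, theta_sd = 1.3, seed = 83)
  fit <- rasch_cml(sim$responses, control = quickfit)
  irs <- item_restscore(fit, B = 50, seed = 1)
  ## oracle: enumerate P(pattern | S = s) at the fitted thresholds and
  ## accumulate the (item, restscore) joint over the observed score margin
  tl <- split(unname(coef(fit, "tau")), rep(1:3, fit$m))
  pat <- all_patterns(fit$m)
  lw <- rowSums(vapply(1:3, function(i) {
    beta <- c(0, -cumsum(tl[[i]]))
    beta[pat[, i] + 1L]
  }, numeric(nrow(pat))))
  w <- exp(lw)
  s_all <- rowSums(pat)
  ns <- tabulate(fit$score + 1L, fit$model$max_score + 1L)
  for (i in 1:3) {
    TT <- matrix(0, fit$m[i] + 1L, fit$model$max_score + 1L)
    for (s in which(ns > 0) - 1L) {
      sel <- s_all == s
      ps <- w[sel] / sum(w[sel])
      xs <- pat[sel, i]
      for (k in seq_along(ps))
        TT[xs[k] + 1L, s - xs[k] + 1L] <- TT[xs[k] + 1L, s - xs[k] + 1L] +
          ns[s + 1L] * ps[k]
    }
    expect_equal(irs$expected[i], gk_gamma(TT)$gamma, tolerance = 1e-6)
  }
})

test_that("item-restscore discrepancies centre at zero under the model", {
  set.seed(84)
  sim <- simulate_responses(500, toy_tau6()[1:4], theta_sd = 1.4, seed = 84)
  fit <- rasch_cml(sim$responses, control = quickfit)
  irs <- item_restscore(fit, B = 120, seed = 2)
  expect_lt(max(abs(irs$observed - irs$expected) / irs$se), 3.5)
  expect_true(all(irs$p_adj >= irs$p))
})

test_that("model-based screens do not flag structure the model carries", {
  sim <- simulate_responses(800, toy_tau6()[1:4],
                            ld = list(list(items = c("I1", "I2"), lambda = 0.8)),
                            theta_sd = 1.4, seed = 85)
  fit <- gllrm(sim$responses, gllrm_spec(ld = list(c("I1", "I2"))),
               control = quickfit)
  ld <- scan_ld(fit)
  row <- ld[ld$item1 == "I1" & ld$item2 == "I2", ]
  expect_true(row$in_spec)
  expect_gt(row$p, 0.01) # modelled LD is not re-flagged
  ## but the plain Rasch fit flags it strongly
  ld0 <- scan_ld(rasch_cml(sim$responses, control = quickfit))
  expect_lt(ld0$p_adj[ld0$item1 == "I1" & ld0$item2 == "I2"], 0.001)
})

test_that("Kelderman tests are zero on equal specs and non-negative when nested", {
  cov <- data.frame(s = factor(rep(c("a", "b"), 150)))
  sim <- simulate_responses(300, toy_tau6()[1:4], theta_sd = 1.3, seed = 86)
  spec <- gllrm_spec(dif = list(c("I1", "s")))
  fit <- gllrm(sim$responses, spec, covariates = cov, control = quickfit)
  same <- kelderman_lr(fit, spec)
  expect_equal(same$statistic, 0)
  expect_equal(same$df, 0)
  drop1 <- kelderman_lr(fit, "I1:s")
  expect_equal(drop1$df, 3L) # 2 levels x 3 thresholds
  expect_gte(drop1$statistic, 0)
  expect_error(kelderman_lr(fit, gllrm_spec(ld = list(c("I1", "I2")))),
               "nested")
})

test_that("duplicated subscores give observed unidimensionality gamma of one", {
  set.seed(87)
  tau3 <- toy_tau6()[1:3]
  sim <- simulate_responses(250, tau3, theta_sd = 1.3, seed = 87)
  x <- sim$responses$responses
  dup <- cbind(x, x)
  colnames(dup) <- c("I1", "I2", "I3", "J1", "J2", "J3")
  fit <- suppressWarnings(
    gllrm(resp_matrix(dup, base = 0L, max_cat = rep(3L, 6)), control = quickfit))
  u <- unidimensionality_test(fit, first = c("I1", "I2", "I3"),
                              second = c("J1", "J2", "J3"), M = 120, seed = 3)
  expect_equal(u$statistic, 1)
  expect_lte(u$p, 1)
})

test_that("a planted second dimension is detected as too-low subscore correlation", {
  set.seed(88)
  n <- 400
  th1 <- rnorm(n, 0, 1.3)
  th2 <- 0.3 * th1 + sqrt(1 - 0.09) * rnorm(n, 0, 1.3)
  tau <- toy_tau6()
  a <- simulate_responses(n, tau[1:3], theta = th1)
  b <- simulate_responses(n, tau[4:6], theta = th2)
  x <- cbind(a$responses$responses, b$responses$responses)
  fit <- gllrm(resp_matrix(x, base = 0L, max_cat = rep(3L, 6)), control = quickfit)
  u <- unidimensionality_test(fit, first = colnames(x)[1:3],
                              second = colnames(x)[4:6], M = 200, seed = 4)
  expect_lt(u$statistic, u$expected)
  expect_lt(u$p, 0.05)
})
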