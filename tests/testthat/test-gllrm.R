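test_that("LD-connected components become generalized items", {
  ids <- paste0("INQ", 1:6)
  spec <- gllrm_spec(ld = list(c("INQ1", "INQ2"), c("INQ1", "INQ4"),
                               c("INQ4", "INQ5")))
  gen <- build_generalized_items(spec, ids)
  sets <- lapply(gen, sort)
  expect_true(list(c("INQ1", "INQ2", "INQ4", "INQ5")) %in% sets ||
                any(vapply(sets, identical, TRUE,
                           c("INQ1", "INQ2", "INQ4", "INQ5"))))
  expect_length(gen, 3L)
  ## no edges: every item its own generalized item
  expect_length(build_generalized_items(gllrm_spec(), ids), 6L)
})

test_that("a two-item component spans the cross-product with summed scores", {
  m <- c(A = 3L, B = 3L)
  model <- gllrm:::build_model(m, gllrm_spec(ld = list(c("A", "B"))))
  comp <- model$components[[1L]]
  expect_equal(nrow(comp$combos), 16L)
  expect_equal(sort(unique(comp$score)), 0:6)
  ## the combination cap rejects oversized components
  m2 <- c(A = 7L, B = 7L, C = 7L, D = 7L, E = 7L)
  expect_error(gllrm:::build_model(m2, gllrm_spec(ld = list(c("A", "B"),
                                                            c("B", "C"),
                                                            c("C", "D"),
                                                            c("D", "E")))),
               "cap")
})

test_that("free-parameter bookkeeping matches the standard configurations", {
  m6 <- stats::setNames(rep(3L, 6), paste0("INQ", 1:6))
  m5 <- stats::setNames(rep(3L, 5), paste0("T", 1:5))
  expect_equal(free_param_count(m6)$tau, 17L)
  expect_equal(free_param_count(m5)$tau, 14L)
  expect_equal(unname(free_param_count(m6, gllrm_spec(ld = list(c("INQ1", "INQ2"))))$ld), 9L)
  expect_equal(unname(free_param_count(
    m6, gllrm_spec(dif = list(c("INQ2", "age"))),
    cov_levels = list(age = letters[1:4]))$dif), 9L)
  expect_equal(unname(free_param_count(
    m6, gllrm_spec(dif = list(c("INQ1", "sample"))),
    cov_levels = list(sample = c("gp", "clinical")))$dif), 3L)
})

test_that("an empty specification reproduces the Rasch fit exactly", {
  set.seed(41)
  sim <- simulate_responses(300, toy_tau6()[1:4], theta_sd = 1.3, seed = 1)
  cov <- data.frame(g = factor(sample(c("a", "b"), 300, TRUE)))
  f1 <- rasch_cml(sim$responses, control = quickfit)
  f2 <- gllrm(sim$responses, gllrm_spec(), covariates = cov, control = quickfit)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-8)
})

test_that("nested conditional likelihoods are ordered", {
  for (s in 1:4) {
    sim <- simulate_responses(250, toy_tau6()[1:4], theta_sd = 1.2, seed = 50 + s)
    cov <- data.frame(g = factor(rep(c("a", "b"), length.out = 250)))
    rm_fit <- rasch_cml(sim$responses, control = quickfit)
    gl <- gllrm(sim$responses, gllrm_spec(ld = list(c("I1", "I2")),
                                          dif = list(c("I3", "g"))),
                covariates = cov, control = quickfit)
    expect_gte(gl$logLik - rm_fit$logLik, -1e-6)
  }
})

test_that("planted LD is recovered in sign and ordering and confirmed", {
  sim <- simulate_responses(1000, toy_tau6()[1:4],
                            ld = list(list(items = c("I1", "I2"), lambda = 0.8)),
                            theta_sd = 1.5, seed = 61)
  fit <- gllrm(sim$responses, gllrm_spec(ld = list(c("I1", "I2"))),
               control = quickfit)
  lam <- matrix(coef(fit, "lambda"), 3, 3)
  ## linear-by-linear truth: estimates increase along the diagonal
  expect_gt(lam[3, 3], lam[1, 1])
  expect_gt(lam[3, 3], 0)
  kl <- kelderman_lr(fit, "I1~I2")
  expect_equal(kl$df, 9L)
  expect_lt(kl$p, 0.01)
})

test_that("planted uniform DIF offsets are recovered", {
  cov <- data.frame(grp = factor(rep(c("a", "b"), each = 1000)))
  sim <- simulate_responses(2000, toy_tau6()[1:4],
                            dif = list(list(item = "I2", covariate = "grp",
                                            delta = list(b = 0.5))),
                            covariates = cov, theta_sd = 1.5, seed = 62)
  fit <- gllrm(sim$responses, gllrm_spec(dif = list(c("I2", "grp"))),
               covariates = cov, control = quickfit)
  expect_lt(abs(mean(coef(fit, "delta")) - 0.5), 0.15)
})

test_that("GLLRM fitted to Rasch data gives interaction estimates near zero", {
  sim <- simulate_responses(1500, toy_tau6()[1:4], theta_sd = 1.5, seed = 63)
  cov <- data.frame(g = factor(rep(c("a", "b"), length.out = 1500)))
  fit <- gllrm(sim$responses, gllrm_spec(ld = list(c("I1", "I3")),
                                         dif = list(c("I4", "g"))),
               covariates = cov, control = quickfit)
  expect_lt(mean(abs(coef(fit, "lambda"))), 0.5)
  expect_lt(mean(abs(coef(fit, "delta"))), 0.25)
})

test_that("score sufficiency holds under LD: conditional probabilities are theta-free", {
  ## brute-force: P(pattern | S = r) from the generating weights at two
  ## different theta values must coincide and match the fitted machinery
  tau <- list(A = c(-0.5, 0.5), B = c(0, 0.3), C = c(-0.2, 0.1))
  lam <- 0.6
  pat <- all_patterns(c(2, 2, 2))
  lw <- rowSums(vapply(1:3, function(i) {
    beta <- c(0, -cumsum(tau[[i]]))
    beta[pat[, i] + 1L]
  }, numeric(nrow(pat)))) + lam * pat[, 1] * pat[, 2]
  for (th in c(0, 1.3)) {
    w <- exp(lw + th * rowSums(pat))
    p4 <- w[rowSums(pat) == 4] / sum(w[rowSums(pat) == 4])
    if (th == 0) p4_ref <- p4 else expect_equal(p4, p4_ref, tolerance = 1e-12)
  }
})
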