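test_that("clean Rasch data terminates the search at the Rasch model", {
  sim <- simulate_responses(500, toy_tau6()[1:4], theta_sd = 1.3, seed = 111)
  cov <- data.frame(g = factor(rep(c("a", "b"), length.out = 500)))
  sr <- model_search(sim$responses, covariates = cov, dif_covariates = "g",
                     boot = 100, seed = 1)
  expect_equal(sr$status, "final")
  expect_length(spec_term_labels(sr$spec), 0L)
  expect_equal(sort(sr$items), paste0("I", 1:4))
})

test_that("a planted LD edge and DIF term are both recovered", {
  cov <- data.frame(g = factor(rep(c("a", "b"), each = 185)))
  sim <- simulate_responses(370, toy_tau6(),
                            ld = list(list(items = c("I1", "I2"), lambda = 0.8)),
                            dif = list(list(item = "I4", covariate = "g",
                                            delta = list(b = 0.5))),
                            covariates = cov, theta_sd = 1.4, seed = 112)
  sr <- model_search(sim$responses, covariates = cov, dif_covariates = "g",
                     boot = 100, seed = 2)
  found <- spec_term_labels(sr$spec)
  expect_true("I1~I2" %in% found)
  truth <- list(ld = "I1~I2", dif = "I4:g",
                dif_delta = list(g = c(I4 = 0.5)), items = paste0("I", 1:6))
  expect_gte(structure_recovery(truth, sr$spec, sr$items)$fraction, 0.5)
})

test_that("a non-scalable item is the one eliminated", {
  set.seed(113)
  n <- 1500
  th <- rnorm(n, 0, 1.3)
  tau <- toy_tau6()
  sim <- simulate_responses(n, tau, theta = th,
                            theta_item = list(I3 = 0.3 * th), seed = 113)
  sr <- model_search(sim$responses, boot = 150, seed = 3, max_iter = 8)
  expect_true("I3" %in% sr$dropped_items)
  expect_false("I3" %in% sr$items)
})

test_that("the search is deterministic under a fixed seed", {
  cov <- data.frame(g = factor(rep(c("a", "b"), each = 150)))
  sim <- simulate_responses(300, toy_tau6()[1:4],
                            ld = list(list(items = c("I1", "I3"), lambda = 0.8)),
                            covariates = cov, theta_sd = 1.3, seed = 114)
  s1 <- model_search(sim$responses, covariates = cov, dif_covariates = "g",
                     boot = 80, seed = 9)
  s2 <- model_search(sim$responses, covariates = cov, dif_covariates = "g",
                     boot = 80, seed = 9)
  expect_identical(spec_term_labels(s1$spec), spec_term_labels(s2$spec))
  expect_identical(s1$status, s2$status)
  expect_identical(lapply(s1$log, `[[`, "action"), lapply(s2$log, `[[`, "action"))
})

test_that("retained terms always pass their confirmatory tests", {
  cov <- data.frame(g = factor(rep(c("a", "b"), each = 250)))
  sim <- simulate_responses(500, toy_tau6()[1:4],
                            ld = list(list(items = c("I2", "I4"), lambda = 0.8)),
                            covariates = cov, theta_sd = 1.3, seed = 115)
  sr <- model_search(sim$responses, covariates = cov, dif_covariates = "g",
                     boot = 80, seed = 4)
  if (!is.null(sr$confirmatory) && nrow(sr$confirmatory))
    expect_true(all(sr$confirmatory$p < 0.05))
})
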