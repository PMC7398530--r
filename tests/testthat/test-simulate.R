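test_that("generated item means match closed-form expectations", {
  ## dichotomous items with tau = 0 at theta = 0: mean 1/2
  tau <- list(A = 0, B = 0, C = 0)
  sim <- simulate_responses(40000, tau, theta = rep(0, 40000), seed = 101)
  means <- colMeans(sim$responses$responses)
  mc_se <- sqrt(0.25 / 40000)
  expect_true(all(abs(means - 0.5) < 3 * mc_se + 1e-9))
})

test_that("conditional pattern frequencies match the model given the score", {
  ## sample patterns at fixed total scores and compare with conditional
  ## probabilities from enumeration
  tau <- list(A = c(-0.5, 0.4), B = c(0.2, 0.1), C = c(-0.1, 0.3))
  sim <- simulate_responses(60000, tau, theta_sd = 1.2, seed = 102)
  x <- sim$responses$responses
  s <- rowSums(x)
  for (r in c(2, 3)) {
    sel <- s == r
    pat <- all_patterns(c(2, 2, 2))
    pr <- pat[rowSums(pat) == r, , drop = FALSE]
    probs <- apply(pr, 1, function(p) bf_cond_prob(p, tau))
    key <- apply(pr, 1, paste, collapse = "")
    obs <- table(factor(apply(x[sel, ], 1, paste, collapse = ""), levels = key))
    gof <- suppressWarnings(stats::chisq.test(as.vector(obs), p = probs))
    expect_gt(gof$p.value, 1e-3)
  }
})

test_that("the fixture reproduces the study-like structure", {
  fx <- inq_fixture(seed = 5, n_gp = 900, n_clinical = 185)
  expect_equal(nrow(fx$gp$responses$responses), 900L)
  expect_equal(nrow(fx$clinical$responses$responses), 185L)
  expect_equal(length(fx$gp$responses$item_ids), 15L)
  ## raw coding is 1..7
  expect_true(all(fx$gp$responses$responses + 1L >= 1 &
                    fx$gp$responses$responses + 1L <= 7))
  ## ground truth lists exactly the planted terms
  expect_setequal(fx$truth$pb$ld, c("INQ1~INQ2", "INQ4~INQ5"))
  expect_setequal(fx$truth$pb$dif,
                  paste0(c("INQ1", "INQ2", "INQ4", "INQ5"), ":sample"))
  expect_setequal(fx$truth$tb$ld, c("INQ7~INQ8", "INQ13~INQ14"))
  expect_equal(fx$truth$tb$nonscalable, "INQ10")
})

test_that("generator regimes deliver the intended floor and targeting", {
  ## general-population-like configuration: latent mean three logits below
  ## the mean threshold gives a severe floor
  off <- c(0.3, 0, -0.1)
  tau <- lapply(seq(-0.7, 0.7, length.out = 6), function(l) l + off)
  names(tau) <- paste0("I", 1:6)
  mu <- mean(unlist(tau)) - 3
  gp <- simulate_responses(1500, tau, theta_mean = mu, theta_sd = 0.65,
                           seed = 131)
  expect_gt(mean(score_extremes(gp$responses)$score == 0), 0.70)
  ## clinical-like configuration: centred on the thresholds
  cl <- simulate_responses(400, tau, theta_mean = mean(unlist(tau)),
                           theta_sd = 1.0, seed = 132)
  expect_lt(mean(score_extremes(cl$responses)$score == 0), 0.15)
  fit <- gllrm(cl$responses, control = quickfit)
  expect_gt(targeting(fit)$indices$info_target_index[1], 0.6)
})

test_that("the fixture's two populations bracket the floor regimes", {
  fx <- inq_fixture(seed = 6, n_gp = 1500, n_clinical = 185)
  pb_gp <- apply_coding(fx$gp$responses, fx$scales$pb)
  pb_cl <- apply_coding(fx$clinical$responses, fx$scales$pb)
  expect_gt(mean(score_extremes(pb_gp)$score == 0), 0.60)
  expect_lt(mean(score_extremes(pb_cl)$score == 0), 0.15)
  tb_gp <- apply_coding(fx$gp$responses, fx$scales$tb)
  expect_gt(mean(score_extremes(tb_gp)$score == 0), 0.10)
})

test_that("structure recovery scores DIF up to anchoring equivalence", {
  truth <- list(ld = c("A~B"), dif = paste0(c("A", "B", "C"), ":g"),
                dif_delta = list(g = c(A = -0.5, B = -0.5, C = -0.5)),
                items = c("A", "B", "C", "D", "E"))
  ## exact representation
  s1 <- gllrm_spec(ld = list(c("A", "B")),
                   dif = list(c("A", "g"), c("B", "g"), c("C", "g")))
  expect_equal(structure_recovery(truth, s1)$fraction, 1)
  ## complementary representation: DIF on D and E with opposite sign is the
  ## same conditional model
  s2 <- gllrm_spec(ld = list(c("A", "B")), dif = list(c("D", "g"), c("E", "g")))
  expect_equal(structure_recovery(truth, s2)$fraction, 1)
  ## missing the edge costs its share
  s3 <- gllrm_spec(dif = list(c("D", "g"), c("E", "g")))
  expect_equal(structure_recovery(truth, s3)$fraction, 0.75)
  ## unrelated terms are reported as extras
  s4 <- gllrm_spec(ld = list(c("C", "D")))
  rec <- structure_recovery(truth, s4)
  expect_equal(rec$recovered, 0)
  expect_true("C~D" %in% rec$extra)
})
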