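test_that("Monte-Carlo reliability recovers the generator's truth", {
  tau <- toy_tau6()
  sim <- simulate_responses(800, tau, theta_mean = 0, theta_sd = 1.3, seed = 91)
  fit <- rasch_cml(sim$responses, control = quickfit)
  rel <- mc_reliability(fit, M = 1500, seed = 7)
  ## oracle: the generator's own true-score variance ratio at large n
  big <- simulate_responses(20000, tau, theta_mean = 0, theta_sd = 1.3, seed = 92)
  ## true score E[S | theta] by enumeration of per-item expectations
  et <- function(th) {
    s <- 0
    for (t in tau) {
      beta <- c(0, -cumsum(t))
      w <- exp(beta + th * (0:3))
      s <- s + sum(w * (0:3)) / sum(w)
    }
    s
  }
  ts <- vapply(big$theta, et, 0)
  truth <- stats::var(ts) / stats::var(rowSums(big$responses$responses))
  expect_equal(rel$reliability, truth, tolerance = 0.03)
})

test_that("reliability is seed-stable and degenerate scores give zero", {
  sim <- simulate_responses(600, toy_tau6()[1:4], theta_sd = 1.2, seed = 93)
  fit <- rasch_cml(sim$responses, control = quickfit)
  r1 <- mc_reliability(fit, M = 1000, seed = 1)$reliability
  r2 <- mc_reliability(fit, M = 1000, seed = 99)$reliability
  expect_lt(abs(r1 - r2), 0.02)
  ## all persons at one score: no observable variance, reliability 0
  x <- matrix(c(1, 0, 0,
                0, 1, 0,
                0, 0, 1), 3, byrow = TRUE)[rep(1:3, 12), ]
  colnames(x) <- c("A", "B", "C")
  dfit <- rasch_cml(resp_matrix(x, base = 0L, max_cat = 1L), control = quickfit)
  expect_warning(r0 <- mc_reliability(dfit, M = 200, seed = 2), "degenerate")
  expect_equal(r0$reliability, 0)
})

test_that("targeting indices are one in the degenerate single-score case", {
  x <- matrix(c(1, 0, 0,
                0, 1, 0,
                0, 0, 1), 3, byrow = TRUE)[rep(1:3, 15), ]
  colnames(x) <- c("A", "B", "C")
  fit <- rasch_cml(resp_matrix(x, base = 0L, max_cat = 1L), control = quickfit)
  tg <- targeting(fit)
  ov <- tg$indices[tg$indices$group == "overall", ]
  expect_equal(ov$rmse_target_index, 1) # min SEM = mean SEM at one score
  expect_equal(ov$floor_pct + ov$ceiling_pct, 0)
})

test_that("targeting indices are bounded and floors counted", {
  sim <- simulate_responses(600, toy_tau6(), theta_mean = -3, theta_sd = 0.8,
                            seed = 94)
  fit <- rasch_cml(sim$responses, control = quickfit)
  tg <- targeting(fit)
  ov <- tg$indices[tg$indices$group == "overall", ]
  expect_true(ov$info_target_index > 0 && ov$info_target_index <= 1)
  expect_true(ov$rmse_target_index > 0 && ov$rmse_target_index <= 1)
  expect_gt(ov$floor_pct, 30) # badly targeted population piles on the floor
})

test_that("equating is the identity without DIF and monotone with it", {
  cov <- data.frame(s = factor(rep(c("a", "b"), each = 400)))
  sim <- simulate_responses(800, toy_tau6()[1:4],
                            dif = list(list(item = "I1", covariate = "s",
                                            delta = list(b = 0.5)),
                                       list(item = "I2", covariate = "s",
                                            delta = list(b = 0.5))),
                            covariates = cov, theta_sd = 1.3, seed = 95)
  nodif <- gllrm(sim$responses, gllrm_spec(), covariates = cov,
                 control = quickfit)
  eq0 <- equate_scores(nodif, "s")
  expect_false(eq0$has_dif)
  expect_equal(eq0$table$equated, eq0$table$score)
  expect_equal(eq0$max_abs_diff, 0)

  fit <- gllrm(sim$responses, gllrm_spec(dif = list(c("I1", "s"), c("I2", "s"))),
               covariates = cov, control = quickfit)
  eq <- equate_scores(fit, "s")
  tabb <- eq$table[eq$table$level == "b", ]
  expect_true(all(diff(tabb$equated) > -1e-8)) # monotone in the raw score
  ## group b finds the DIF items harder, so equating onto the reference
  ## scale moves its scores up
  mid <- tabb$score > 2 & tabb$score < 10
  expect_gt(mean(tabb$diff[mid]), 0)
  ## adjustment magnitude in the vicinity of the planted effect
  expect_lt(abs(eq$max_abs_diff - 1.5), 1.4)
})

test_that("equating a group to itself returns the identity map", {
  cov <- data.frame(s = factor(rep(c("a", "b"), each = 200)))
  sim <- simulate_responses(400, toy_tau6()[1:4],
                            dif = list(list(item = "I1", covariate = "s",
                                            delta = list(b = 0.6))),
                            covariates = cov, theta_sd = 1.3, seed = 96)
  fit <- gllrm(sim$responses, gllrm_spec(dif = list(c("I1", "s"))),
               covariates = cov, control = quickfit)
  eq <- equate_scores(fit, "s")
  ref <- eq$table[eq$table$level == eq$reference, ]
  expect_equal(ref$equated, ref$score)
})
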