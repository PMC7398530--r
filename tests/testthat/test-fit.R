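test_that("item-symmetric data yields equal thresholds", {
  ## every pattern and its column swap occur equally often
  pats <- rbind(c(0, 1), c(1, 0), c(0, 2), c(2, 0), c(1, 2), c(2, 1),
                c(1, 1), c(2, 2), c(0, 0), c(2, 2))
  x <- pats[rep(seq_len(nrow(pats)), 5), ]
  colnames(x) <- c("A", "B")
  fit <- rasch_cml(resp_matrix(x, base = 0L, max_cat = 2L), control = quickfit)
  tau <- coef(fit, "tau")
  expect_equal(unname(tau[1:2]), unname(tau[3:4]), tolerance = 1e-6)
})

test_that("tiny dichotomous fit matches a brute-force grid maximiser", {
  set.seed(31)
  ## 2 items x 2 categories; identified parameter is the threshold contrast
  x <- cbind(A = rbinom(60, 1, 0.6), B = rbinom(60, 1, 0.35))
  keep <- rowSums(x) == 1 # only mixed scores inform the conditional fit
  expect_gt(sum(keep), 5)
  fit <- rasch_cml(resp_matrix(x, base = 0L, max_cat = 1L), control = quickfit)
  ## grid: tau = (t, -t); cll = sum over score-1 persons of log P(x | s = 1)
  n10 <- sum(x[keep, 1] == 1)
  n01 <- sum(keep) - n10
  cll <- function(t) {
    p10 <- exp(-t) / (exp(-t) + exp(t))
    n10 * log(p10) + n01 * log(1 - p10)
  }
  grid <- seq(-3, 3, by = 1e-4)
  t_hat <- grid[which.max(vapply(grid, cll, 0))]
  expect_equal(unname(coef(fit, "tau")[1]), t_hat, tolerance = 1e-4)
})

test_that("CML recovers generating thresholds with shrinking error", {
  tau <- toy_tau6()
  rmse_at <- function(n, seed) {
    sim <- simulate_responses(n, tau, theta_mean = 0, theta_sd = 1.5, seed = seed)
    fit <- rasch_cml(sim$responses, control = quickfit)
    est <- split(unname(coef(fit, "tau")), rep(1:6, each = 3))
    sqrt(mean((unlist(est) - unlist(tau))^2))
  }
  r200 <- mean(vapply(1:3, function(s) rmse_at(200, s), 0))
  r1000 <- mean(vapply(1:3, function(s) rmse_at(1000, 10 + s), 0))
  expect_lt(r1000, r200)
  expect_lt(r1000, 0.2)
})

test_that("gradient is driven to the convergence tolerance", {
  set.seed(33)
  sim <- simulate_responses(300, toy_tau6()[1:4], theta_sd = 1.2, seed = 3)
  fit <- rasch_cml(sim$responses)
  expect_true(fit$converged)
  expect_lt(fit$gradient_norm, 1e-6 * fit$n_used)
  ## standard errors present and positive
  expect_true(all(fit$se[seq_len(fit$model$K - 1L)] > 0))
})

test_that("expected item scores increase with the latent trait", {
  set.seed(34)
  sim <- simulate_responses(400, toy_tau6()[1:4], theta_sd = 1.2, seed = 5)
  fit <- rasch_cml(sim$responses, control = quickfit)
  grid <- seq(-4, 4, length.out = 17)
  probs <- predict(fit, theta = grid, type = "prob")
  escore <- vapply(probs, function(P) as.vector(P %*% 0:max(fit$m)),
                   numeric(length(fit$item_ids)))
  for (i in seq_len(nrow(escore)))
    expect_true(all(diff(escore[i, ]) > -1e-10))
})

test_that("zero-frequency categories are merged and logged", {
  set.seed(35)
  x <- matrix(sample(c(0L, 1L, 3L), 80, replace = TRUE), 20) # category 2 absent
  colnames(x) <- paste0("I", 1:4)
  fit <- rasch_cml(resp_matrix(x, base = 0L, max_cat = 3L), control = quickfit)
  expect_gt(length(fit$collapse_log), 0)
  expect_true(all(fit$m <= 3L))
  expect_true(fit$converged)
})

test_that("score table is monotone with information matching enumeration", {
  set.seed(36)
  tau <- lapply(c(2, 2, 2), function(mm) sort(rnorm(mm)))
  names(tau) <- c("A", "B", "C")
  sim <- simulate_responses(400, tau, theta_sd = 1.5, seed = 7)
  fit <- rasch_cml(sim$responses, control = quickfit)
  st <- score_table(fit)
  expect_true(all(diff(st$theta) > 0))
  ## I(theta) equals Var(S | theta) by brute-force enumeration
  pat <- all_patterns(fit$m)
  tl <- split(unname(coef(fit, "tau")), rep(seq_along(fit$m), fit$m))
  lw <- rowSums(vapply(seq_along(tl), function(i) {
    beta <- c(0, -cumsum(tl[[i]]))
    beta[pat[, i] + 1L]
  }, numeric(nrow(pat))))
  th <- st$theta[4] # a mid-range location
  w <- exp(lw + th * rowSums(pat))
  p <- w / sum(w)
  vs <- sum(p * rowSums(pat)^2) - sum(p * rowSums(pat))^2
  expect_equal(st$info[4], vs, tolerance = 1e-8)
  ## symmetric items: mid-range score sits at theta 0
  tau_sym <- list(A = c(-1, 1), B = c(-1, 1))
  sim2 <- simulate_responses(200, tau_sym, theta_sd = 1, seed = 8)
  fit2 <- rasch_cml(sim2$responses, control = quickfit)
  st2 <- score_table(fit2)
  mid <- st2$theta[st2$score == 2]
  expect_lt(abs(mid), 0.3)
})
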