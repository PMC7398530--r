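test_that("elementary symmetric functions match closed forms", {
  expect_equal(esf(list(0)), c(1, 1))
  ## n dichotomous items with tau = 0: binomial coefficients
  for (n in 2:5)
    expect_equal(esf(rep(list(0), n)), choose(n, 0:n))
})

test_that("ESF matches brute-force enumeration on polytomous items", {
  set.seed(21)
  for (rep in 1:5) {
    m <- sample(1:3, sample(2:4, 1), replace = TRUE)
    tau <- lapply(m, function(mm) rnorm(mm))
    expect_equal(esf(tau), bf_esf(tau), tolerance = 1e-12)
  }
})

test_that("log-space and direct ESF agree", {
  set.seed(22)
  tau <- lapply(c(3, 3, 2), function(mm) rnorm(mm, 0, 2))
  expect_equal(exp(esf(tau, log = TRUE)), esf(tau), tolerance = 1e-10)
})

test_that("conditional probabilities are correct and normalised", {
  ## two dichotomous items, tau = 0, score 1: each pattern has probability 1/2
  expect_equal(conditional_prob(c(1, 0), 1, list(0, 0)), 0.5)
  expect_equal(conditional_prob(c(0, 1), 1, list(0, 0)), 0.5)
  ## normalisation over all patterns at every score, 3-item toy
  set.seed(23)
  tau <- lapply(c(2, 2, 2), function(mm) rnorm(mm))
  pat <- all_patterns(c(2, 2, 2))
  for (r in 0:6) {
    ps <- apply(pat[rowSums(pat) == r, , drop = FALSE], 1L,
                function(x) conditional_prob(x, r, tau))
    expect_equal(sum(ps), 1, tolerance = 1e-12)
  }
  ## enumeration oracle at a fixed pattern
  set.seed(24)
  tau <- lapply(c(2, 2, 2), function(mm) rnorm(mm))
  x <- c(2, 1, 1)
  expect_equal(conditional_prob(x, 4, tau), bf_cond_prob(x, tau),
               tolerance = 1e-12)
  expect_error(conditional_prob(c(1, 0), 0, list(0, 0)), "must equal")
})

test_that("conditional probabilities are invariant to location shifts", {
  ## adding a constant to every threshold moves the latent scale only
  set.seed(25)
  tau <- lapply(c(2, 3), function(mm) rnorm(mm))
  shifted <- lapply(tau, function(t) t + 0.7)
  x <- c(1, 2)
  expect_equal(conditional_prob(x, 3, tau), conditional_prob(x, 3, shifted),
               tolerance = 1e-12)
})
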