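test_that("category recoding merges seven options into four as specified", {
  raw <- resp_matrix(matrix(c(1, 5, 7,
                              2, 4, 6), nrow = 2, byrow = TRUE,
                            dimnames = list(NULL, c("A", "B", "C"))),
                     base = 1L, max_cat = 6L)
  spec <- scale_spec("S", c("A", "B", "C"), recode = c(1, 2, 2, 3, 3, 4, 4))
  coded <- apply_coding(raw, spec)
  ## 1-based: 1 -> 1, 5 -> 3, 7 -> 4, 2 -> 2, 4 -> 3, 6 -> 4
  expect_equal(coded$responses + 1L,
               matrix(c(1, 3, 4, 2, 3, 4), nrow = 2, byrow = TRUE,
                      dimnames = list(NULL, c("A", "B", "C"))))
  expect_equal(unname(coded$max_cat), rep(3L, 3))
})

test_that("reverse keying is an involution applied before recoding", {
  x <- matrix(c(7, 2, 1, 4), 2, dimnames = list(NULL, c("A", "B")))
  raw <- resp_matrix(x, base = 1L, max_cat = 6L)
  spec_rev <- scale_spec("S", c("A", "B"), reverse = "A")
  once <- apply_coding(raw, spec_rev)
  ## 7 -> 1, 2 -> 6 on item A
  expect_equal(once$responses[, "A"] + 1L, c(1, 6))
  twice <- apply_coding(resp_matrix(once$responses + 1L, base = 1L, max_cat = 6L),
                        spec_rev)
  expect_equal(twice$responses[, "A"], raw$responses[, "A"])
  ## reverse before recode: raw 7 reversed to 1, then merged to category 1
  spec_both <- scale_spec("S", c("A", "B"), reverse = "A",
                          recode = c(1, 2, 2, 3, 3, 4, 4))
  coded <- apply_coding(raw, spec_both)
  expect_equal(coded$responses[, "A"] + 1L, c(1, 4))
})

test_that("coding log replays to reproduce the coded matrix bit-exactly", {
  set.seed(4)
  x <- matrix(sample(1:7, 60, replace = TRUE), 10,
              dimnames = list(NULL, paste0("I", 1:6)))
  raw <- resp_matrix(x, base = 1L, max_cat = 6L)
  spec <- scale_spec("S", paste0("I", 1:6), reverse = c("I2", "I5"),
                     recode = c(1, 2, 2, 3, 3, 4, 4))
  coded <- apply_coding(raw, spec)
  replayed <- replay_coding(raw, coded$coding_log)
  expect_identical(replayed$responses, coded$responses)
  expect_identical(replayed$max_cat, coded$max_cat)
})

test_that("responses outside the declared range are rejected with location", {
  expect_error(resp_matrix(matrix(c(1, 8), 1), base = 1L, max_cat = 6L),
               "out of range.*item")
  expect_error(resp_matrix(matrix(c(1, NA), 1), base = 1L), "missing")
  expect_error(resp_matrix(matrix(c(1, 2.5), 1), base = 1L), "non-integer")
})

test_that("total scores flag exactly the floor and ceiling patterns", {
  x <- resp_matrix(matrix(c(0, 0,
                            1, 1,
                            2, 2), 3, byrow = TRUE,
                          dimnames = list(NULL, c("A", "B"))),
                   base = 0L, max_cat = 2L)
  se <- score_extremes(x)
  expect_equal(se$score, c(0L, 2L, 4L))
  expect_equal(se$extreme, c(TRUE, FALSE, TRUE))
  expect_equal(se$max_score, 4L)
  expect_error(score_extremes(x, character()), "empty item set")
})

test_that("extreme flags are invariant under endpoint-preserving monotone recoding", {
  set.seed(9)
  x <- matrix(sample(1:7, 120, replace = TRUE), 20,
              dimnames = list(NULL, paste0("I", 1:6)))
  raw <- resp_matrix(x, base = 1L, max_cat = 6L)
  plain <- apply_coding(raw, scale_spec("S", paste0("I", 1:6)))
  merged <- apply_coding(raw, scale_spec("S", paste0("I", 1:6),
                                         recode = c(1, 2, 2, 3, 3, 4, 4)))
  expect_equal(score_extremes(plain)$extreme, score_extremes(merged)$extreme)
})

test_that("age grouping uses quartile boundaries with ties to the lower group", {
  age <- c(20, 30, 30, 40, 50, 60, 60, 70)
  g <- age_groups(age)
  br <- attr(g, "breaks")
  expect_length(levels(g), 4L)
  ## persons exactly at a boundary fall in the lower group
  expect_true(all(as.integer(g)[age == br[1]] == 1L))
  expect_true(all(diff(as.integer(g)[order(age)]) >= 0))
})

test_that("matched mixed sampling is deterministic, matched, and avoids extremes", {
  set.seed(11)
  n_gp <- 300; n_cl <- 60
  mk <- function(n, mu) {
    tau <- toy_tau6()[1:4]
    sim <- simulate_responses(n, tau, theta_mean = mu, theta_sd = 1, seed = n + 7)
    cov <- data.frame(gender = factor(sample(c("f", "m"), n, TRUE)),
                      age = sample(18:80, n, TRUE))
    list(responses = sim$responses, covariates = cov)
  }
  gp <- mk(n_gp, -1.5); cl <- mk(n_cl, 0)
  m1 <- build_mixed_sample(gp, cl, seed = 5)
  m2 <- build_mixed_sample(gp, cl, seed = 5)
  expect_identical(m1$gp_rows, m2$gp_rows)
  expect_equal(nrow(m1$responses$responses), 2L * n_cl)
  ## no drawn GP person is extreme on the subscale
  ext <- score_extremes(gp$responses)$extreme
  expect_false(any(ext[m1$gp_rows]))
  ## gender marginals match the clinical sample exactly (no fallbacks here)
  if (!length(m1$match_log)) {
    tg <- table(m1$covariates$gender[m1$covariates$sample == "gp"])
    tc <- table(m1$covariates$gender[m1$covariates$sample == "clinical"])
    expect_equal(as.vector(tg), as.vector(tc))
  }
})
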