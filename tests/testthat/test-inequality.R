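test_that("fractional ranks follow the cumulative-share midpoint rule", {
  fr <- fractional_rank(rep(c("a", "b"), each = 5), rep(1, 10),
                        group_order = c("a", "b"))
  expect_equal(fr$groups$rank, c(0.25, 0.75))
  fr <- fractional_rank(c(rep("a", 2), rep("b", 8)), rep(1, 10),
                        group_order = c("a", "b"))
  expect_equal(fr$groups$rank, c(0.1, 0.6))
  fr1 <- fractional_rank(rep("only", 4), c(1, 2, 3, 4))
  expect_equal(fr1$rank, rep(0.5, 4))
  # population-share-weighted mean rank is exactly one half
  set.seed(10)
  g <- sample(letters[1:5], 200, replace = TRUE)
  w <- rexp(200) + 0.1
  fr <- fractional_rank(g, w)
  expect_equal(sum(w * fr$rank) / sum(w), 0.5, tolerance = 1e-10)
  expect_true(all(diff(fr$groups$rank) > 0))
})

test_that("rank errors name the problem", {
  expect_error(fractional_rank(c("a", NA), c(1, 1)), "unlabelled")
  expect_error(fractional_rank(c("a", "a"), c(1, 1), group_order = c("a", "b")),
               "empty group")
  expect_error(fractional_rank(c("a", "b"), c(1, -1)), "positive")
})

test_that("the concentration index reproduces the two-group hand case", {
  y <- c(rep(1, 1), rep(0, 9), rep(1, 3), rep(0, 7))
  g <- rep(c("least", "most"), each = 10)
  ci <- wagstaff_ci(y, g, group_order = c("least", "most"))
  expect_equal(ci$mu, 0.2)
  expect_equal(ci$raw_ci, 0.25)
  expect_equal(ci$corrected_ci, 0.3125)
  # reversing the social ordering negates the index
  ci_rev <- wagstaff_ci(y, g, group_order = c("most", "least"))
  expect_equal(ci_rev$raw_ci, -ci$raw_ci, tolerance = 1e-12)
  ci_desc <- wagstaff_ci(y, g, group_order = c("least", "most"),
                         direction = "descending")
  expect_equal(ci_desc$corrected_ci, -ci$corrected_ci, tolerance = 1e-12)
})

test_that("equal group prevalences give exactly zero inequality", {
  y <- rep(c(1, 0, 0, 0), 3)
  g <- rep(c("g1", "g2", "g3"), each = 4)
  ci <- wagstaff_ci(y, g, group_order = c("g1", "g2", "g3"))
  expect_equal(ci$raw_ci, 0, tolerance = 1e-12)
})

test_that("grouped computation equals the individual-level oracle", {
  set.seed(31)
  for (i in 1:10) {
    n <- 300
    g <- sample(c("least", "less", "more", "most"), n, replace = TRUE)
    w <- rexp(n) + 0.05
    p <- c(least = 0.1, less = 0.2, more = 0.25, most = 0.4)
    y <- rbinom(n, 1, p[g])
    if (mean(y) %in% c(0, 1)) next
    ord <- c("least", "less", "more", "most")
    ci <- wagstaff_ci(y, g, w, group_order = ord)
    oracle <- ci_oracle(y, g, w, ord)
    expect_equal(ci$raw_ci, oracle$raw, tolerance = 1e-12)
    expect_equal(ci$corrected_ci, oracle$corrected, tolerance = 1e-12)
    # corrected index stays in [-1, 1]; uniform weight rescaling is a no-op
    expect_lte(abs(ci$corrected_ci), 1)
    ci2 <- wagstaff_ci(y, g, w * 13.7, group_order = ord)
    expect_equal(ci2$corrected_ci, ci$corrected_ci, tolerance = 1e-12)
  }
})

test_that("degenerate outcomes are rejected", {
  expect_error(wagstaff_ci(rep(1, 6), rep(c("a", "b"), 3)), "0 or 1")
  expect_error(wagstaff_ci(c(0.5, 1, 0, 1), rep(c("a", "b"), 2)), "binary")
})

test_that("context-driven risks show a positive index and gradient", {
  d <- simulate_survey(sim_config(n_communities = 47, seed = 61))
  f <- gcci(d)
  tab <- risk_gradient_table(d, f$gccs, outcomes = "multiparity")
  expect_gt(tab$wagstaff_ci, 0)
  # inverting the outcome flips the sign (the cesarean-section pattern)
  d$not_multiparity <- !d$multiparity
  tab2 <- risk_gradient_table(d, f$gccs, outcomes = c("multiparity",
                                                      "not_multiparity"))
  expect_lt(tab2$wagstaff_ci[2], 0)
  expect_error(risk_gradient_table(d, f$gccs, outcomes = "age"), "not binary")
})

test_that("index magnitude grows with the generated context effect", {
  ci_at <- function(effect) {
    cfg <- sim_config(n_communities = 80, n_per_community = 150,
                      outcome_context_effect = effect,
                      outcome_residual_community_sd = 0.1, seed = 55)
    d <- simulate_survey(cfg)
    f <- gcci(d)
    risk_gradient_table(d, f$gccs)$wagstaff_ci
  }
  vals <- vapply(c(0, 0.5, 1.2), ci_at, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_lt(abs(vals[1]), 0.12)       # no context effect: index near zero
})
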