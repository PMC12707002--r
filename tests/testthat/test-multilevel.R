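test_that("latent-scale ICC follows the logistic-variance formula", {
  expect_equal(icc_latent(0), 0)
  expect_equal(icc_latent(pi^2 / 3), 0.5)
  expect_equal(icc_latent(0.423), 0.423 / (0.423 + pi^2 / 3))
  expect_equal(round(100 * icc_latent(0.423), 1), 11.4)
  expect_equal(round(100 * icc_latent(0.240), 1), 6.8)
  # strictly increasing in the level-2 variance
  s <- seq(0, 3, by = 0.2)
  expect_true(all(diff(icc_latent(s)) > 0))
  expect_error(icc_latent(-0.1), "nonnegative")
})

test_that("proportional change in variance is the relative reduction", {
  expect_equal(pcv(0.472, 0.472), 0)
  expect_equal(pcv(0.472, 0.240), 100 * (0.472 - 0.240) / 0.472)
  expect_equal(pcv(0.4, 0.1), 75)
  expect_lt(pcv(0.3, 0.45), 0)       # variance can increase
  expect_error(pcv(0, 0.1), "positive")
})

test_that("the likelihood-ratio test uses the chi-square reference", {
  fake <- function(ll, npar) {
    structure(list(logLik = ll, n_par = npar, n = 100,
                   beta = setNames(rep(0, npar - 1),
                                   paste0("b", seq_len(npar - 1)))),
              class = "ml_fit")
  }
  same <- lr_test(fake(-50, 3), fake(-50, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  lr <- lr_test(fake(-51.92, 3), fake(-50, 4))
  expect_equal(lr$statistic, 3.84)
  expect_equal(lr$df, 1)
  expect_equal(lr$p_value, pchisq(3.84, 1, lower.tail = FALSE))
  expect_equal(round(lr$p_value, 2), 0.05)
  bad <- fake(-50, 3)
  bad$n <- 99
  expect_error(lr_test(bad, fake(-49, 4)), "same data")
})

test_that("singleton clusters collapse to ordinary logistic regression", {
  set.seed(9)
  n <- 300
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x))
  d <- data.frame(y = y, x = x, community_id = seq_len(n))
  m <- fit_random_intercept_logit(y ~ x, d, quad_points = 9)
  g <- glm(y ~ x, family = binomial, data = d)
  expect_lt(m$sigma2_u, 1e-4)
  expect_equal(m$logLik, as.numeric(logLik(g)), tolerance = 1e-6)
  expect_equal(unname(m$beta), unname(coef(g)), tolerance = 1e-4)
})

test_that("the quadrature approximation is converged at moderate node counts", {
  set.seed(23)
  J <- 30
  nj <- 40
  u <- rnorm(J, sd = sqrt(0.5))
  d <- data.frame(community_id = rep(1:J, each = nj),
                  x = rnorm(J * nj))
  d$y <- rbinom(nrow(d), 1, plogis(-0.8 + 0.5 * d$x + u[d$community_id]))
  m7 <- fit_random_intercept_logit(y ~ x, d, quad_points = 7)
  m15 <- fit_random_intercept_logit(y ~ x, d, quad_points = 15)
  expect_lt(abs(m7$logLik - m15$logLik), 1e-3)
  expect_equal(m7$sigma2_u, m15$sigma2_u, tolerance = 1e-3)
})

test_that("parameters are recovered on simulated clustered data", {
  set.seed(41)
  J <- 60
  nj <- 60
  u <- rnorm(J, sd = sqrt(0.4))
  d <- data.frame(community_id = rep(1:J, each = nj), x = rnorm(J * nj))
  d$y <- rbinom(nrow(d), 1, plogis(-1 + 0.5 * d$x + u[d$community_id]))
  m <- fit_random_intercept_logit(y ~ x, d, quad_points = 12)
  expect_lt(abs(m$beta[["(Intercept)"]] - (-1)), 3 * m$se[1])
  expect_lt(abs(m$beta[["x"]] - 0.5), 3 * m$se[2])
  expect_lt(abs(m$sigma2_u - 0.4), 0.25)
  expect_true(is.finite(m$sigma2_u_se) && m$sigma2_u_se > 0)
  expect_true(all(m$or$lower < m$or$upper))
  expect_equal(m$or$or, exp(unname(m$beta)))
})

test_that("design problems are reported before fitting", {
  d <- data.frame(y = rbinom(40, 1, 0.5), x = rnorm(40),
                  community_id = rep(1:4, each = 10))
  d$x2 <- 2 * d$x
  expect_error(fit_random_intercept_logit(y ~ x + x2, d), "singular")
  d$yy <- d$x
  expect_error(fit_random_intercept_logit(yy ~ x, d), "binary")
  d1 <- d
  d1$community_id <- 1
  expect_error(fit_random_intercept_logit(y ~ x, d1), "two clusters")
})

test_that("the model ladder decomposes community variance", {
  d <- simulate_survey(sim_config(n_communities = 30, n_per_community = 120,
                                  seed = 71))
  f <- gcci(d)
  lad <- model_ladder(d, f$gccs, quad_points = 5)
  expect_named(lad$fits, c("null", "individual", "individual_gccs"))
  expect_true(all(lad$icc >= 0 & lad$icc < 1))
  expect_equal(unname(lad$pcv["gccs_vs_individual"]),
               pcv(lad$fits$individual$sigma2_u,
                   lad$fits$individual_gccs$sigma2_u))
  expect_equal(lad$lr_23$df,
               lad$fits$individual_gccs$n_par - lad$fits$individual$n_par)
  # the reference level of the ordinal term is the most restrictive category
  gccs_terms <- grep("^gccs", names(lad$fits$individual_gccs$beta), value = TRUE)
  expect_equal(length(gccs_terms), f$gccs$k - 1L)
  top_label <- levels(f$gccs$assignment$label)[f$gccs$k]
  expect_false(any(grepl(top_label, gccs_terms, fixed = TRUE)))
})
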