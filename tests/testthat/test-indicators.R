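test_that("indicator coding rules follow the questionnaire definitions", {
  # married at 17 counts as child marriage
  d <- code_indicators(raw_row(age_first_cohabitation = 17L))
  expect_true(d$child_marriage)
  expect_false(code_indicators(raw_row(age_first_cohabitation = 18L))$child_marriage)

  # sole or joint decider on exactly one decision is NOT "no decision power"
  d <- code_indicators(raw_row(decide_earnings = "husband",
                               decide_health = "joint",
                               decide_purchases = "husband",
                               decide_visits = "other"))
  expect_false(d$no_decision_power)
  d <- code_indicators(raw_row(decide_earnings = "husband",
                               decide_health = "husband",
                               decide_purchases = "other",
                               decide_visits = "husband"))
  expect_true(d$no_decision_power)

  # a single endorsed reason suffices; violence needs an act in the past year
  d <- code_indicators(raw_row(beat_burns_food = TRUE,
                               viol_push = "not_12m", viol_slap = "not_12m"))
  expect_true(d$beating_justifiable)
  expect_false(d$violence_12m)
  d <- code_indicators(raw_row(viol_kick = "sometimes"))
  expect_true(d$violence_12m)

  # education below secondary
  expect_true(code_indicators(raw_row(education_level = "preparatory"))$low_education)
  expect_false(code_indicators(raw_row(education_level = "secondary"))$low_education)
  expect_identical(
    as.character(code_indicators(raw_row(education_level = "university"))$education),
    "university+")
})

test_that("violence responses may be missing only outside the DV subsample", {
  ok <- raw_row(dv_flag = FALSE, viol_push = NA, viol_slap = NA,
                viol_kick = NA, viol_forced_sex = NA)
  expect_true(is.na(code_indicators(ok)$violence_12m))
  bad <- raw_row(viol_push = NA)
  expect_error(code_indicators(bad), "DV subsample")
  expect_error(code_indicators(raw_row(age_first_cohabitation = NA)),
               "age_first_cohabitation")
  expect_error(code_indicators(raw_row()[-2]), "age_first_cohabitation")
})

test_that("weighted community prevalence matches hand computations", {
  d <- micro_frame(rep(c(1, 2), each = 4), rep(1, 8),
                   rep(c(1, 0, 0, 1), 2))
  cp <- community_prevalence(d)
  expect_equal(unname(cp$prevalence[, "child_marriage"]), c(0.5, 0.5))

  d <- micro_frame(c(1, 1, 2, 2), c(3, 1, 1, 1), c(1, 0, 1, 0))
  cp <- community_prevalence(d)
  expect_equal(unname(cp$prevalence[1, "child_marriage"]), 0.75)
  expect_equal(unname(cp$prevalence[2, "child_marriage"]), 0.5)

  d <- micro_frame(rep(1:3, each = 2), rep(1, 6), rep(1, 6))
  expect_true(all(community_prevalence(d)$prevalence == 1))
})

test_that("prevalence is invariant to uniform weight rescaling", {
  d <- simulate_survey(sim_config(n_communities = 6, n_per_community = 50,
                                  seed = 4))
  cp1 <- community_prevalence(d)
  d$survey_weight <- d$survey_weight * 7.3
  d$dv_weight <- d$dv_weight * 7.3
  cp2 <- community_prevalence(d)
  expect_equal(cp1$prevalence, cp2$prevalence, tolerance = 1e-12)
})

test_that("aggregation equals a brute-force per-community loop", {
  d <- simulate_survey(sim_config(n_communities = 7, n_per_community = 35,
                                  seed = 10))
  cp <- community_prevalence(d)
  oracle <- prevalence_oracle(d)
  expect_equal(cp$prevalence, oracle, tolerance = 1e-12)
  # unweighted mode: plain means
  cp_u <- community_prevalence(d, use_weights = FALSE)
  j1 <- d$community_id == d$community_id[1]
  expect_equal(unname(cp_u$prevalence[1, "child_marriage"]),
               mean(d$child_marriage[j1]))
})

test_that("violence prevalence uses only the DV subsample", {
  d <- micro_frame(rep(1:2, each = 4), rep(1, 8), rep(0, 8),
                   indicator = "child_marriage")
  d$dv_flag <- rep(c(TRUE, TRUE, FALSE, FALSE), 2)
  d$dv_weight <- ifelse(d$dv_flag, 2, NA)
  d$violence_12m <- ifelse(d$dv_flag, c(1, 0, NA, NA, 1, 1, NA, NA), NA)
  cp <- community_prevalence(d)
  expect_equal(unname(cp$prevalence[, "violence_12m"]), c(0.5, 1))
  expect_equal(cp$n_dv, c(2L, 2L))

  d$dv_flag[5:6] <- FALSE
  expect_error(community_prevalence(d), "no DV-subsample rows: 2")
})

test_that("community descriptives use the n-1 standard deviation", {
  p <- matrix(0.2, 3, 5, dimnames = list(NULL, gcci_indicators()))
  p[, 1] <- c(0.1, 0.2, 0.6)
  p[, 2] <- c(0.1, 0.3, 0.2)
  cp <- structure(list(community_id = 1:3, prevalence = p,
                       n = rep(10L, 3), n_dv = rep(5L, 3)),
                  class = "community_prevalence")
  tab <- describe_communities(cp)
  expect_equal(tab$sd[1], 0.2645751, tolerance = 1e-6)
  expect_equal(tab$mean[2], 0.2)
  expect_equal(tab$min[2], 0.1)
  expect_equal(tab$max[2], 0.3)
  expect_equal(tab$sd[3], 0)          # constant column
})
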