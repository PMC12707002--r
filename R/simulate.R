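#' Indicator names used throughout the package
#'
#' The five restrictive-context indicators, in their canonical column order:
#' child marriage, no decision-making power, wife-beating justifiable,
#' physical violence in the past 12 months, less than secondary education.
#'
#' @return Character vector of length five.
#' @export
gcci_indicators <- function() {
  c("child_marriage", "no_decision_power", "beating_justifiable",
    "violence_12m", "low_education")
}

#' Configuration for the synthetic survey generator
#'
#' Builds the parameter set for [simulate_survey()].  A single latent
#' community restrictiveness factor \eqn{\eta_j \sim N(0,1)} drives all five
#' indicators on the logit scale; the binary outcome (multiparity, five or
#' more children) carries both an \eqn{\eta_j}-mediated community effect and
#' an independent residual community intercept, so the share of level-2
#' variance the index can explain has a known truth.
#'
#' Defaults emulate a national family-health survey design: 47 communities
#' (strata), roughly 20,500 ever-married women, a half-household
#' domestic-violence subsample, indicator prevalences near
#' (0.21, 0.22, 0.17, 0.11, 0.36) and a total outcome level-2 variance near
#' 0.42 on the latent logit scale.  Indicator intercepts are solved
#' numerically so the marginal prevalence over \eqn{\eta_j} hits
#' `target_prevalence` exactly.
#'
#' @param n_communities Number of communities (strata).
#' @param n_per_community Respondents per community; scalar or a vector of
#'   length `n_communities`.
#' @param target_prevalence Length-5 marginal prevalences used to solve the
#'   indicator intercepts; ignored when `indicator_intercepts` is given.
#' @param indicator_intercepts Optional length-5 logit-scale intercepts
#'   \eqn{a_k}; overrides `target_prevalence`.
#' @param indicator_loadings Length-5 nonnegative logit-scale loadings
#'   \eqn{b_k} of the indicators on \eqn{\eta_j}.
#' @param indicator_noise_sd Optional indicator-specific community noise SD
#'   (a departure from the pure one-factor model); default 0 (off).
#' @param outcome_intercept Logit-scale intercept of the outcome model.
#' @param outcome_covariate_effects Named log-odds for the individual
#'   covariates; see Details for the recognised names.
#' @param outcome_context_effect Log-odds of the outcome per unit of
#'   \eqn{\eta_j} (the index-explainable community effect).
#' @param outcome_residual_community_sd SD of the residual community
#'   intercept \eqn{e_j}, independent of \eqn{\eta_j}.
#' @param dv_subsample_fraction Fraction of respondents per community
#'   assigned to the domestic-violence module.
#' @param seed Integer seed; identical seed and config give a byte-identical
#'   dataset.
#'
#' @details Recognised covariate-effect names: `age` (per year, grand-mean
#'   centered), `education_secondary`, `education_university`,
#'   `wealth_q2` ... `wealth_q5`, `early_married`, `child_death`.  Default
#'   values follow typical odds ratios for multiparity in this literature
#'   (e.g. OR 1.14 per year of age, 2.81 for early marriage, 4.99 for an
#'   experienced child death).  Covariates other than the indicator-derived
#'   education and early-marriage variables are drawn independently of
#'   \eqn{\eta_j}.
#'
#' @return An object of class `"gcci_sim_config"`.
#' @seealso [simulate_survey()]
#' @export
sim_config <- function(n_communities = 47L,
                       n_per_community = 436L,
                       target_prevalence = c(0.21, 0.22, 0.17, 0.11, 0.36),
                       indicator_intercepts = NULL,
                       indicator_loadings = c(0.55, 0.65, 0.80, 0.60, 0.75),
                       indicator_noise_sd = 0,
                       outcome_intercept = -2.5,
                       outcome_covariate_effects = c(
                         age = log(1.14),
                         education_secondary = log(0.84),
                         education_university = log(0.57),
                         wealth_q2 = log(0.81),
                         wealth_q3 = log(0.62),
                         wealth_q4 = log(0.50),
                         wealth_q5 = log(0.41),
                         early_married = log(2.81),
                         child_death = log(4.99)),
                       outcome_context_effect = 0.46,
                       outcome_residual_community_sd = 0.46,
                       dv_subsample_fraction = 0.5,
                       seed = 20210L) {
  if (n_communities < 2L) stop("need at least two communities", call. = FALSE)
  n_per_community <- as.integer(n_per_community)
  if (length(n_per_community) == 1L) {
    n_per_community <- rep(n_per_community, n_communities)
  }
  if (length(n_per_community) != n_communities || any(n_per_community < 1L)) {
    stop("'n_per_community' must be a positive scalar or one count per community",
         call. = FALSE)
  }
  if (length(indicator_loadings) != 5L || any(!is.finite(indicator_loadings)) ||
      any(indicator_loadings < 0)) {
    stop("'indicator_loadings' must be five finite nonnegative values", call. = FALSE)
  }
  if (is.null(indicator_intercepts)) {
    if (length(target_prevalence) != 5L || any(target_prevalence <= 0) ||
        any(target_prevalence >= 1)) {
      stop("'target_prevalence' must be five values in (0, 1)", call. = FALSE)
    }
    indicator_intercepts <- vapply(
      1:5, function(k) marginal_logit_intercept(target_prevalence[k],
                                                indicator_loadings[k]),
      numeric(1))
  }
  if (length(indicator_intercepts) != 5L || any(!is.finite(indicator_intercepts))) {
    stop("'indicator_intercepts' must be five finite values", call. = FALSE)
  }
  stop_if_not_scalar_prob(dv_subsample_fraction, "dv_subsample_fraction")
  if (!is.finite(outcome_intercept) || !is.finite(outcome_context_effect) ||
      !is.finite(outcome_residual_community_sd) ||
      outcome_residual_community_sd < 0 ||
      any(!is.finite(outcome_covariate_effects))) {
    stop("outcome parameters must be finite (residual SD nonnegative)", call. = FALSE)
  }
  structure(list(
    n_communities = as.integer(n_communities),
    n_per_community = n_per_community,
    indicator_intercepts = as.numeric(indicator_intercepts),
    indicator_loadings = as.numeric(indicator_loadings),
    indicator_noise_sd = indicator_noise_sd,
    outcome_intercept = outcome_intercept,
    outcome_covariate_effects = outcome_covariate_effects,
    outcome_context_effect = outcome_context_effect,
    outcome_residual_community_sd = outcome_residual_community_sd,
    dv_subsample_fraction = dv_subsample_fraction,
    seed = as.integer(seed)
  ), class = "gcci_sim_config")
}

#' Simulate survey microdata with a latent community restrictiveness factor
#'
#' Generates one row per ever-married woman: survey design columns
#' (community id, weights, domestic-violence-module flag and weight), raw
#' questionnaire responses sufficient for [code_indicators()], individual
#' covariates, the five coded indicators, and the binary multiparity
#' outcome.  Indicator \eqn{k} in community \eqn{j} is
#' \eqn{\mathrm{Bernoulli}(\mathrm{logit}^{-1}(a_k + b_k \eta_j))};
#' the outcome adds covariate effects, the context effect
#' \eqn{\gamma \eta_j} and a residual community intercept \eqn{e_j}.
#'
#' The physical-violence responses are observed only for rows with
#' `dv_flag = TRUE`; for those rows `dv_weight = survey_weight /`
#' `dv_subsample_fraction` so the subsample reweights to the full population.
#'
#' @param config A [sim_config()] object.
#' @return A `data.frame` with one row per respondent and attributes
#'   `truth` (the latent `eta`, `e` and config used) recording the
#'   generating values.
#' @examples
#' d <- simulate_survey(sim_config(n_communities = 5, n_per_community = 50))
#' table(d$community_id)
#' @export
simulate_survey <- function(config = sim_config()) {
  if (!inherits(config, "gcci_sim_config")) {
    stop("'config' must come from sim_config()", call. = FALSE)
  }
  with_preserved_seed(config$seed, simulate_survey_impl(config))
}

simulate_survey_impl <- function(config) {
  J <- config$n_communities
  nj <- config$n_per_community
  n <- sum(nj)
  community_id <- rep(seq_len(J), nj)

  eta <- stats::rnorm(J)
  e_j <- stats::rnorm(J, sd = config$outcome_residual_community_sd)

  a <- config$indicator_intercepts
  b <- config$indicator_loadings
  ind <- matrix(NA, n, 5L, dimnames = list(NULL, gcci_indicators()))
  for (k in 1:5) {
    lp <- a[k] + b[k] * eta[community_id]
    if (config$indicator_noise_sd > 0) {
      lp <- lp + stats::rnorm(J, sd = config$indicator_noise_sd)[community_id]
    }
    ind[, k] <- stats::rbinom(n, 1L, inv_logit(lp)) == 1L
  }

  # Covariates independent of eta, except education and early marriage which
  # are the indicator variables themselves.
  age <- round(stats::runif(n, 15, 49), 1)
  wealth_quintile <- sample.int(5L, n, replace = TRUE)
  child_death <- stats::rbinom(n, 1L, 0.035) == 1L
  pregnancy_loss <- stats::rbinom(n, 1L, 0.27) == 1L
  survey_weight <- stats::rlnorm(n, meanlog = -0.045, sdlog = 0.3)

  # DV subsample: a fixed random half (fraction) of each community.
  dv_flag <- logical(n)
  for (j in seq_len(J)) {
    rows <- which(community_id == j)
    m <- round(length(rows) * config$dv_subsample_fraction)
    if (m > 0) dv_flag[sample(rows, m)] <- TRUE
  }
  dv_weight <- ifelse(dv_flag, survey_weight / config$dv_subsample_fraction, NA_real_)

  # Raw questionnaire responses consistent with the coded indicators.
  raw <- backfill_raw_responses(ind, dv_flag, age)
  # violence is observed only inside the DV subsample
  ind[!dv_flag, "violence_12m"] <- NA
  age <- raw$age

  eff <- config$outcome_covariate_effects
  education <- raw$education
  lp_out <- config$outcome_intercept +
    eff[["age"]] * (age - mean(age)) +
    eff[["education_secondary"]] * (education == "secondary") +
    eff[["education_university"]] * (education == "university+") +
    eff[["wealth_q2"]] * (wealth_quintile == 2L) +
    eff[["wealth_q3"]] * (wealth_quintile == 3L) +
    eff[["wealth_q4"]] * (wealth_quintile == 4L) +
    eff[["wealth_q5"]] * (wealth_quintile == 5L) +
    eff[["early_married"]] * ind[, "child_marriage"] +
    eff[["child_death"]] * child_death +
    config$outcome_context_effect * eta[community_id] +
    e_j[community_id]
  multiparity <- stats::rbinom(n, 1L, inv_logit(lp_out)) == 1L

  out <- data.frame(
    respondent_id = seq_len(n),
    community_id = community_id,
    survey_weight = survey_weight,
    dv_flag = dv_flag,
    dv_weight = dv_weight,
    age = age,
    wealth_quintile = wealth_quintile,
    child_death = child_death,
    pregnancy_loss = pregnancy_loss,
    raw$responses,
    education = education,
    married_before_18 = unname(ind[, "child_marriage"]),
    as.data.frame(ind),
    multiparity = multiparity,
    stringsAsFactors = FALSE
  )
  attr(out, "truth") <- list(eta = eta, community_residual = e_j, config = config)
  out
}

# Fill raw questionnaire fields so that code_indicators() reproduces the
# generated indicator matrix exactly.  Violence responses exist only for DV
# rows; ages are nudged up where needed so cohabitation cannot precede age.
backfill_raw_responses <- function(ind, dv_flag, age) {
  n <- nrow(ind)
  decision_levels <- c("respondent", "joint", "husband", "other")
  freq_levels <- c("never", "not_12m", "sometimes", "often")

  cohab <- integer(n)
  cm <- ind[, "child_marriage"]
  cohab[cm] <- sample(14:17, sum(cm), replace = TRUE)
  cohab[!cm] <- sample(18:28, sum(!cm), replace = TRUE)
  age <- pmax(age, cohab)

  draw_decision <- function(m, allow_self) {
    pool <- if (allow_self) decision_levels else c("husband", "other")
    sample(pool, m, replace = TRUE)
  }
  nd <- ind[, "no_decision_power"]
  dec <- matrix("", n, 4L)
  dec[nd, ] <- draw_decision(4L * sum(nd), allow_self = FALSE)
  dec[!nd, ] <- draw_decision(4L * sum(!nd), allow_self = TRUE)
  # A "participates in none" row must not contain respondent/joint (already
  # true); a participating row must contain at least one.
  fix <- which(!nd & !apply(dec, 1L, function(r) any(r %in% c("respondent", "joint"))))
  if (length(fix)) {
    dec[cbind(fix, sample.int(4L, length(fix), replace = TRUE))] <-
      sample(c("respondent", "joint"), length(fix), replace = TRUE)
  }

  bj <- ind[, "beating_justifiable"]
  beat <- matrix(FALSE, n, 5L)
  beat[bj, ] <- stats::rbinom(5L * sum(bj), 1L, 0.4) == 1L
  none <- which(bj & rowSums(beat) == 0L)
  if (length(none)) beat[cbind(none, sample.int(5L, length(none), replace = TRUE))] <- TRUE

  vi <- ind[, "violence_12m"]
  viol <- matrix(NA_character_, n, 4L)
  dv_yes <- dv_flag & vi
  dv_no <- dv_flag & !vi
  viol[dv_yes, ] <- sample(freq_levels, 4L * sum(dv_yes), replace = TRUE,
                           prob = c(0.45, 0.15, 0.3, 0.1))
  recent <- which(dv_yes & !apply(viol, 1L, function(r) any(r %in% c("sometimes", "often"))))
  if (length(recent)) {
    viol[cbind(recent, sample.int(4L, length(recent), replace = TRUE))] <-
      sample(c("sometimes", "often"), length(recent), replace = TRUE)
  }
  viol[dv_no, ] <- sample(c("never", "not_12m"), 4L * sum(dv_no), replace = TRUE,
                          prob = c(0.8, 0.2))

  low <- ind[, "low_education"]
  edu_raw <- character(n)
  edu_raw[low] <- sample(c("none", "primary", "preparatory"), sum(low),
                         replace = TRUE, prob = c(0.45, 0.35, 0.2))
  edu_raw[!low] <- sample(c("secondary", "upper_intermediate", "university",
                            "postgraduate"), sum(!low),
                          replace = TRUE, prob = c(0.55, 0.12, 0.28, 0.05))
  education <- factor(
    ifelse(low, "less_than_secondary",
           ifelse(edu_raw %in% c("university", "postgraduate"),
                  "university+", "secondary")),
    levels = c("less_than_secondary", "secondary", "university+"))

  responses <- data.frame(
    age_first_cohabitation = cohab,
    decide_earnings = dec[, 1L], decide_health = dec[, 2L],
    decide_purchases = dec[, 3L], decide_visits = dec[, 4L],
    beat_goes_out = beat[, 1L], beat_neglects = beat[, 2L],
    beat_argues = beat[, 3L], beat_refuses_sex = beat[, 4L],
    beat_burns_food = beat[, 5L],
    viol_push = viol[, 1L], viol_slap = viol[, 2L],
    viol_kick = viol[, 3L], viol_forced_sex = viol[, 4L],
    education_level = edu_raw,
    stringsAsFactors = FALSE
  )
  list(responses = responses, education = education, age = age)
}
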