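#' Random-intercept logistic regression via adaptive quadrature
#'
#' Fits a logistic regression with a cluster-level random intercept by
#' maximising the marginal likelihood with adaptive Gauss-Hermite
#' quadrature (through [lme4::glmer()]).  Returns coefficients on the
#' log-odds scale with Wald standard errors and 95% intervals, the
#' level-2 variance \eqn{\sigma^2_u} with a delta-method standard error
#' (from the numerically differentiated deviance Hessian on the
#' standard-deviation parameterisation), and the log-likelihood.
#'
#' @param formula Fixed-effects formula, e.g. `y ~ age + wealth`.
#' @param data Data frame.
#' @param cluster Name of the cluster (community) id column.
#' @param quad_points Number of adaptive quadrature nodes (default 12).
#' @return Object of class `"ml_fit"`: `beta`, `se`, `or`
#'   (odds ratios with bounds), `sigma2_u`, `sigma2_u_se`, `logLik`,
#'   `n`, `J`, `quad_points`, `formula` and the underlying `glmer` fit.
#' @export
fit_random_intercept_logit <- function(formula, data, cluster = "community_id",
                                       quad_points = 12L) {
  if (!cluster %in% names(data)) {
    stop(sprintf("cluster column '%s' not found", cluster), call. = FALSE)
  }
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  yv <- as.numeric(y)
  if (anyNA(yv) || !all(yv %in% c(0, 1))) {
    stop("outcome must be binary", call. = FALSE)
  }
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) stop("singular design matrix", call. = FALSE)
  J <- length(unique(data[[cluster]]))
  if (J < 2L) stop("need at least two clusters", call. = FALSE)

  f <- stats::as.formula(paste(deparse1(formula), "+ (1 |", cluster, ")"))
  fit <- lme4::glmer(f, data = data, family = stats::binomial(),
                     nAGQ = as.integer(quad_points))

  beta <- lme4::fixef(fit)
  if (any(abs(beta) > 15)) {
    stop("apparent separation: divergent coefficient for ",
         paste(names(beta)[abs(beta) > 15], collapse = ", "), call. = FALSE)
  }
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vc <- lme4::VarCorr(fit)[[cluster]]
  sigma2 <- as.numeric(vc)
  theta <- sqrt(sigma2)

  # SE of sigma^2 by the delta method from the deviance Hessian in
  # (theta, beta); glmer stores this when derivative checks run.
  sigma2_se <- NA_real_
  H <- fit@optinfo$derivs$Hessian
  if (!is.null(H)) {
    V <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(V) && V[1L, 1L] > 0) sigma2_se <- 2 * theta * sqrt(V[1L, 1L])
  }

  structure(list(
    beta = beta,
    se = se,
    or = data.frame(or = exp(beta),
                    lower = exp(beta - 1.96 * se),
                    upper = exp(beta + 1.96 * se)),
    sigma2_u = sigma2,
    sigma2_u_se = sigma2_se,
    logLik = as.numeric(stats::logLik(fit)),
    n_par = attr(stats::logLik(fit), "df"),
    n = nrow(mf),
    J = J,
    quad_points = as.integer(quad_points),
    formula = formula,
    fit = fit
  ), class = "ml_fit")
}

#' @export
print.ml_fit <- function(x, digits = 3, ...) {
  cat("Random-intercept logistic regression (adaptive quadrature, ",
      x$quad_points, " nodes)\n", sep = "")
  cat(sprintf("  n = %d individuals in %d clusters; logLik = %.2f\n",
              x$n, x$J, x$logLik))
  tab <- cbind(beta = x$beta, se = x$se, x$or)
  print(round(tab, digits))
  cat(sprintf("  Level-2 variance %.3f (SE %s); latent-scale ICC %.3f\n",
              x$sigma2_u,
              if (is.na(x$sigma2_u_se)) "NA" else sprintf("%.3f", x$sigma2_u_se),
              icc_latent(x$sigma2_u)))
  invisible(x)
}

#' Marginal log-likelihood of a random-intercept logit at fixed parameters
#'
#' Evaluates the adaptive-quadrature marginal log-likelihood at supplied
#' coefficients and level-2 variance, without optimising.  Useful for
#' checking the quadrature itself: at \eqn{\sigma^2_u = 0} the value must
#' equal the ordinary logistic log-likelihood.
#'
#' @inheritParams fit_random_intercept_logit
#' @param beta Fixed-effect coefficients, in model-matrix column order.
#' @param sigma2_u Level-2 variance at which to evaluate.
#' @return The marginal log-likelihood (a single number).
#' @export
ri_logit_loglik <- function(formula, data, beta, sigma2_u,
                            cluster = "community_id", quad_points = 12L) {
  if (sigma2_u < 0) stop("sigma2_u must be nonnegative", call. = FALSE)
  f <- stats::as.formula(paste(deparse1(formula), "+ (1 |", cluster, ")"))
  parsed <- lme4::glFormula(f, data = data, family = stats::binomial())
  devfun <- do.call(lme4::mkGlmerDevfun, parsed)
  devfun <- lme4::updateGlmerDevfun(devfun, parsed$reTrms,
                                    nAGQ = as.integer(quad_points))
  -devfun(c(sqrt(sigma2_u), beta)) / 2
}

#' Latent-scale intraclass correlation for a logistic random intercept
#'
#' \deqn{ICC = \sigma^2_u / (\sigma^2_u + \pi^2/3)}
#' where \eqn{\pi^2/3} is the variance of the standard logistic
#' distribution, the level-1 residual variance on the latent scale.
#'
#' @param sigma2_u Level-2 (between-cluster) variance, nonnegative.
#' @return The ICC as a proportion in `[0, 1)`.
#' @examples
#' icc_latent(0.423) # ~0.114
#' @export
icc_latent <- function(sigma2_u) {
  if (any(!is.finite(sigma2_u)) || any(sigma2_u < 0)) {
    stop("sigma2_u must be nonnegative", call. = FALSE)
  }
  sigma2_u / (sigma2_u + pi^2 / 3)
}

#' Proportional change in level-2 variance
#'
#' \deqn{PCV = 100\,(\sigma^2_{ref} - \sigma^2_{model}) / \sigma^2_{ref}}
#' the percentage of the reference model's between-cluster variance removed
#' by the richer model's additional terms.
#'
#' @param sigma2_ref Level-2 variance of the reference (smaller) model.
#' @param sigma2_model Level-2 variance of the richer model.
#' @return Percentage (can be negative when variance increases).
#' @export
pcv <- function(sigma2_ref, sigma2_model) {
  if (!is.finite(sigma2_ref) || sigma2_ref <= 0) {
    stop("reference variance must be positive", call. = FALSE)
  }
  100 * (sigma2_ref - sigma2_model) / sigma2_ref
}

#' Likelihood-ratio test between nested random-intercept fits
#'
#' @param fit_restricted,fit_full Nested [fit_random_intercept_logit()]
#'   fits on identical data (the restricted model's fixed effects must be
#'   a subset of the full model's).
#' @return List with `statistic`, `df` and `p_value`.
#' @export
lr_test <- function(fit_restricted, fit_full) {
  stopifnot(inherits(fit_restricted, "ml_fit"), inherits(fit_full, "ml_fit"))
  if (fit_restricted$n != fit_full$n) {
    stop("fits are not on the same data (different n)", call. = FALSE)
  }
  if (!all(names(fit_restricted$beta) %in% names(fit_full$beta))) {
    stop("models are not nested", call. = FALSE)
  }
  df <- fit_full$n_par - fit_restricted$n_par
  if (df < 0) stop("full model has fewer parameters", call. = FALSE)
  stat <- max(0, 2 * (fit_full$logLik - fit_restricted$logLik))
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Three-model random-intercept ladder for a clustered binary outcome
#'
#' Fits the conventional variance-decomposition ladder: Model 1 is the
#' null (intercept-only) random-intercept model; Model 2 adds the
#' individual covariates (age grand-mean centered; education, reference
#' less than secondary; wealth quintile, reference poorest; early
#' marriage; experienced child death); Model 3 adds the ordinal
#' restrictiveness category (reference: most restrictive).  Reports the
#' latent-scale ICC per model, the proportional change in level-2
#' variance of each model against its predecessor, and the likelihood-
#' ratio test of Model 3 against Model 2.
#'
#' @param data Microdata containing the outcome, `community_id`, `age`,
#'   `education`, `wealth_quintile`, `married_before_18` (or
#'   `child_marriage`) and `child_death`.
#' @param gccs A [select_k()] assignment for the same communities.
#' @param outcome Binary outcome column (default `"multiparity"`).
#' @param quad_points Adaptive quadrature nodes (default 12).
#' @return Object of class `"ml_ladder"`: `fits` (list of three
#'   [fit_random_intercept_logit()] objects), `icc`, `pcv` (Model 2 vs 1,
#'   Model 3 vs 2), `lr_23`, and the prepared model frame.
#' @export
model_ladder <- function(data, gccs, outcome = "multiparity", quad_points = 12L) {
  stopifnot(inherits(gccs, "gccs"))
  if (!"married_before_18" %in% names(data) && "child_marriage" %in% names(data)) {
    data$married_before_18 <- data$child_marriage
  }
  needed <- c(outcome, "community_id", "age", "education", "wealth_quintile",
              "married_before_18", "child_death")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("missing covariate column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- data.frame(
    y = as.numeric(data[[outcome]]),
    community_id = data$community_id,
    age_c = data$age - mean(data$age),
    education = data$education,
    wealth = factor(data$wealth_quintile),
    early_married = as.numeric(data$married_before_18),
    child_death = as.numeric(data$child_death)
  )
  idx <- match(d$community_id, gccs$assignment$community_id)
  if (anyNA(idx)) stop("communities missing from the assignment", call. = FALSE)
  lev <- levels(gccs$assignment$label)
  d$gccs <- factor(as.character(gccs$assignment$label[idx]),
                   levels = rev(lev))    # reference = most restrictive

  m1 <- fit_random_intercept_logit(y ~ 1, d, "community_id", quad_points)
  m2 <- fit_random_intercept_logit(
    y ~ age_c + education + wealth + early_married + child_death,
    d, "community_id", quad_points)
  m3 <- fit_random_intercept_logit(
    y ~ age_c + education + wealth + early_married + child_death + gccs,
    d, "community_id", quad_points)

  structure(list(
    fits = list(null = m1, individual = m2, individual_gccs = m3),
    icc = c(null = icc_latent(m1$sigma2_u),
            individual = icc_latent(m2$sigma2_u),
            individual_gccs = icc_latent(m3$sigma2_u)),
    pcv = c(individual_vs_null = pcv(m1$sigma2_u, m2$sigma2_u),
            gccs_vs_individual = pcv(m2$sigma2_u, m3$sigma2_u)),
    lr_23 = lr_test(m2, m3),
    outcome = outcome
  ), class = "ml_ladder")
}

#' @export
print.ml_ladder <- function(x, digits = 3, ...) {
  cat(sprintf("Random-intercept model ladder for '%s'\n\n", x$outcome))
  tab <- data.frame(
    model = c("1: null", "2: individual", "3: individual + GCCS"),
    sigma2_u = vapply(x$fits, function(f) f$sigma2_u, numeric(1)),
    sigma2_u_se = vapply(x$fits, function(f) f$sigma2_u_se, numeric(1)),
    icc_pct = 100 * x$icc,
    minus2LL = vapply(x$fits, function(f) -2 * f$logLik, numeric(1))
  )
  print(cbind(tab[1], round(tab[-1], digits)), row.names = FALSE)
  cat(sprintf("\nPCV: individual vs null %.1f%%; GCCS vs individual %.1f%%\n",
              x$pcv[1], x$pcv[2]))
  cat(sprintf("LR test (Model 3 vs 2): chi-sq %.2f, df %d, p %.3g\n",
              x$lr_23$statistic, x$lr_23$df, x$lr_23$p_value))
  cat("\nModel 3 odds ratios:\n")
  print(round(x$fits$individual_gccs$or, digits))
  invisible(x)
}
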