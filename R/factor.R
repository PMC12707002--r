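#' One-factor principal-factor extraction with regression scoring
#'
#' Fits a single common factor to the community-level indicator prevalences
#' by principal-factor (principal-axis) extraction: the correlation matrix
#' has its diagonal replaced by squared multiple correlations (SMC) and the
#' leading eigenpair of this reduced matrix is retained.  Loadings are
#' \eqn{\sqrt{\lambda_1}\, v_1} with the sign chosen so their sum is
#' positive (higher score = more restrictive); uniqueness is
#' \eqn{1 - \ell_k^2}.  Regression (Thomson) scoring coefficients are
#' \eqn{R^{-1} \ell}.  With a single factor, orthogonal rotation is the
#' identity, so the loadings are reported as the rotated solution.
#'
#' The proportion of variance explained is \eqn{\lambda_1} over the sum of
#' the *positive* eigenvalues of the reduced matrix — the convention of
#' standard principal-factor routines, which makes a strong single factor
#' account for most of the common variance even when its eigenvalue is well
#' below the number of items.
#'
#' @param cp A [community_prevalence()] object, or a numeric matrix of
#'   communities x indicators.
#' @param iterate Re-estimate communalities iteratively (communality =
#'   squared loading, re-extract until convergence).  Off by default: the
#'   non-iterated SMC solution is the common default in survey workflows.
#' @param max_iter,tol Iteration controls when `iterate = TRUE`.
#' @return Object of class `"factor_model"`: correlation matrix, SMC
#'   communalities, eigenvalues of the reduced matrix, loadings, uniqueness,
#'   scoring coefficients, proportion of variance, and the column
#'   means/SDs used for standardization.
#' @export
fit_one_factor <- function(cp, iterate = FALSE, max_iter = 100L, tol = 1e-8) {
  x <- if (inherits(cp, "community_prevalence")) cp$prevalence else as.matrix(cp)
  K <- ncol(x)
  J <- nrow(x)
  if (J <= K) stop("need more communities than indicators", call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) stop("constant prevalence column", call. = FALSE)
  R <- stats::cor(x)
  Rinv <- tryCatch(solve(R), error = function(e) {
    stop("singular correlation matrix", call. = FALSE)
  })
  smc <- 1 - 1 / diag(Rinv)

  extract <- function(h) {
    Rr <- R
    diag(Rr) <- h
    e <- eigen(Rr, symmetric = TRUE)
    lambda1 <- e$values[1L]
    if (lambda1 <= .Machine$double.eps^0.5) {
      stop("degenerate factor solution: leading eigenvalue is not positive",
           call. = FALSE)
    }
    loading <- sqrt(lambda1) * e$vectors[, 1L]
    if (sum(loading) < 0) loading <- -loading
    list(values = e$values, loading = loading)
  }

  h <- smc
  sol <- extract(h)
  if (iterate) {
    for (i in seq_len(max_iter)) {
      h_new <- pmin(sol$loading^2, 1 - 1e-8)
      if (max(abs(h_new - h)) < tol) break
      h <- h_new
      sol <- extract(h)
    }
  }
  loading <- sol$loading
  names(loading) <- colnames(x)
  pos <- sol$values[sol$values > 0]
  if (any(abs(loading) < 0.3)) {
    warning("factor loading(s) below 0.3: ",
            paste(names(loading)[abs(loading) < 0.3], collapse = ", "),
            "; item(s) retained", call. = FALSE)
  }
  structure(list(
    correlation = R,
    smc = smc,
    communalities = h,
    eigenvalues = sol$values,
    retained_eigenvalue = sol$values[1L],
    loadings = loading,
    uniqueness = 1 - loading^2,
    scoring = drop(Rinv %*% loading),
    proportion_of_variance = sol$values[1L] / sum(pos),
    center = colMeans(x),
    scale = sds,
    n = J,
    iterate = iterate
  ), class = "factor_model")
}

#' @export
print.factor_model <- function(x, digits = 3, ...) {
  cat("One-factor principal-factor solution\n")
  tab <- data.frame(loading = x$loadings, uniqueness = x$uniqueness,
                    scoring = x$scoring)
  print(round(tab, digits))
  cat(sprintf("Proportion of variance: %.1f%% (eigenvalue %.3f)\n",
              100 * x$proportion_of_variance, x$retained_eigenvalue))
  invisible(x)
}

#' Score communities on a fitted one-factor model
#'
#' Regression (Thomson) factor scores: prevalences are standardized with
#' the means/SDs stored in the model and multiplied by the scoring
#' coefficients.  Scores have mean zero by construction (when scoring the
#' fitting sample) and variance at most one.
#'
#' @param model A [fit_one_factor()] object.
#' @param cp A [community_prevalence()] object or prevalence matrix with
#'   the same indicator columns the model was fitted on.
#' @return Data frame with `community_id` and `score` (the continuous
#'   index value, higher = more restrictive).
#' @export
score_communities <- function(model, cp) {
  stopifnot(inherits(model, "factor_model"))
  if (inherits(cp, "community_prevalence")) {
    x <- cp$prevalence
    ids <- cp$community_id
  } else {
    x <- as.matrix(cp)
    ids <- if (!is.null(rownames(x))) rownames(x) else seq_len(nrow(x))
  }
  if (ncol(x) != length(model$loadings) ||
      !identical(colnames(x), names(model$loadings))) {
    stop("indicator set does not match the fitted model", call. = FALSE)
  }
  z <- scale(x, center = model$center, scale = model$scale)
  data.frame(community_id = ids, score = drop(z %*% model$scoring),
             row.names = NULL)
}
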