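#' Fit the Gendered Cultural Context Index
#'
#' The central fitting function: from microdata (or a ready community
#' prevalence matrix) it aggregates the five restrictive-context indicator
#' prevalences per community, runs the Cronbach's alpha item analysis,
#' extracts one principal factor with regression scoring to obtain the
#' continuous index (GCCI), and partitions the scores into ordinal
#' restrictiveness categories (GCCS) by exact 1-D k-means with
#' Calinski-Harabasz selection of the number of clusters.
#'
#' @param data Microdata `data.frame` with coded indicators (see
#'   [code_indicators()]), or a [community_prevalence()] object.
#' @param k_range Candidate cluster counts for the ordinal score.
#' @param use_weights Use survey weights when aggregating microdata.
#' @param iterate_communalities Iterate the principal-factor communalities
#'   (see [fit_one_factor()]).
#' @return Object of class `"gcci"`: `prevalence`
#'   ([community_prevalence()]), `alpha` ([cronbach_alpha()]), `model`
#'   ([fit_one_factor()]), `scores` (data frame community_id, score) and
#'   `gccs` ([select_k()]).
#' @examples
#' d <- simulate_survey(sim_config(n_communities = 20, n_per_community = 120,
#'                                 seed = 7))
#' fit <- gcci(d)
#' fit
#' @export
gcci <- function(data, k_range = 3:5, use_weights = TRUE,
                 iterate_communalities = FALSE) {
  cp <- if (inherits(data, "community_prevalence")) {
    data
  } else {
    community_prevalence(data, use_weights = use_weights)
  }
  alpha <- cronbach_alpha(cp$prevalence)
  model <- fit_one_factor(cp, iterate = iterate_communalities)
  scores <- score_communities(model, cp)
  gccs <- select_k(scores, k_range = k_range)
  structure(list(prevalence = cp, alpha = alpha, model = model,
                 scores = scores, gccs = gccs, k_range = k_range),
            class = "gcci")
}

#' @export
print.gcci <- function(x, ...) {
  cat(sprintf("Gendered Cultural Context Index: %d communities\n",
              nrow(x$scores)))
  cat(sprintf("  Cronbach's alpha %.3f; factor explains %.1f%% of variance\n",
              x$alpha$alpha, 100 * x$model$proportion_of_variance))
  cat(sprintf("  Scores: mean %.2g, SD %.3f, range [%.2f, %.2f]\n",
              mean(x$scores$score), stats::sd(x$scores$score),
              min(x$scores$score), max(x$scores$score)))
  cat(sprintf("  Ordinal score: k = %d clusters (pseudo-F %.2f)\n",
              x$gccs$k, max(x$gccs$ch_table$pseudo_F)))
  invisible(x)
}

#' @export
summary.gcci <- function(object, ...) {
  structure(list(fit = object), class = "summary.gcci")
}

#' @export
print.summary.gcci <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nIndicator prevalences across communities:\n")
  print(within(describe_communities(f$prevalence),
               { mean <- round(mean, 3); sd <- round(sd, 3)
                 min <- round(min, 3); max <- round(max, 3) }),
        row.names = FALSE)
  cat("\n")
  print(f$alpha)
  cat("\n")
  print(f$model)
  cat("\n")
  print(f$gccs)
  invisible(x)
}

#' @describeIn gcci Factor loadings and scoring coefficients.
#' @param object,... S3 method arguments.
#' @export
coef.gcci <- function(object, ...) {
  cbind(loading = object$model$loadings,
        uniqueness = object$model$uniqueness,
        scoring = object$model$scoring)
}

#' Score new communities with a fitted index
#'
#' Applies the stored standardization and scoring coefficients to new
#' community prevalences, so communities outside the fitting sample can be
#' placed on the same index scale.
#'
#' @param object A [gcci()] fit.
#' @param newdata A [community_prevalence()] object or prevalence matrix
#'   with the same indicator columns; omitted = fitted scores.
#' @param ... Unused.
#' @return Data frame with `community_id` and `score`.
#' @export
predict.gcci <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  score_communities(object$model, newdata)
}

#' @describeIn gcci Dot plot of community scores coloured by ordinal
#'   category.
#' @param x A `gcci` fit.
#' @export
plot.gcci <- function(x, ...) {
  a <- x$gccs$assignment
  ord <- order(a$score)
  graphics::plot(seq_along(ord), a$score[ord], col = a$cluster[ord],
                 pch = 19, xlab = "community (ranked)",
                 ylab = "index score", ...)
  graphics::legend("topleft", legend = levels(a$label),
                   col = seq_len(x$gccs$k), pch = 19, bty = "n", cex = 0.8)
  invisible(x)
}
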