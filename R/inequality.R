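#' Fractional ranks of ordered social groups
#'
#' Weighted fractional rank for individuals grouped into ordered
#' categories: each group's rank is the cumulative population share of the
#' groups below it plus half its own share, and every member of a group
#' shares that rank.  With groups ordered least to most restrictive the
#' ranks run from 0 towards 1, and the population-share-weighted mean rank
#' is exactly 0.5.
#'
#' @param group Group label per individual (character or factor).
#' @param weights Positive weight per individual.
#' @param group_order Character vector giving the group order (ascending
#'   restrictiveness); defaults to factor levels / sorted unique values.
#' @return Object of class `"ranked_groups"`: `groups` data frame
#'   (group, share, rank in group order) and the per-individual `rank`
#'   vector.
#' @export
fractional_rank <- function(group, weights, group_order = NULL) {
  if (length(group) != length(weights)) stop("length mismatch", call. = FALSE)
  if (anyNA(group)) stop("unlabelled individuals", call. = FALSE)
  if (any(!is.finite(weights) | weights <= 0)) {
    stop("weights must be positive", call. = FALSE)
  }
  if (is.null(group_order)) {
    group_order <- if (is.factor(group)) levels(group) else sort(unique(group))
  }
  g <- factor(group, levels = group_order)
  if (anyNA(g)) stop("group label(s) outside 'group_order'", call. = FALSE)
  wsum <- as.numeric(tapply(weights, g, sum))
  wsum[is.na(wsum)] <- 0
  if (any(wsum == 0)) {
    stop("empty group(s): ",
         paste(group_order[wsum == 0], collapse = ", "), call. = FALSE)
  }
  share <- wsum / sum(wsum)
  rank_g <- cumsum(share) - share / 2
  structure(list(
    groups = data.frame(group = group_order, share = share, rank = rank_g),
    rank = rank_g[as.integer(g)]
  ), class = "ranked_groups")
}

#' Wagstaff concentration index of a binary outcome
#'
#' The concentration index is an adaptation of the Gini coefficient to an
#' ordinal social-group distribution:
#' \deqn{CI = \frac{2}{\mu}\,\mathrm{cov}(y_i, R_i)}
#' with \eqn{y_i} the outcome, \eqn{\mu} its weighted mean and \eqn{R_i}
#' the fractional rank from [fractional_rank()].  For a bounded (binary)
#' outcome the index is corrected by dividing by \eqn{1-\mu} so its
#' attainable range is \eqn{[-1, 1]}.  Covariances are population-weighted
#' (normalised by total weight).
#'
#' Groups are ranked least to most restrictive, so a risk concentrated in
#' the most restrictive communities yields a *positive* index.  Set
#' `direction = "descending"` to reverse the convention (which negates the
#' index).
#'
#' @param y Binary (0/1 or logical) outcome per individual.
#' @param group Ordered group label per individual.
#' @param weights Positive weight per individual.
#' @param group_order Group order, ascending restrictiveness.
#' @param binary_correction Divide by `1 - mu` (default TRUE).
#' @param direction `"ascending"` (default; rank 0 = least restrictive) or
#'   `"descending"`.
#' @param outcome Optional outcome name carried into the result.
#' @return Object of class `"ci_result"`: outcome name, `mu`, `raw_ci`,
#'   `corrected_ci`, and per-group weighted prevalences.
#' @export
wagstaff_ci <- function(y, group, weights = rep(1, length(y)),
                        group_order = NULL, binary_correction = TRUE,
                        direction = c("ascending", "descending"),
                        outcome = deparse(substitute(y))) {
  direction <- match.arg(direction)
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("outcome must be binary with no missing values", call. = FALSE)
  }
  fr <- fractional_rank(group, weights, group_order)
  r <- fr$rank
  if (direction == "descending") r <- 1 - r
  mu <- wmean(y, weights)
  if (mu <= 0 || mu >= 1) {
    stop("concentration index undefined: outcome mean is 0 or 1", call. = FALSE)
  }
  raw <- (2 / mu) * wcov(y, r, weights)
  corrected <- if (binary_correction) raw / (1 - mu) else raw
  g <- factor(group, levels = fr$groups$group)
  prev <- vapply(split(seq_along(y), g), function(i) wmean(y[i], weights[i]),
                 numeric(1))
  structure(list(outcome = outcome, mu = mu, raw_ci = raw,
                 corrected_ci = corrected, group_prevalence = prev,
                 binary_correction = binary_correction,
                 direction = direction),
            class = "ci_result")
}

#' @export
print.ci_result <- function(x, ...) {
  cat(sprintf("Wagstaff concentration index for '%s'\n", x$outcome))
  cat(sprintf("  mean %.4f, raw CI %.4f%s\n", x$mu, x$raw_ci,
              if (x$binary_correction)
                sprintf(", corrected CI %.4f", x$corrected_ci) else ""))
  print(round(x$group_prevalence, 4))
  invisible(x)
}

#' Risk-gradient table: outcome prevalence by restrictiveness category
#'
#' For each binary outcome, the weighted prevalence (in percent) within
#' each ordinal restrictiveness category and the corrected Wagstaff
#' concentration index across categories.  An absolute index above 0.10 is
#' flagged as high inequality (a conventional reporting heuristic, not a
#' test).
#'
#' @param data Microdata with `community_id`, `survey_weight` and the
#'   outcome columns.
#' @param gccs A [select_k()] assignment.
#' @param outcomes Character vector of binary outcome column names.
#' @return Data frame, one row per outcome: prevalence (%) per category,
#'   `wagstaff_ci` (corrected), `high_inequality` flag.
#' @export
risk_gradient_table <- function(data, gccs, outcomes = "multiparity") {
  stopifnot(inherits(gccs, "gccs"))
  missing_cols <- setdiff(c("community_id", "survey_weight", outcomes), names(data))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  idx <- match(data$community_id, gccs$assignment$community_id)
  if (anyNA(idx)) stop("communities missing from the assignment", call. = FALSE)
  lab <- gccs$assignment$label[idx]
  levels_order <- levels(gccs$assignment$label)

  rows <- lapply(outcomes, function(oc) {
    y <- data[[oc]]
    if (anyNA(y) || !all(as.numeric(y) %in% c(0, 1))) {
      stop(sprintf("outcome '%s' is not binary", oc), call. = FALSE)
    }
    ci <- wagstaff_ci(y, lab, data$survey_weight, group_order = levels_order,
                      outcome = oc)
    out <- as.data.frame(as.list(round(100 * ci$group_prevalence, 1)),
                         check.names = FALSE)
    out <- cbind(data.frame(outcome = oc, stringsAsFactors = FALSE), out)
    out$wagstaff_ci <- ci$corrected_ci
    out$high_inequality <- abs(ci$corrected_ci) > 0.10
    out
  })
  do.call(rbind, rows)
}
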