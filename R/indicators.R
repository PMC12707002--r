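#' Code the five restrictive-context indicators from raw responses
#'
#' Applies the standard coding rules to the raw questionnaire columns and
#' appends the five binary indicator columns (see [gcci_indicators()]):
#'
#' * `child_marriage`: first cohabitation before age 18;
#' * `no_decision_power`: the respondent is neither sole nor joint decider
#'   on *any* of the four decisions (husband's earnings, own health care,
#'   major purchases, family visits);
#' * `beating_justifiable`: wife-beating endorsed for *any* of the five
#'   listed reasons;
#' * `violence_12m`: any listed physical-violence act in the past
#'   12 months ("sometimes" or "often"); defined only for the
#'   domestic-violence subsample (`dv_flag`), `NA` elsewhere;
#' * `low_education`: highest schooling below secondary.
#'
#' Missing raw responses outside the domestic-violence design are an error
#' (they are not imputed); the error names the offending field.
#'
#' @param data A `data.frame` of microdata with the raw response columns
#'   produced by [simulate_survey()] (or mapped real data): a `dv_flag`
#'   column, `age_first_cohabitation`, `decide_*`, `beat_*`, `viol_*`,
#'   `education_level`.
#' @return `data` with the five indicator columns (and a 3-level
#'   `education` covariate) added or overwritten.
#' @export
code_indicators <- function(data) {
  decision_cols <- c("decide_earnings", "decide_health", "decide_purchases",
                     "decide_visits")
  beat_cols <- c("beat_goes_out", "beat_neglects", "beat_argues",
                 "beat_refuses_sex", "beat_burns_food")
  viol_cols <- c("viol_push", "viol_slap", "viol_kick", "viol_forced_sex")
  needed <- c("dv_flag", "age_first_cohabitation", decision_cols, beat_cols,
              viol_cols, "education_level")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("missing raw response column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(needed, viol_cols)) {
    if (anyNA(data[[col]])) {
      stop(sprintf("missing values in raw field '%s'", col), call. = FALSE)
    }
  }
  viol <- as.matrix(data[viol_cols])
  if (anyNA(viol[data$dv_flag, ])) {
    stop("missing violence responses inside the DV subsample", call. = FALSE)
  }

  data$child_marriage <- data$age_first_cohabitation < 18
  dec <- as.matrix(data[decision_cols])
  data$no_decision_power <- !apply(dec, 1L, function(r) any(r %in% c("respondent", "joint")))
  data$beating_justifiable <- rowSums(as.matrix(data[beat_cols])) > 0
  v12 <- apply(viol, 1L, function(r) any(r %in% c("sometimes", "often")))
  data$violence_12m <- ifelse(data$dv_flag, v12, NA)
  low_levels <- c("none", "primary", "preparatory")
  high_levels <- c("secondary", "upper_intermediate", "university", "postgraduate")
  bad <- setdiff(unique(data$education_level), c(low_levels, high_levels))
  if (length(bad)) {
    stop("unrecognised education_level value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  data$low_education <- data$education_level %in% low_levels
  data$education <- factor(
    ifelse(data$low_education, "less_than_secondary",
           ifelse(data$education_level %in% c("university", "postgraduate"),
                  "university+", "secondary")),
    levels = c("less_than_secondary", "secondary", "university+"))
  data
}

#' Aggregate indicator prevalences at the community level
#'
#' Computes the (survey-weighted) prevalence of each of the five indicators
#' per community.  The physical-violence column is computed only over
#' domestic-violence-subsample rows using `dv_weight`; all other columns use
#' all rows with `survey_weight`.  With `use_weights = FALSE` plain means
#' are taken instead (violence still restricted to the subsample).
#'
#' @param data Microdata with coded indicator columns (see
#'   [code_indicators()]), `community_id`, `survey_weight`, `dv_flag` and
#'   `dv_weight`.
#' @param use_weights Use survey weights (default) or plain means.
#' @return An object of class `"community_prevalence"`: a list with
#'   `community_id`, the J x 5 `prevalence` matrix, per-community
#'   respondent counts `n` and DV-subsample counts `n_dv`.
#' @export
community_prevalence <- function(data, use_weights = TRUE) {
  ind <- gcci_indicators()
  missing_cols <- setdiff(c("community_id", "survey_weight", "dv_flag",
                            "dv_weight", ind), names(data))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(data$survey_weight <= 0)) stop("survey weights must be positive", call. = FALSE)
  ids <- sort(unique(data$community_id))
  if (length(ids) < 2L) stop("need at least two communities", call. = FALSE)

  g <- factor(data$community_id, levels = ids)
  dv <- data$dv_flag
  no_dv <- ids[tabulate(g[dv], nbins = length(ids)) == 0L]
  if (length(no_dv)) {
    stop("communities with no DV-subsample rows: ", paste(no_dv, collapse = ", "),
         call. = FALSE)
  }

  w_all <- if (use_weights) data$survey_weight else rep(1, nrow(data))
  w_dv <- if (use_weights) data$dv_weight else rep(1, nrow(data))
  if (use_weights && any(is.na(w_dv[dv]) | w_dv[dv] <= 0)) {
    stop("dv_weight must be positive on all DV-subsample rows", call. = FALSE)
  }

  wmean_by <- function(x, w, grp) {
    as.numeric(rowsum(as.numeric(x) * w, grp) / rowsum(w, grp))
  }
  prev <- matrix(NA_real_, length(ids), 5L, dimnames = list(ids, ind))
  for (k in ind) {
    if (k == "violence_12m") {
      prev[, k] <- wmean_by(data[[k]][dv], w_dv[dv], g[dv])
    } else {
      prev[, k] <- wmean_by(data[[k]], w_all, g)
    }
  }
  structure(list(
    community_id = ids,
    prevalence = prev,
    n = as.integer(table(g)),
    n_dv = as.integer(table(g[dv]))
  ), class = "community_prevalence")
}

#' @export
print.community_prevalence <- function(x, ...) {
  cat(sprintf("Community prevalences: %d communities x %d indicators\n",
              nrow(x$prevalence), ncol(x$prevalence)))
  print(utils::head(round(x$prevalence, 3)))
  if (nrow(x$prevalence) > 6L) cat("...\n")
  invisible(x)
}

#' Descriptive summary of community-level indicator prevalences
#'
#' Mean, standard deviation (n-1 denominator), minimum and maximum of each
#' indicator's prevalence across communities.
#'
#' @param cp A [community_prevalence()] object.
#' @return A `data.frame` with one row per indicator.
#' @export
describe_communities <- function(cp) {
  stopifnot(inherits(cp, "community_prevalence"))
  p <- cp$prevalence
  if (nrow(p) < 2L) stop("need at least two communities", call. = FALSE)
  data.frame(
    indicator = colnames(p),
    mean = colMeans(p),
    sd = apply(p, 2L, stats::sd),
    min = apply(p, 2L, min),
    max = apply(p, 2L, max),
    row.names = NULL
  )
}
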