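# Independent oracle implementations used to cross-check package routines.
# These deliberately take the dumbest correct route (loops, expansions).

# Cronbach's alpha straight from the defining variance ratio.
alpha_oracle <- function(x) {
  k <- ncol(x)
  k / (k - 1) * (1 - sum(apply(x, 2, var)) / var(rowSums(x)))
}

# Weighted concentration index computed by an explicit individual-level loop.
ci_oracle <- function(y, group, weights, group_order) {
  shares <- sapply(group_order, function(g) sum(weights[group == g])) / sum(weights)
  rank_g <- numeric(length(group_order))
  below <- 0
  for (i in seq_along(group_order)) {
    rank_g[i] <- below + shares[i] / 2
    below <- below + shares[i]
  }
  r <- rank_g[match(group, group_order)]
  mu <- sum(weights * y) / sum(weights)
  rb <- sum(weights * r) / sum(weights)
  cv <- sum(weights * (y - mu) * (r - rb)) / sum(weights)
  raw <- 2 / mu * cv
  list(raw = raw, corrected = raw / (1 - mu))
}

# Within-cluster SS of the best of `nstart` randomly initialised Lloyd runs.
lloyd_1d_best <- function(x, k, nstart = 100) {
  best <- Inf
  ux <- unique(x)
  for (s in seq_len(nstart)) {
    centers <- sample(ux, k)
    repeat {
      d <- abs(outer(x, centers, "-"))
      cl <- max.col(-d, ties.method = "first")
      new_centers <- centers
      for (c in seq_len(k)) {
        if (any(cl == c)) new_centers[c] <- mean(x[cl == c])
        else new_centers[c] <- sample(ux, 1)     # re-seed empty cluster
      }
      if (max(abs(new_centers - centers)) < 1e-12) break
      centers <- new_centers
    }
    W <- sum((x - centers[cl])^2)
    if (W < best) best <- W
  }
  best
}

# Same contract as lloyd_1d_best but with all restarts advanced in lockstep
# (matrix ops), so large restart counts stay affordable.  Empty clusters are
# re-seeded at a random data point.
lloyd_1d_best_vec <- function(x, k, nstart = 1000, max_iter = 60) {
  n <- length(x)
  centers <- matrix(replicate(nstart, sample(x, k)), k, nstart)
  cl <- matrix(1L, n, nstart)
  dbest <- NULL
  for (iter in seq_len(max_iter)) {
    cl[] <- 1L
    dbest <- abs(outer(x, centers[1, ], "-"))
    if (k > 1) for (c in 2:k) {
      dc <- abs(outer(x, centers[c, ], "-"))
      upd <- dc < dbest
      cl[upd] <- c
      dbest[upd] <- dc[upd]
    }
    new_centers <- centers
    for (c in seq_len(k)) {
      msk <- cl == c
      cnt <- colSums(msk)
      s <- colSums(x * msk)
      new_centers[c, ] <- ifelse(cnt > 0, s / cnt,
                                 x[sample.int(n, nstart, replace = TRUE)])
    }
    done <- max(abs(new_centers - centers)) < 1e-12
    centers <- new_centers
    if (done) break
  }
  min(colSums(dbest^2))
}

# Per-community weighted prevalence by an explicit double loop.
prevalence_oracle <- function(data) {
  ids <- sort(unique(data$community_id))
  ind <- gcci_indicators()
  out <- matrix(NA_real_, length(ids), length(ind),
                dimnames = list(ids, ind))
  for (i in seq_along(ids)) {
    rows <- data[data$community_id == ids[i], ]
    for (k in ind) {
      if (k == "violence_12m") {
        sub <- rows[rows$dv_flag, ]
        out[i, k] <- sum(sub[[k]] * sub$dv_weight) / sum(sub$dv_weight)
      } else {
        out[i, k] <- sum(rows[[k]] * rows$survey_weight) / sum(rows$survey_weight)
      }
    }
  }
  out
}

# Minimal hand-built microdata for indicator-coding tests: one row of raw
# responses with overridable fields.
raw_row <- function(...) {
  base <- list(
    dv_flag = TRUE,
    age_first_cohabitation = 20L,
    decide_earnings = "joint", decide_health = "respondent",
    decide_purchases = "husband", decide_visits = "joint",
    beat_goes_out = FALSE, beat_neglects = FALSE, beat_argues = FALSE,
    beat_refuses_sex = FALSE, beat_burns_food = FALSE,
    viol_push = "never", viol_slap = "never", viol_kick = "never",
    viol_forced_sex = "never",
    education_level = "secondary"
  )
  mods <- list(...)
  base[names(mods)] <- mods
  as.data.frame(base, stringsAsFactors = FALSE)
}

# Small microdata frame with explicit indicator values for aggregation tests.
micro_frame <- function(community_id, weights, values,
                        indicator = "child_marriage") {
  n <- length(community_id)
  d <- data.frame(
    community_id = community_id,
    survey_weight = weights,
    dv_flag = TRUE,
    dv_weight = weights
  )
  for (k in gcci_indicators()) d[[k]] <- values
  d[[indicator]] <- values
  d
}
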