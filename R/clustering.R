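#' Globally optimal one-dimensional k-means
#'
#' Partitions a numeric vector into `k` clusters minimising the within-
#' cluster sum of squares exactly, by dynamic programming over interval
#' splits of the sorted values (optimal 1-D clusters are contiguous
#' intervals).  Deterministic: no starting values, no seed dependence.
#' Ties in the input are kept in input order (stable sort), so equal scores
#' always land in the same cluster regardless of labelling order.
#'
#' @param x Numeric vector.
#' @param k Number of clusters, `2 <= k <=` number of distinct values.
#' @return Integer cluster assignment (same length as `x`), numbered in
#'   ascending order of cluster mean, with attributes `withinss` (total
#'   within-cluster sum of squares) and `centers` (cluster means).
#' @export
kmeans_1d <- function(x, k) {
  n <- length(x)
  k <- as.integer(k)
  if (n < 1L || anyNA(x)) stop("x must be non-missing", call. = FALSE)
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  n_distinct <- length(unique(x))
  if (k > n_distinct) {
    stop(sprintf("k = %d exceeds the number of distinct values (%d)", k, n_distinct),
         call. = FALSE)
  }
  ord <- order(x)                       # stable: ties keep input order
  xs <- x[ord]
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  # within-SS of the sorted segment i..j, O(1) via prefix sums
  seg_ss <- function(i, j) {
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    max(s2 - s^2 / (j - i + 1L), 0)
  }
  D <- matrix(Inf, k, n)
  split_at <- matrix(0L, k, n)
  for (j in seq_len(n)) D[1L, j] <- seg_ss(1L, j)
  if (k > 1L) {
    for (q in 2L:k) {
      for (j in q:n) {
        best <- Inf
        best_i <- q
        for (i in q:j) {
          v <- D[q - 1L, i - 1L] + seg_ss(i, j)
          if (v < best) {
            best <- v
            best_i <- i
          }
        }
        D[q, j] <- best
        split_at[q, j] <- best_i
      }
    }
  }
  # backtrack interval boundaries
  cl_sorted <- integer(n)
  j <- n
  for (q in k:1L) {
    i <- if (q == 1L) 1L else split_at[q, j]
    cl_sorted[i:j] <- q
    j <- i - 1L
  }
  cl <- integer(n)
  cl[ord] <- cl_sorted
  centers <- as.numeric(tapply(x, cl, mean))
  structure(cl, withinss = D[k, n], centers = centers)
}

#' Calinski-Harabasz pseudo-F of a clustering
#'
#' \deqn{CH(k) = \frac{B_k/(k-1)}{W_k/(n-k)}}
#' where \eqn{B_k} is the between-cluster dispersion (cluster-size-weighted
#' squared deviations of cluster means from the grand mean) and \eqn{W_k}
#' the within-cluster dispersion.  \eqn{B_k + W_k} equals the total sum of
#' squares.  Larger values indicate a better partition.
#'
#' @param x Numeric vector of observations.
#' @param cluster Cluster assignment for each observation.
#' @return Object of class `"ch_result"`: list with `k`, `n`, `B`, `W` and
#'   `value` (`Inf`, with a warning, when `W = 0`).
#' @export
ch_pseudo_f <- function(x, cluster) {
  n <- length(x)
  stopifnot(length(cluster) == n)
  cluster <- as.integer(factor(cluster))
  k <- max(cluster)
  if (k <= 1L || k >= n) {
    stop("Calinski-Harabasz requires 1 < k < n", call. = FALSE)
  }
  gm <- mean(x)
  sizes <- tabulate(cluster, nbins = k)
  means <- as.numeric(tapply(x, cluster, mean))
  B <- sum(sizes * (means - gm)^2)
  W <- sum((x - means[cluster])^2)
  value <- if (W <= 0) {
    warning("zero within-cluster dispersion; pseudo-F is infinite", call. = FALSE)
    Inf
  } else {
    (B / (k - 1)) / (W / (n - k))
  }
  structure(list(k = k, n = n, B = B, W = W, value = value),
            class = "ch_result")
}

#' @export
print.ch_result <- function(x, ...) {
  cat(sprintf("CH(%d) = %.2f  (B = %.3f, W = %.3f, n = %d)\n",
              x$k, x$value, x$B, x$W, x$n))
  invisible(x)
}

#' Select the number of clusters and assign ordinal restrictiveness labels
#'
#' Fits the exact 1-D k-means partition for every `k` in `k_range`,
#' computes the Calinski-Harabasz pseudo-F for each, and keeps the `k`
#' with the largest value (smallest such `k` on ties).  Clusters are then
#' labelled in ascending order of mean score; for `k = 4` the conventional
#' vocabulary "least restrictive" < "less restrictive" < "restrictive" <
#' "most restrictive" is used, otherwise "level i of k".
#'
#' @param scores Numeric index scores, or the data frame from
#'   [score_communities()].
#' @param k_range Candidate cluster counts (default 3:5).
#' @param community_id Optional ids (taken from `scores` when it is a
#'   data frame).
#' @return Object of class `"gccs"`: `assignment` data frame
#'   (community_id, score, cluster, ordered factor `label`), `clusters`
#'   summary (size, mean score), `ch_table` of diagnostics per candidate
#'   `k`, and `k` selected.
#' @export
select_k <- function(scores, k_range = 3:5, community_id = NULL) {
  if (is.data.frame(scores)) {
    community_id <- scores$community_id
    scores <- scores$score
  }
  n <- length(scores)
  if (is.null(community_id)) community_id <- seq_len(n)
  n_distinct <- length(unique(scores))
  valid <- k_range[k_range >= 2L & k_range < n & k_range <= n_distinct]
  if (!length(valid)) {
    stop("no valid cluster counts in k_range for these scores", call. = FALSE)
  }
  fits <- lapply(valid, function(k) {
    cl <- kmeans_1d(scores, k)
    list(k = k, cl = cl, ch = ch_pseudo_f(scores, cl))
  })
  ch_values <- vapply(fits, function(f) f$ch$value, numeric(1))
  best <- fits[[which.max(ch_values)]]
  k <- best$k

  cl <- as.integer(best$cl)             # already ordered by cluster mean
  labels <- if (k == 4L) {
    c("least restrictive", "less restrictive", "restrictive", "most restrictive")
  } else {
    sprintf("level %d of %d", seq_len(k), k)
  }
  label <- factor(labels[cl], levels = labels, ordered = TRUE)
  sizes <- tabulate(cl, nbins = k)
  means <- as.numeric(tapply(scores, cl, mean))
  structure(list(
    assignment = data.frame(community_id = community_id, score = scores,
                            cluster = cl, label = label),
    clusters = data.frame(cluster = seq_len(k), label = labels,
                          size = sizes, mean_score = means),
    ch_table = data.frame(
      k = vapply(fits, function(f) f$k, integer(1)),
      pseudo_F = ch_values,
      sizes = vapply(fits, function(f)
        paste(tabulate(as.integer(f$cl), nbins = f$k), collapse = ", "),
        character(1))),
    k = k
  ), class = "gccs")
}

#' @export
print.gccs <- function(x, ...) {
  cat(sprintf("Ordinal restrictiveness score: k = %d selected by pseudo-F\n\n", x$k))
  print(x$ch_table, row.names = FALSE)
  cat("\n")
  print(x$clusters, row.names = FALSE)
  invisible(x)
}
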