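#' Cronbach's alpha item analysis
#'
#' Covariance-based (raw) Cronbach's alpha over the columns of a matrix,
#' with the per-item diagnostics of a standard item analysis: item-test and
#' item-rest correlations, the average interitem covariance among the
#' remaining items, and alpha if the item is deleted.  All variances and
#' covariances use the n-1 denominator.
#'
#' \deqn{\alpha = \frac{K}{K-1}\left(1 - \frac{\sum_k \mathrm{var}(x_k)}
#'   {\mathrm{var}(\sum_k x_k)}\right)}
#'
#' Items whose deletion would increase alpha are flagged, not dropped:
#' retention is a substantive decision (an item can matter for what the
#' scale measures even when it lowers internal consistency).
#'
#' @param x Numeric matrix or data frame, rows = units (communities),
#'   columns = items; at least 3 rows and 2 non-constant columns.
#' @return An object of class `"alpha_report"`: list with `alpha`, the
#'   overall `avg_interitem_cov`, and an `items` data frame
#'   (sign, item-test r, item-rest r, average interitem covariance of the
#'   remaining items, alpha-if-deleted, raises-alpha flag).
#' @examples
#' set.seed(1)
#' f <- rnorm(40)
#' x <- sapply(c(.8, .7, .6), function(l) l * f + rnorm(40, sd = sqrt(1 - l^2)))
#' cronbach_alpha(x)
#' @export
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  K <- ncol(x)
  J <- nrow(x)
  if (K < 2L) stop("need at least two items", call. = FALSE)
  if (J < 3L) stop("need at least three rows", call. = FALSE)
  if (anyNA(x)) stop("missing values are not allowed", call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant item column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("item", seq_len(K))

  S <- stats::cov(x)
  total <- rowSums(x)
  alpha_of <- function(Sm) {
    k <- ncol(Sm)
    k / (k - 1) * (1 - sum(diag(Sm)) / sum(Sm))
  }
  alpha <- alpha_of(S)
  off <- function(Sm) sum(Sm[lower.tri(Sm)]) / (ncol(Sm) * (ncol(Sm) - 1) / 2)

  items <- data.frame(
    item = colnames(x),
    sign = character(K),
    item_test_r = NA_real_,
    item_rest_r = NA_real_,
    avg_interitem_cov = NA_real_,
    alpha_if_deleted = NA_real_,
    raises_alpha = NA,
    stringsAsFactors = FALSE
  )
  for (k in seq_len(K)) {
    rest <- total - x[, k]
    items$item_test_r[k] <- stats::cor(x[, k], total)
    items$item_rest_r[k] <- stats::cor(x[, k], rest)
    items$sign[k] <- if (items$item_test_r[k] >= 0) "+" else "-"
    Sk <- S[-k, -k, drop = FALSE]
    items$avg_interitem_cov[k] <- off(Sk)
    items$alpha_if_deleted[k] <- alpha_of(Sk)
    items$raises_alpha[k] <- items$alpha_if_deleted[k] > alpha
  }
  structure(list(alpha = alpha, avg_interitem_cov = off(S), items = items,
                 n = J, k = K),
            class = "alpha_report")
}

#' @export
print.alpha_report <- function(x, digits = 3, ...) {
  cat(sprintf("Cronbach's alpha item analysis (%d units, %d items)\n\n", x$n, x$k))
  it <- x$items
  it[3:6] <- lapply(it[3:6], round, digits = digits)
  print(it, row.names = FALSE)
  cat(sprintf("\nTest scale: average interitem covariance %.4g, alpha %.3f\n",
              x$avg_interitem_cov, x$alpha))
  if (any(x$items$raises_alpha)) {
    cat("Note: deleting ",
        paste(x$items$item[x$items$raises_alpha], collapse = ", "),
        " would increase alpha.\n", sep = "")
  }
  invisible(x)
}
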