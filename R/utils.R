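# Internal numerical helpers shared across modules.

inv_logit <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

#' @noRd
stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", name), call. = FALSE)
  }
}

# Gauss-Hermite nodes/weights by Golub-Welsch; used for deterministic
# integration over a standard-normal latent variable (calibration only --
# the mixed-model likelihood quadrature lives in lme4).
gauss_hermite <- function(n) {
  i <- seq_len(n - 1L)
  off <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- off
  J[cbind(i + 1L, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = (e$vectors[1L, ]^2)[ord] * sqrt(pi))
}

# E[f(Z)] for Z ~ N(0, 1) by 40-node Gauss-Hermite quadrature.
normal_expectation <- function(f, n_nodes = 40L) {
  gh <- gauss_hermite(n_nodes)
  sum(gh$weights * f(sqrt(2) * gh$nodes)) / sqrt(pi)
}

# Intercept a such that E[inv_logit(a + b * Z)] = p for Z ~ N(0, 1).
marginal_logit_intercept <- function(p, b) {
  stop_if_not_scalar_prob(p, "p")
  if (p <= 0 || p >= 1) stop("target prevalence must be in (0, 1)", call. = FALSE)
  f <- function(a) normal_expectation(function(z) inv_logit(a + b * z)) - p
  stats::uniroot(f, lower = -20, upper = 20, tol = 1e-12)$root
}

# Weighted mean with strictly positive weights.
wmean <- function(x, w) {
  if (any(w <= 0)) stop("weights must be strictly positive", call. = FALSE)
  sum(w * x) / sum(w)
}

# Population-weighted covariance: sum w (x - xbar)(y - ybar) / sum w.
wcov <- function(x, y, w) {
  xb <- wmean(x, w)
  yb <- wmean(y, w)
  sum(w * (x - xb) * (y - yb)) / sum(w)
}

# Evaluate RNG-consuming code under a seed without disturbing the caller's
# stream.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
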