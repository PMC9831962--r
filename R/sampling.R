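#' Power specification for the multiple-regression sample-size analysis
#'
#' @param predictors Number of predictors (shape modes) in the regression.
#' @param rho2 Squared multiple correlation under the alternative.
#' @param alpha Significance level of the test of R^2 = 0.
#' @param power Target power.
#' @return A list of class `power_spec`.
#' @export
power_spec <- function(predictors = 30L, rho2 = 0.15, alpha = 0.05,
                       power = 0.95) {
  check_scalar(predictors, "predictors", lower = 1)
  check_scalar(rho2, "rho2", lower = 1e-12, upper = 1 - 1e-12)
  check_scalar(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  check_scalar(power, "power", lower = 1e-12, upper = 1 - 1e-12)
  structure(list(predictors = as.integer(predictors), rho2 = rho2,
                 alpha = alpha, power = power),
            class = "power_spec")
}

# Density of the squared multiple correlation coefficient R^2 for k random
# (jointly normal) predictors, N observations, population rho^2 (Fisher's
# distribution; Gauss-hypergeometric series summed to convergence).
dR2_random <- function(x, N, k, rho2) {
  vapply(x, function(xx) {
    if (xx <= 0 || xx >= 1) return(0)
    j <- 0; term <- 1; s <- 0
    repeat {
      s <- s + term
      j <- j + 1
      term <- term * ((N - 1) / 2 + j - 1)^2 / ((k / 2 + j - 1) * j) *
        (rho2 * xx)
      if (term < s * 1e-13 || j > 100000) break
    }
    lg <- lgamma((N - 1) / 2) - lgamma(k / 2) - lgamma((N - k - 1) / 2) +
      ((N - 1) / 2) * log1p(-rho2) + (k / 2 - 1) * log(xx) +
      ((N - k - 1) / 2 - 1) * log1p(-xx)
    exp(lg) * s
  }, 0)
}

# Power of the test of R^2 = 0 at sample size n, for either formulation.
regression_power <- function(n, predictors, rho2, alpha,
                             method = c("exact_random", "ncf_fixed")) {
  method <- match.arg(method)
  u <- predictors; v <- n - predictors - 1
  if (v < 1) return(0)
  if (method == "ncf_fixed") {
    f2 <- rho2 / (1 - rho2)
    1 - pf(qf(1 - alpha, u, v), u, v, ncp = f2 * n)
  } else {
    # under H0 the sample R^2 is Beta(k/2, (N-k-1)/2)
    xcrit <- qbeta(1 - alpha, u / 2, v / 2)
    integrate(dR2_random, xcrit, 1, N = n, k = u, rho2 = rho2,
              rel.tol = 1e-10)$value
  }
}

#' Minimum sample size for detecting a squared multiple correlation
#'
#' Smallest `n` at which the test of R^2 = 0 in multiple regression with
#' `predictors` predictors reaches the target power at level `alpha`, given a
#' population squared multiple correlation `rho2`. The default
#' `"exact_random"` method uses the exact distribution of the sample R^2 with
#' jointly-normal random predictors; `"ncf_fixed"` uses the fixed-predictor
#' noncentral-F approximation with noncentrality `f^2 * n`,
#' `f^2 = rho2 / (1 - rho2)`. The search walks upward from the smallest
#' feasible `n = predictors + 2`.
#'
#' @param spec A [power_spec()].
#' @param method `"exact_random"` (default) or `"ncf_fixed"`.
#' @param n_max Search ceiling (error if the target is not reached by then).
#' @return Integer sample size.
#' @export
min_sample_size <- function(spec, method = c("exact_random", "ncf_fixed"),
                            n_max = 100000L) {
  method <- match.arg(method)
  n <- spec$predictors + 2L
  repeat {
    pw <- regression_power(n, spec$predictors, spec$rho2, spec$alpha, method)
    if (pw >= spec$power) return(n)
    n <- n + 1L
    if (n > n_max) stopf("target power %.3f unreachable by n = %d",
                         spec$power, n_max)
  }
}

#' Latin hypercube sample of shape-mode weights
#'
#' Draws `n` synthetic-subject weight vectors over the model's leading
#' `retained` modes. Each column is a stratified sample of the
#' Normal(0, lambda_m) distribution truncated at `+/- sd_range * sqrt(lambda_m)`:
#' `n` equal-probability strata of the truncated distribution, one draw per
#' stratum (inverse CDF of a uniform jitter within each stratum). Under the
#' correlation-minimisation criterion the column pairings are rearranged by
#' an Iman-Conover-style rank permutation toward an identity target
#' correlation, which reduces the maximum absolute pairwise correlation while
#' preserving each column's marginal multiset exactly.
#'
#' @param n Number of samples (>= 2).
#' @param model An `fsu_ssm` (its leading retained modes and eigenvalues set
#'   the column scales), or a numeric vector of eigenvalues.
#' @param sd_range Truncation bound in SD units (default 2).
#' @param criterion `"correlation_min"` (default), `"maximin"` or `"none"`.
#' @param seed RNG seed; the draw is deterministic given the seed.
#' @return A list of class `weight_matrix`: `values` (n x M, raw mm units,
#'   columns `mode_1..mode_M`), `eigenvalues`, `sd_range`, `criterion`,
#'   `seed`.
#' @export
latin_hypercube <- function(n, model, sd_range = 2,
                            criterion = c("correlation_min", "maximin", "none"),
                            seed = 1L) {
  criterion <- match.arg(criterion)
  if (n < 2) stopf("n must be >= 2")
  lam <- if (inherits(model, "fsu_ssm")) {
    model$eigenvalues[seq_len(model$retained)]
  } else {
    as.numeric(model)
  }
  M <- length(lam)
  with_seed(seed, {
    U <- lhs::randomLHS(as.integer(n), M)      # one point per stratum per column
    if (criterion == "maximin" && M > 1) U <- lhs::maximinLHS(as.integer(n), M)
    plo <- pnorm(-sd_range); phi <- pnorm(sd_range)
    W <- vapply(seq_len(M), function(m) {
      qnorm(plo + U[, m] * (phi - plo)) * sqrt(lam[m])
    }, numeric(n))
    W <- matrix(W, nrow = n)
    if (criterion == "correlation_min" && M > 1) W <- iman_conover(W)
  })
  colnames(W) <- paste0("mode_", seq_len(M))
  structure(list(values = W, eigenvalues = lam, sd_range = sd_range,
                 criterion = criterion, seed = as.integer(seed)),
            class = "weight_matrix")
}

# Iman-Conover rearrangement toward an identity rank-correlation target:
# decorrelate van der Waerden scores via Cholesky, then reorder each data
# column to match the ranks of the decorrelated scores. Permutation-only, so
# marginals (and LHS stratification) are preserved exactly.
iman_conover <- function(W) {
  n <- nrow(W); M <- ncol(W)
  if (n <= M + 1) return(W)   # too few samples to decorrelate
  scores <- qnorm(apply(W, 2, rank) / (n + 1))
  C <- cor(scores)
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) return(W)  # degenerate score correlation: leave as drawn
  # decorrelate: S* = S %*% solve(chol(C))
  S_star <- scores %*% solve(ch)
  out <- W
  for (m in seq_len(M)) {
    out[, m] <- sort(W[, m])[rank(S_star[, m], ties.method = "first")]
  }
  out
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf(
    "<weight_matrix> %d samples x %d modes (criterion '%s', +/-%g SD, seed %d)\n",
    nrow(x$values), ncol(x$values), x$criterion, x$sd_range, x$seed))
  cat(sprintf("  max |pairwise r| = %.4f\n", max_abs_cor(x$values)))
  invisible(x)
}

max_abs_cor <- function(W) {
  if (ncol(W) < 2) return(0)
  C <- cor(W); max(abs(C[upper.tri(C)]))
}

#' Convert a weight matrix between raw and SD units
#'
#' Raw weights are multiples of the orthonormal mode vectors (mm scale); SD
#' units divide column `m` by `sqrt(lambda_m)`.
#'
#' @param w A `weight_matrix`.
#' @param model An `fsu_ssm` or eigenvalue vector (defaults to the
#'   eigenvalues stored in `w`).
#' @return A plain matrix in SD units.
#' @export
weights_to_sd_units <- function(w, model = NULL) {
  lam <- if (is.null(model)) w$eigenvalues
         else if (inherits(model, "fsu_ssm")) model$eigenvalues[seq_len(ncol(w$values))]
         else as.numeric(model)
  if (length(lam) != ncol(w$values)) stopf("column count mismatch")
  if (any(lam <= 0)) stopf("zero eigenvalue column: SD units undefined")
  sweep(w$values, 2, sqrt(lam), `/`)
}

#' Write a weight matrix to CSV
#'
#' Columns `mode_1..mode_M` in raw mm units; a comment header records the SD
#' range, criterion and seed.
#'
#' @param w A `weight_matrix`.
#' @param path Output path.
#' @export
write_weights_csv <- function(w, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sd_range=%g criterion=%s seed=%d",
                     w$sd_range, w$criterion, w$seed), con)
  utils::write.csv(as.data.frame(w$values), con, row.names = FALSE)
  invisible(path)
}
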