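#' Per-mode correlation map between mode weights and outcomes
#'
#' Pearson's linear and Spearman's rank correlation of every shape-mode
#' weight column against every outcome, with two-sided p-values from the
#' t-transform (`df = n - 2`); Spearman uses average ranks (tie-corrected
#' via the Pearson correlation of ranks). Subjects with invalid simulations
#' are dropped listwise first. Constant columns yield `NA` correlations
#' (undefined, not zero).
#'
#' @param weights A `weight_matrix`, or a plain numeric matrix.
#' @param outcomes A data frame with outcome columns (e.g. `idp`, `fcp`) and
#'   optionally `valid`; rows align with weight rows.
#' @param outcome_cols Outcome column names (default all numeric columns
#'   except bookkeeping ones).
#' @param significance_level Two-sided significance threshold (default 0.05).
#' @return A tibble: `mode`, `outcome`, `pearson_r`, `pearson_p`,
#'   `spearman_rho`, `spearman_p`, `significant` (Pearson p below level).
#' @export
correlation_map <- function(weights, outcomes, outcome_cols = NULL,
                            significance_level = 0.05) {
  W <- if (inherits(weights, "weight_matrix")) weights$values else as.matrix(weights)
  outcomes <- as.data.frame(outcomes)
  if (nrow(outcomes) != nrow(W)) stopf("row count mismatch")
  if (!is.null(outcomes$valid)) {
    keep <- which(outcomes$valid)
    W <- W[keep, , drop = FALSE]
    outcomes <- outcomes[keep, , drop = FALSE]
  }
  if (nrow(W) < 4) stopf("need at least 4 valid subjects")
  if (is.null(outcome_cols)) {
    outcome_cols <- setdiff(names(outcomes)[vapply(outcomes, is.numeric, TRUE)],
                            c("valid"))
  }
  n <- nrow(W)
  p_from_r <- function(r) {
    if (is.na(r) || abs(r) >= 1) return(if (is.na(r)) NA_real_ else 0)
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tval), df = n - 2)
  }
  modes <- colnames(W) %||% paste0("mode_", seq_len(ncol(W)))
  rows <- list()
  for (m in seq_len(ncol(W))) {
    for (oc in outcome_cols) {
      y <- outcomes[[oc]]
      if (sd(W[, m]) == 0 || sd(y) == 0) {
        r <- rho <- NA_real_
      } else {
        r <- cor(W[, m], y)
        rho <- cor(rank(W[, m]), rank(y))   # average ranks, tie-corrected
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        mode = modes[m], outcome = oc,
        pearson_r = r, pearson_p = p_from_r(r),
        spearman_rho = rho, spearman_p = p_from_r(rho))
    }
  }
  out <- dplyr::bind_rows(rows)
  out$significant <- !is.na(out$pearson_p) & out$pearson_p <= significance_level
  attr(out, "n") <- n
  attr(out, "significance_level") <- significance_level
  out
}

#' Kernel SHAP configuration
#'
#' @param n_coalitions Number of feature coalitions to include (default
#'   1024), capped at `2^M`. Coalition cardinalities are enumerated in
#'   descending Shapley-kernel weight (highest and lowest cardinalities
#'   first); a partially included cardinality is sampled uniformly, seeded.
#' @param background Reference feature vector for absent features (default:
#'   column means of the data).
#' @param seed RNG seed for partial-cardinality sampling.
#' @return A list of class `shap_config`.
#' @export
shap_config <- function(n_coalitions = 1024L, background = NULL, seed = 1L) {
  check_scalar(n_coalitions, "n_coalitions", lower = 1)
  structure(list(n_coalitions = as.integer(n_coalitions),
                 background = background, seed = as.integer(seed),
                 surrogate = "linear_regression"),
            class = "shap_config")
}

# enumerate coalition matrix Z (rows = coalitions, cols = features) in
# descending Shapley-kernel weight order, up to n_coalitions rows
shap_coalitions <- function(M, n_coalitions, seed = 1L) {
  sizes <- seq_len(M - 1)
  kw <- (M - 1) / (choose(M, sizes) * sizes * (M - sizes))
  ord <- order(kw, decreasing = TRUE)
  Z <- matrix(integer(0), 0, M)
  wts <- numeric(0)
  budget <- n_coalitions
  with_seed(seed, {
    for (s in sizes[ord]) {
      ncs <- choose(M, s)
      if (budget <= 0) break
      if (ncs <= budget) {
        combs <- utils::combn(M, s)
        zz <- matrix(0L, ncol(combs), M)
        for (k in seq_len(ncol(combs))) zz[k, combs[, k]] <- 1L
      } else {
        # sample distinct coalitions of this cardinality uniformly
        seen <- new.env(hash = TRUE)
        zz <- matrix(0L, budget, M)
        k <- 0L
        while (k < budget) {
          idx <- sort(sample.int(M, s))
          key <- paste(idx, collapse = ",")
          if (is.null(seen[[key]])) {
            seen[[key]] <- TRUE
            k <- k + 1L
            zz[k, idx] <- 1L
          }
        }
      }
      Z <- rbind(Z, zz)
      wts <- c(wts, rep(kw[s], nrow(zz)))
      budget <- budget - nrow(zz)
    }
  })
  list(Z = Z, weights = wts)
}

#' Kernel SHAP values on a linear regression surrogate
#'
#' Fits an ordinary least-squares surrogate of the outcome on the mode
#' weights, then estimates per-subject Shapley values by the Kernel SHAP
#' weighted least squares: coalitions are weighted by the Shapley kernel
#' `(M-1) / (choose(M,s) * s * (M-s))`, enumerated in descending weight
#' (extreme cardinalities first) up to the coalition budget; absent features
#' are replaced by the background value; the local-accuracy constraint
#' `sum(phi) = f(x) - f(background)` is imposed exactly.
#'
#' @param weights n x M matrix (or `weight_matrix`) of mode weights.
#' @param outcome Numeric outcome vector of length n.
#' @param config A [shap_config()].
#' @return An n x M matrix of Shapley values, with attributes `background`,
#'   `f_background`, `surrogate_coefficients`.
#' @export
kernel_shap <- function(weights, outcome, config = shap_config()) {
  X <- if (inherits(weights, "weight_matrix")) weights$values else as.matrix(weights)
  y <- as.numeric(outcome)
  n <- nrow(X); M <- ncol(X)
  if (length(y) != n) stopf("outcome length mismatch")
  if (n <= M) stopf("need n > M observations to fit the linear surrogate")
  if (M > 1 && config$n_coalitions < M + 2) {
    stopf("n_coalitions = %d is underdetermined for M = %d (need >= M + 2)",
          config$n_coalitions, M)
  }
  fit <- lm(y ~ X)
  beta0 <- coef(fit)[1]
  beta <- coef(fit)[-1]
  beta[is.na(beta)] <- 0
  bg <- config$background %||% colMeans(X)
  f_bg <- beta0 + sum(beta * bg)
  f_x <- beta0 + as.numeric(X %*% beta)
  delta <- f_x - f_bg                       # per subject

  if (M == 1) {
    phi <- matrix(delta, ncol = 1)
  } else {
    n_coal <- min(config$n_coalitions, 2^M - 2)
    co <- shap_coalitions(M, n_coal, seed = config$seed)
    Z <- co$Z; w <- co$weights
    # surrogate value of masked input minus baseline, all subjects at once:
    # y_z[c, i] = sum_{j in z_c} beta_j (x_ij - bg_j)
    C <- sweep(X, 2, bg) * rep(beta, each = n)      # n x M contributions
    Yz <- Z %*% t(C)                                # n_coal x n
    A <- crossprod(Z, Z * w)                        # M x M
    Bv <- crossprod(Z, Yz * w)                      # M x n
    # constrained WLS via Lagrange bordered system
    ones <- rep(1, M)
    KKT <- rbind(cbind(A, ones), c(ones, 0))
    rhs <- rbind(Bv, delta)
    sol <- solve(KKT, rhs)
    phi <- t(sol[seq_len(M), , drop = FALSE])
  }
  colnames(phi) <- colnames(X) %||% paste0("mode_", seq_len(M))
  attr(phi, "background") <- bg
  attr(phi, "f_background") <- f_bg
  attr(phi, "surrogate_coefficients") <- c(intercept = unname(beta0), beta)
  attr(phi, "f_x") <- f_x
  phi
}

#' Normalised mean absolute Shapley contributions
#'
#' Mean over subjects of the absolute Shapley value per mode, normalised to
#' sum to 100 percent.
#'
#' @param shap_values n x M matrix from [kernel_shap()].
#' @return A tibble: `mode`, `contribution_pct`, `rank`.
#' @export
contribution_percentages <- function(shap_values) {
  avg <- colMeans(abs(shap_values))
  tot <- sum(avg)
  if (tot == 0) {
    out <- tibble::tibble(mode = colnames(shap_values),
                          contribution_pct = NA_real_,
                          rank = NA_integer_)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  pct <- 100 * avg / tot
  tibble::tibble(mode = colnames(shap_values) %||% paste0("mode_", seq_along(pct)),
                 contribution_pct = as.numeric(pct),
                 rank = as.integer(rank(-pct, ties.method = "first")))
}

#' Importance cutoff by the largest relative drop in contributions
#'
#' Sorts contributions in descending order and finds, within the top-`window`
#' ranks, the largest consecutive relative drop (the smallest ratio of the
#' next contribution to the current one). Modes before the drop are deemed
#' important. If no ratio falls below `drop_threshold` (e.g. uniform
#' contributions) the important set is empty and flagged.
#'
#' @param percentages Tibble from [contribution_percentages()], or a numeric
#'   vector of contributions.
#' @param window Number of leading ranks searched for the drop (default 8).
#' @param drop_threshold A consecutive ratio must fall below this value to
#'   count as a drop (default 0.8).
#' @return Character (or integer) vector of important modes, with attribute
#'   `no_drop` = TRUE when the set is empty.
#' @export
importance_cutoff <- function(percentages, window = 8L, drop_threshold = 0.8) {
  if (is.data.frame(percentages)) {
    vals <- percentages$contribution_pct
    ids <- percentages$mode
  } else {
    vals <- as.numeric(percentages)
    ids <- names(percentages) %||% seq_along(vals)
  }
  if (length(vals) < 2) stopf("need at least 2 modes")
  ord <- order(vals, decreasing = TRUE)
  v <- vals[ord]
  kmax <- min(window, length(v) - 1L)
  ratio <- vapply(seq_len(kmax), function(i) {
    if (v[i] <= 0) 1 else max(v[i + 1], 0) / v[i]
  }, 0)
  if (all(ratio >= drop_threshold)) {
    out <- ids[integer(0)]
    attr(out, "no_drop") <- TRUE
    return(out)
  }
  cut <- which.min(ratio)               # ties.min -> smaller set
  out <- ids[ord[seq_len(cut)]]
  attr(out, "no_drop") <- FALSE
  out
}

#' Full shape-mode sensitivity report
#'
#' Correlation map, kernel SHAP contributions, importance ranks and the
#' drop-based important set for each outcome, on the valid subjects only.
#' SHAP runs on SD-unit weights (scale-free); this is recorded in the
#' report metadata.
#'
#' @param weights A `weight_matrix`.
#' @param outcomes Tibble from [batch_simulate()] (columns `idp`, `fcp`,
#'   `valid`).
#' @param config A [shap_config()].
#' @param significance_level Correlation significance threshold.
#' @param outcome_cols Outcome columns to analyse.
#' @return A list of class `sensitivity_report`: `correlations` (tibble),
#'   `contributions` (tibble: outcome, mode, contribution_pct, rank),
#'   `important` (named list of mode sets), `shap_values` (named list of
#'   matrices), `meta`.
#' @export
sensitivity_report <- function(weights, outcomes, config = shap_config(),
                               significance_level = 0.05,
                               outcome_cols = c("idp", "fcp")) {
  outcomes <- as.data.frame(outcomes)
  keep <- if (!is.null(outcomes$valid)) which(outcomes$valid)
          else seq_len(nrow(outcomes))
  W_sd <- weights_to_sd_units(weights)
  corr <- correlation_map(weights, outcomes, outcome_cols = outcome_cols,
                          significance_level = significance_level)
  shap_list <- list(); contrib_rows <- list(); important <- list()
  for (oc in outcome_cols) {
    phi <- kernel_shap(W_sd[keep, , drop = FALSE], outcomes[[oc]][keep], config)
    shap_list[[oc]] <- phi
    pct <- contribution_percentages(phi)
    contrib_rows[[oc]] <- dplyr::mutate(pct, outcome = oc, .before = 1)
    important[[oc]] <- importance_cutoff(pct)
  }
  structure(
    list(correlations = corr,
         contributions = dplyr::bind_rows(contrib_rows),
         important = important,
         shap_values = shap_list,
         meta = list(n_valid = length(keep),
                     n_total = nrow(outcomes),
                     weight_units = "sd",
                     n_coalitions = config$n_coalitions,
                     significance_level = significance_level)),
    class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> %d/%d valid subjects\n",
              x$meta$n_valid, x$meta$n_total))
  top <- dplyr::slice_min(dplyr::group_by(x$contributions, .data$outcome),
                          order_by = .data$rank, n = 3)
  print(as.data.frame(top))
  for (oc in names(x$important)) {
    cat(sprintf("  important (%s): %s\n", oc,
                paste(x$important[[oc]], collapse = ", ")))
  }
  invisible(x)
}
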