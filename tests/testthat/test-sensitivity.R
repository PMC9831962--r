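test_that("perfect linear dependence gives r = rho = 1 with tiny p", {
  set.seed(1)
  W <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("mode_1", "mode_2")))
  out <- data.frame(idp = 2 * W[, 1], valid = TRUE)
  cm <- correlation_map(W, out, outcome_cols = "idp")
  row1 <- cm[cm$mode == "mode_1", ]
  expect_equal(row1$pearson_r, 1, tolerance = 1e-12)
  expect_equal(row1$spearman_rho, 1, tolerance = 1e-12)
  expect_lt(row1$pearson_p, 1e-12)
  expect_true(row1$significant)
})

test_that("monotone nonlinear response: rho = 1 while r < 1", {
  set.seed(2)
  W <- matrix(rnorm(40), 40, 1, dimnames = list(NULL, "mode_1"))
  out <- data.frame(idp = W[, 1]^3)
  cm <- correlation_map(W, out, outcome_cols = "idp")
  expect_equal(cm$spearman_rho, 1, tolerance = 1e-12)
  expect_lt(cm$pearson_r, 1 - 1e-6)
})

test_that("correlations and p-values match longhand formulas on a 12-row table", {
  set.seed(3)
  W <- matrix(rnorm(12), 12, 1, dimnames = list(NULL, "mode_1"))
  y <- 0.6 * W[, 1] + rnorm(12, sd = 0.8)
  cm <- correlation_map(W, data.frame(idp = y), outcome_cols = "idp")
  n <- 12
  r <- sum((W[, 1] - mean(W)) * (y - mean(y))) /
    sqrt(sum((W[, 1] - mean(W))^2) * sum((y - mean(y))^2))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tval), n - 2)
  expect_equal(cm$pearson_r, r, tolerance = 1e-12)
  expect_equal(cm$pearson_p, p, tolerance = 1e-12)
  rk_w <- rank(W[, 1]); rk_y <- rank(y)
  rho <- sum((rk_w - mean(rk_w)) * (rk_y - mean(rk_y))) /
    sqrt(sum((rk_w - mean(rk_w))^2) * sum((rk_y - mean(rk_y))^2))
  expect_equal(cm$spearman_rho, rho, tolerance = 1e-12)
  # cross-check against the standard library implementation
  ct <- cor.test(W[, 1], y)
  expect_equal(cm$pearson_r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(cm$pearson_p, ct$p.value, tolerance = 1e-10)
})

test_that("constant columns are reported as undefined, not zero", {
  W <- cbind(mode_1 = rep(1, 10), mode_2 = rnorm(10))
  out <- data.frame(idp = rnorm(10))
  cm <- correlation_map(W, out, outcome_cols = "idp")
  expect_true(is.na(cm$pearson_r[cm$mode == "mode_1"]))
  expect_false(cm$significant[cm$mode == "mode_1"])
})

test_that("invalid subjects are dropped listwise", {
  set.seed(4)
  W <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("mode_1", "mode_2")))
  out <- data.frame(idp = 2 * W[, 1], valid = rep(c(TRUE, FALSE), 10))
  out$idp[!out$valid] <- 99               # garbage that must be ignored
  cm <- correlation_map(W, out, outcome_cols = "idp")
  expect_equal(attr(cm, "n"), 10)
  expect_equal(cm$pearson_r[cm$mode == "mode_1"], 1, tolerance = 1e-12)
})

test_that("single-feature SHAP equals f(x) - f(background) exactly", {
  set.seed(5)
  x <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "mode_1"))
  y <- 1.5 + 2 * x[, 1] + rnorm(30, sd = 0.1)
  phi <- kernel_shap(x, y, shap_config(n_coalitions = 4))
  fit <- lm(y ~ x)
  f_x <- fitted(fit)
  f_bg <- coef(fit)[1] + coef(fit)[2] * mean(x)
  expect_equal(phi[, 1], unname(f_x - f_bg), tolerance = 1e-9)
})

test_that("kernel SHAP matches the closed-form linear attribution", {
  set.seed(6)
  n <- 80; M <- 6
  X <- matrix(rnorm(n * M), n, M, dimnames = list(NULL, paste0("mode_", 1:M)))
  beta <- c(2, -1, 0.5, 0, 0.25, -0.75)
  y <- 1 + X %*% beta + rnorm(n, sd = 0.05)
  phi <- kernel_shap(X, y, shap_config(n_coalitions = 2^M))
  bhat <- coef(lm(y ~ X))[-1]
  bg <- colMeans(X)
  oracle <- sweep(X, 2, bg) * rep(bhat, each = n)
  expect_equal(unname(phi[, ]), unname(oracle), tolerance = 1e-6)
})

test_that("truncated coalition budgets still satisfy local accuracy", {
  set.seed(7)
  n <- 50; M <- 8
  X <- matrix(rnorm(n * M), n, M)
  y <- X %*% rnorm(M) + rnorm(n, sd = 0.1)
  phi <- kernel_shap(X, y, shap_config(n_coalitions = 40, seed = 3))
  f_x <- attr(phi, "f_x")
  f_bg <- attr(phi, "f_background")
  expect_equal(rowSums(phi), unname(f_x - f_bg), tolerance = 1e-6)
  expect_error(kernel_shap(X, y, shap_config(n_coalitions = 5)),
               "underdetermined")
})

test_that("kernel SHAP agrees with brute-force Shapley enumeration at M = 5", {
  set.seed(8)
  n <- 40; M <- 5
  X <- matrix(rnorm(n * M), n, M)
  y <- X %*% c(1.2, -0.6, 0.3, 0.9, -0.2) + rnorm(n, sd = 0.05)
  fit <- lm(y ~ X)
  b0 <- coef(fit)[1]; b <- coef(fit)[-1]
  bg <- colMeans(X)
  fval <- function(x, S) {
    xx <- bg; xx[S] <- x[S]
    b0 + sum(b * xx)
  }
  # direct Shapley sum over all subsets of the other features
  shap_direct <- function(x) {
    vapply(1:M, function(j) {
      others <- setdiff(1:M, j)
      tot <- 0
      for (k in 0:length(others)) {
        subs <- if (k == 0) list(integer(0)) else
          asplit(utils::combn(others, k), 2)
        wgt <- factorial(k) * factorial(M - k - 1) / factorial(M)
        for (S in subs) {
          tot <- tot + wgt * (fval(x, c(S, j)) - fval(x, S))
        }
      }
      tot
    }, 0)
  }
  phi <- kernel_shap(X, y, shap_config(n_coalitions = 2^M))
  for (i in c(1, 17, 40)) {
    expect_equal(unname(phi[i, ]), shap_direct(X[i, ]), tolerance = 1e-6)
  }
})

test_that("contribution percentages normalise to 100 with sane ranks", {
  set.seed(9)
  phi <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("mode_", 1:3)))
  pct <- contribution_percentages(phi)
  expect_equal(sum(pct$contribution_pct), 100, tolerance = 1e-6)
  expect_setequal(pct$rank, 1:3)
  only1 <- matrix(0, 20, 3, dimnames = list(NULL, paste0("mode_", 1:3)))
  only1[, 1] <- rnorm(20)
  p1 <- contribution_percentages(only1)
  expect_equal(p1$contribution_pct, c(100, 0, 0))
  zero <- contribution_percentages(matrix(0, 5, 2,
                                          dimnames = list(NULL, c("a", "b"))))
  expect_true(isTRUE(attr(zero, "degenerate")))
})

test_that("importance cutoff finds the dominant drop", {
  expect_equal(importance_cutoff(c(a = 40, b = 30, c = 5, d = 5, e = 20)),
               c("a", "b", "e"), ignore_attr = TRUE)
  expect_equal(importance_cutoff(c(m1 = 40, m2 = 30, m3 = 5, m4 = 5)),
               c("m1", "m2"), ignore_attr = TRUE)
  v <- c(17, 8, 6, 5, 1.5, 1.4, 1.2, 1.0, 0.8)
  names(v) <- paste0("m", 1:9)
  # enumerate consecutive ratios: the drop after rank 4 dominates
  ratios <- v[-1] / v[-9]
  expect_equal(which.min(ratios[1:8]), 4L, ignore_attr = TRUE)
  expect_equal(importance_cutoff(v), paste0("m", 1:4), ignore_attr = TRUE)
  uni <- importance_cutoff(rep(12.5, 8))
  expect_length(uni, 0)
  expect_true(attr(uni, "no_drop"))
  expect_error(importance_cutoff(5), "at least 2")
})

test_that("phantom cohort analysis recovers the true importance ordering", {
  # analytic outcomes on a large phantom cohort: SHAP ranking should match
  # the ground-truth contribution ranking for the leading modes
  sp <- phantom_spec(t = 400, noise_sd = 0.02, size_sd = 0, seed = 31)
  co <- generate_cohort(sp)
  resp <- t(vapply(co$shapes, function(s) unlist(true_response(s, co$truth)),
                   numeric(2)))
  W <- co$truth$latent_weights
  colnames(W) <- paste0("mode_", 1:4)
  for (o in c("idp", "fcp")) {
    phi <- kernel_shap(W, resp[, o], shap_config(n_coalitions = 16))
    pct <- contribution_percentages(phi)
    truth_rank <- co$truth$true_importance_ranking[[o]]
    expect_equal(pct$mode[pct$rank == 1], paste0("mode_", truth_rank[1]))
    expect_equal(pct$mode[pct$rank == 2], paste0("mode_", truth_rank[2]))
  }
})

test_that("linear responses give nearly equal Pearson and Spearman", {
  sp <- phantom_spec(t = 500, noise_sd = 0.05, size_sd = 0, seed = 33)
  co <- generate_cohort(sp)
  resp <- vapply(co$shapes, function(s) true_response(s, co$truth)$idp, 0)
  W <- co$truth$latent_weights
  colnames(W) <- paste0("mode_", 1:4)
  cm <- correlation_map(W, data.frame(idp = resp), outcome_cols = "idp")
  gap <- abs(cm$pearson_r - cm$spearman_rho)
  expect_true(all(gap[abs(cm$pearson_r) > 0.1] < 0.05))
})

test_that("sensitivity report assembles all pieces on synthetic data", {
  set.seed(10)
  n <- 60
  lam <- c(9, 4, 1)
  w <- latin_hypercube(n, lam, seed = 5)
  colnames(w$values) <- paste0("mode_", 1:3)
  sdu <- weights_to_sd_units(w)
  out <- tibble::tibble(
    idp = 0.5 - 0.1 * sdu[, 1] + 0.02 * sdu[, 2] + rnorm(n, sd = 0.005),
    fcp = 0.8 + 0.08 * sdu[, 1] - 0.05 * sdu[, 3] + rnorm(n, sd = 0.005),
    valid = rep(TRUE, n))
  rep <- sensitivity_report(w, out, config = shap_config(n_coalitions = 8))
  expect_s3_class(rep, "sensitivity_report")
  expect_equal(sum(rep$contributions$contribution_pct[
    rep$contributions$outcome == "idp"]), 100, tolerance = 1e-6)
  expect_equal(rep$contributions$mode[rep$contributions$outcome == "idp" &
                                      rep$contributions$rank == 1], "mode_1")
  expect_true("mode_1" %in% rep$important$idp)
  td <- tidy(rep)
  expect_true(all(c("pearson_r", "contribution_pct") %in% names(td)))
  gl <- glance(rep)
  expect_equal(nrow(gl), 2)
})
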