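make_shape_list <- function(X, p) {
  lapply(seq_len(nrow(X)), function(i) {
    fsusens:::new_fsu_shape(fsusens:::unflatten_shape(X[i, ], p),
                            sprintf("s%02d", i))
  })
}

test_that("rmse_between matches hand and loop oracles", {
  expect_equal(rmse_between(matrix(0, 1, 3), matrix(c(3, 4, 0), 1, 3)), 5)
  set.seed(1)
  A <- matrix(rnorm(30), 10, 3); B <- matrix(rnorm(30), 10, 3)
  loop <- sqrt(mean(vapply(1:10, function(i) sum((A[i, ] - B[i, ])^2), 0)))
  expect_equal(rmse_between(A, B), loop, tolerance = 1e-12)
  expect_equal(rmse_between(A, A), 0)
  expect_error(rmse_between(A, B[-1, ]), "point counts")
})

test_that("eigenvalues match a brute-force covariance oracle on a tiny cohort", {
  set.seed(2)
  X <- matrix(rnorm(5 * 12, sd = 2), 5, 12)       # t=5 shapes, p=4 points
  model <- ssm_fit(make_shape_list(X, 4), retain = 1)
  ev <- eigen(cov(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(model$eigenvalues, ev[seq_along(model$eigenvalues)],
               tolerance = 1e-10)
  expect_equal(model$lambda_total, sum(ev), tolerance = 1e-10)
  expect_equal(model$lambda_bar, mean(ev[seq_along(model$eigenvalues)]),
               tolerance = 1e-10)
})

test_that("a collinear cohort has exactly one nonzero eigenvalue", {
  base <- as.numeric(matrix(rnorm(12), 4, 3))
  dir <- as.numeric(matrix(rnorm(12), 4, 3))
  X <- rbind(base - dir, base, base + dir)
  model <- ssm_fit(make_shape_list(X, 4), retain = 1)
  expect_gt(model$eigenvalues[1], 1e-8)
  expect_lt(model$eigenvalues[2] / model$eigenvalues[1], 1e-12)
})

test_that("modes are orthonormal and reconstruction is complete", {
  co <- tiny_cohort(t = 8)
  model <- ssm_fit(align_cohort(co$shapes))
  MtM <- crossprod(model$modes)
  expect_lt(max(abs(MtM - diag(ncol(model$modes)))), 1e-8)
  al <- align_cohort(co$shapes)
  for (i in c(1, 4, 8)) {
    w <- ssm_project(model, al$shapes[[i]])
    rec <- fsusens:::ssm_reconstruct_any(model, w)
    expect_lt(rmse_between(rec, al$shapes[[i]]$points), 1e-6)
  }
})

test_that("reconstruction is linear with zero weights giving the mean", {
  co <- tiny_cohort(t = 8)
  model <- ssm_fit(align_cohort(co$shapes))
  rec0 <- ssm_reconstruct(model, numeric(0))
  expect_equal(as.numeric(rec0$points), as.numeric(model$mean_shape))
  w <- c(5, -3)
  r1 <- ssm_reconstruct(model, w)$points
  r2 <- ssm_reconstruct(model, 2 * w)$points
  mean_p <- fsusens:::unflatten_shape(model$mean_shape, model$p)
  expect_equal(r2 - mean_p, 2 * (r1 - mean_p), tolerance = 1e-9)
  expect_error(ssm_reconstruct(model, rep(1, model$retained + 1)), "exceeds")
})

test_that("mode displacement map equals the per-point block norms", {
  co <- tiny_cohort(t = 8)
  model <- ssm_fit(align_cohort(co$shapes))
  d <- mode_displacement_map(model, 1, sd_units = 2)
  blocks <- fsusens:::unflatten_shape(
    2 * sqrt(model$eigenvalues[1]) * model$modes[, 1], model$p)
  expect_equal(d, sqrt(rowSums(blocks^2)), tolerance = 1e-12)
  # consistency with reconstruction displacement
  rec <- ssm_reconstruct(model, 2 * sqrt(model$eigenvalues[1]))
  mean_p <- fsusens:::unflatten_shape(model$mean_shape, model$p)
  expect_equal(d, sqrt(rowSums((rec$points - mean_p)^2)), tolerance = 1e-9)
})

test_that("compactness is a cumulative-sum fraction", {
  model <- list(eigenvalues = c(3, 2, 1), lambda_total = 6)
  expect_equal(compactness(model, 2), 5 / 6)
  expect_equal(compactness(model, 3), 1)
  expect_error(compactness(model, 0))
  set.seed(3)
  lam <- sort(rexp(10), decreasing = TRUE)
  m2 <- list(eigenvalues = lam, lambda_total = sum(lam))
  for (M in c(1, 4, 10)) {
    expect_equal(compactness(m2, M), cumsum(lam)[M] / sum(lam))
  }
})

test_that("the modified Kaiser rule thresholds at factor times mean variance", {
  m <- list(eigenvalues = c(10, 5, 0.1), lambda_bar = mean(c(10, 5, 0.1)))
  expect_equal(retain_kaiser(m, 0.7), 2L)
  m2 <- list(eigenvalues = rep(2, 6), lambda_bar = 2)
  expect_equal(retain_kaiser(m2, 0.7), 6L)
  expect_error(retain_kaiser(m, 0), "factor")
  # printed-value arithmetic: lambda_K = 0.7 * lambda_bar
  lambda_bar <- 1.0039e3
  expect_equal(0.7 * lambda_bar, 702.73)
})

test_that("evaluate: full-mode accuracy vanishes and curves behave", {
  co <- tiny_cohort(t = 10)
  al <- align_cohort(co$shapes)
  perf_full <- ssm_evaluate(al, M = 9, n_specificity_samples = 20, seed = 1)
  expect_lt(perf_full$accuracy["mean"], 1e-6)    # all modes reproduce training
  expect_true(all(perf_full$per_mode_generalisation$rmse >= 0))
  # generalisation curve non-increasing (small tolerance for sampling noise)
  g <- perf_full$per_mode_generalisation$rmse
  expect_true(all(diff(g) <= 1e-8 + 0.05 * g[-length(g)]))
  expect_error(ssm_evaluate(al, M = 10), "modes")
})

test_that("noiseless low-rank cohort generalises to near zero at M = k", {
  sp <- phantom_spec(t = 50, latent_sd = c(2, 1), noise_sd = 0, size_sd = 0,
                     seed = 21)
  co <- generate_cohort(sp)
  al <- align_cohort(co$shapes)
  perf <- ssm_evaluate(al, M = 2, n_specificity_samples = 10, seed = 1)
  # residual comes from second-order pose-shape coupling, well below the
  # default correspondence-noise floor of 0.15 mm
  expect_lt(perf$generalisation["mean"], 0.15)
})

test_that("leading modes of a noiseless phantom span the aligned generative directions", {
  sp <- phantom_spec(t = 40, latent_sd = c(2, 1, 0.7, 0.5), noise_sd = 0,
                     size_sd = 0, seed = 22)
  co <- generate_cohort(sp)
  al <- align_cohort(co$shapes)
  model <- ssm_fit(al)
  k <- 4
  # aligned generative directions: span of the centred aligned data itself
  X <- t(vapply(al$shapes, function(s) as.numeric(s$points),
                numeric(3 * sp$p)))
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nv = k)
  ang <- svd(crossprod(model$modes[, 1:k], sv$v))$d
  expect_true(all(acos(pmin(ang, 1)) < 1e-3))
})

test_that("specificity of a zero-variance model is the distance to the nearest training shape", {
  co <- tiny_cohort(t = 6)
  al <- align_cohort(co$shapes)
  model <- ssm_fit(al, retain = 1)
  model$eigenvalues[] <- 0
  pts <- lapply(al$shapes, function(s) s$points)
  mean_p <- fsusens:::unflatten_shape(model$mean_shape, model$p)
  expected <- min(vapply(pts, function(P) rmse_between(mean_p, P), 0))
  set.seed(1)
  w <- rnorm(1, 0, sqrt(model$eigenvalues[1]))
  expect_equal(w, 0)          # sampler degenerates to the mean shape
  synth <- fsusens:::ssm_reconstruct_any(model, 0)
  expect_equal(min(vapply(pts, function(P) rmse_between(synth, P), 0)),
               expected)
})

test_that("eigen-spectrum is invariant to pre-applied similarity transforms", {
  # alignment maps everything into the reference frame, so the reference gets
  # a rigid perturbation and the others full similarity transforms
  co <- tiny_cohort(t = 8)
  base <- ssm_fit(align_cohort(co$shapes))
  set.seed(6)
  shuffled <- lapply(seq_along(co$shapes), function(i) {
    s <- co$shapes[[i]]
    sc <- if (i == 1) 1 else exp(rnorm(1, 0, 0.2))
    Q <- sc * s$points %*% t(random_rotation()) +
      matrix(rnorm(3, 0, 15), nrow(s$points), 3, byrow = TRUE)
    fsusens:::new_fsu_shape(Q, s$subject_id)
  })
  pert <- ssm_fit(align_cohort(shuffled))
  keep <- base$eigenvalues > 1e-6 * base$eigenvalues[1]
  rel <- abs(pert$eigenvalues - base$eigenvalues) / base$eigenvalues
  expect_lt(max(rel[keep]), 1e-8)
  # with the reference rescaled too, the normalised spectrum is what survives
  shuffled[[1]] <- fsusens:::new_fsu_shape(1.3 * shuffled[[1]]$points, "s1")
  pert2 <- ssm_fit(align_cohort(shuffled))
  rel2 <- abs(pert2$eigenvalues / pert2$lambda_total -
              base$eigenvalues / base$lambda_total) /
    (base$eigenvalues / base$lambda_total)
  expect_lt(max(rel2[keep]), 1e-8)
})
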