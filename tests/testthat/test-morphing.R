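test_that("identity TPS has identity affine part and vanishing kernel weights", {
  set.seed(1)
  P <- matrix(rnorm(60, sd = 5), 20, 3)
  fld <- tps_fit(P, P)
  expect_lt(max(abs(fld$kernel_weights)), 1e-10)
  expect_equal(fld$affine[2:4, ], diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fld$affine[1, ], numeric(3), tolerance = 1e-7,
               ignore_attr = TRUE)
})

test_that("TPS reproduces affine maps exactly at controls and probes", {
  set.seed(2)
  P <- matrix(rnorm(45, sd = 5), 15, 3)
  A <- diag(3) + matrix(rnorm(9, sd = 0.2), 3, 3)
  b <- rnorm(3, sd = 3)
  tgt <- P %*% t(A) + matrix(b, 15, 3, byrow = TRUE)
  fld <- tps_fit(P, tgt)
  expect_lt(max(abs(fld$kernel_weights)), 1e-8)
  probes <- matrix(rnorm(90, sd = 8), 30, 3)
  expect_equal(tps_apply(fld, probes),
               probes %*% t(A) + matrix(b, 30, 3, byrow = TRUE),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("TPS side conditions hold and controls interpolate exactly", {
  set.seed(3)
  P <- matrix(rnorm(36, sd = 5), 12, 3)
  tgt <- P + matrix(rnorm(36, sd = 1), 12, 3)
  fld <- tps_fit(P, tgt)
  # sum of kernel weights and first moments vanish
  expect_lt(max(abs(colSums(fld$kernel_weights))), 1e-8)
  expect_lt(max(abs(crossprod(P, fld$kernel_weights))), 1e-7)
  expect_lt(max(abs(tps_apply(fld, P) - tgt)), 1e-8)
})

test_that("TPS mapping matches an independent dense-system oracle", {
  # textbook formulation solved independently with explicit matrices
  set.seed(4)
  src <- matrix(runif(30, -5, 5), 10, 3)
  tgt <- src + matrix(rnorm(30, sd = 0.8), 10, 3)
  probes <- matrix(runif(15, -4, 4), 5, 3)
  K <- as.matrix(dist(src))
  P <- cbind(1, src)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  sol <- solve(A, rbind(tgt, matrix(0, 4, 3)))
  oracle <- sapply(1:3, function(d) {
    vapply(1:5, function(i) {
      r <- sqrt(colSums((t(src) - probes[i, ])^2))
      sum(sol[1:10, d] * r) + sol[11, d] +
        sum(sol[12:14, d] * probes[i, ])
    }, 0)
  })
  fld <- tps_fit(src, tgt)
  expect_equal(tps_apply(fld, probes), oracle, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("degenerate control sets raise informative errors", {
  flat <- cbind(runif(10), runif(10), 0)
  expect_error(tps_fit(flat, flat + 1), "coplanar")
  dup <- rbind(matrix(rnorm(12), 4, 3), matrix(rnorm(12), 4, 3))
  dup[5, ] <- dup[1, ]
  expect_error(tps_fit(dup, dup), "duplicate")
  expect_error(tps_fit(matrix(rnorm(9), 3, 3), matrix(rnorm(9), 3, 3)),
               "at least 4")
})

test_that("control point selection is deterministic, distinct and uniform-ish", {
  expect_identical(select_control_points(100, 100), 1:100)
  s1 <- select_control_points(1000, 200, seed = 7)
  s2 <- select_control_points(1000, 200, seed = 7)
  expect_identical(s1, s2)
  expect_equal(length(unique(s1)), 200)
  expect_error(select_control_points(10, 11), "cannot select")
  # decile occupancy: chi-square over repeated seeds should look uniform
  counts <- numeric(10)
  for (s in 1:50) {
    idx <- select_control_points(1000, 100, seed = s)
    counts <- counts + tabulate(ceiling(idx / 100), nbins = 10)
  }
  chisq <- sum((counts - mean(counts))^2 / mean(counts))
  expect_lt(chisq, qchisq(0.999, df = 9) * 3)
})

test_that("template building averages transformed volumes", {
  co <- tiny_cohort(t = 6)
  al <- align_cohort(co$shapes)
  tm <- build_template(co$meshes, al)
  # identical cohort: template equals the member
  sp0 <- phantom_spec(t = 3, latent_sd = c(0), noise_sd = 0, size_sd = 0,
                      seed = 1)
  co0 <- generate_cohort(sp0)
  al0 <- align_cohort(co0$shapes)
  tm0 <- build_template(co0$meshes, al0)
  expect_equal(tm0$nodes, co0$meshes[[1]]$nodes, tolerance = 1e-9)
  # template surface nodes coincide with the SSM mean shape
  model <- ssm_fit(al)
  mean_p <- fsusens:::unflatten_shape(model$mean_shape, model$p)
  expect_lt(max(abs(tm$nodes[tm$surface_index, ] - mean_p)), 1e-8)
})

test_that("two volumes mirrored about the mean average to the midpoint", {
  co <- tiny_cohort(t = 5)
  base <- co$meshes[[1]]
  d <- matrix(rnorm(length(base$nodes), sd = 0.5), nrow(base$nodes), 3)
  vplus <- fsusens:::new_fsu_mesh(base$nodes + d, base$hexes, base$labels,
                                  base$surface_index)
  vminus <- fsusens:::new_fsu_mesh(base$nodes - d, base$hexes, base$labels,
                                   base$surface_index)
  al <- list(transforms = list(fsusens:::identity_transform(),
                               fsusens:::identity_transform()))
  tm <- build_template(list(vplus, vminus), al)
  expect_equal(tm$nodes, base$nodes, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("identity morph returns the template and labels are conserved", {
  co <- tiny_cohort(t = 5)
  tm <- build_template(co$meshes, align_cohort(co$shapes))
  src <- tm$nodes[tm$surface_index, ]
  ctrl <- select_control_points(nrow(src), 150, seed = 1)
  fld <- tps_fit(src[ctrl, ], src[ctrl, ])
  mr <- morph_mesh(tm, fld, target_surface = src)
  expect_lt(max(abs(mr$mesh$nodes - tm$nodes)), 1e-7)
  expect_identical(mr$mesh$labels, tm$labels)
  expect_identical(mr$mesh$hexes, tm$hexes)
  expect_lt(mr$surface_rmse, 1e-8)
})

test_that("all-point morph interpolates the target surface exactly", {
  co <- tiny_cohort(t = 8)
  al <- align_cohort(co$shapes)
  tm <- build_template(co$meshes, al)
  model <- ssm_fit(al)
  tgt <- ssm_reconstruct(model, 1.5 * sqrt(model$eigenvalues[1]))
  src <- tm$nodes[tm$surface_index, ]
  fld <- tps_fit(src, tgt$points)
  mr <- morph_mesh(tm, fld, target_surface = tgt)
  expect_lt(mr$surface_rmse, 1e-8)
})

test_that("downsampled controls give small but nonzero surface error", {
  co <- tiny_cohort(t = 8)
  al <- align_cohort(co$shapes)
  tm <- build_template(co$meshes, al)
  model <- ssm_fit(al)
  w <- latin_hypercube(3, model, seed = 2)
  ctrl <- select_control_points(length(tm$surface_index), 300, seed = 3)
  mo <- morph_cohort(tm, model, w, ctrl)
  expect_equal(nrow(mo$report), 3)
  expect_true(all(mo$report$surface_rmse > 0))
  expect_true(all(mo$report$surface_rmse < 1.0))
  for (m in mo$meshes) expect_identical(m$hexes, tm$hexes)
})
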