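test_that("unit cube element has scaled Jacobian 1; inverted node is caught", {
  m <- block_mesh(1, 1)
  q <- screen_quality(m)
  expect_true(q$valid)
  expect_equal(q$metrics$min_scaled_jacobian, 1, tolerance = 1e-12)
  bad <- m
  bad$nodes[8, 3] <- -2                       # push through the opposite face
  qb <- screen_quality(bad)
  expect_false(qb$valid)
  expect_lt(qb$metrics$min_corner_jacobian, 0)
  expect_equal(qb$metrics$inverted_fraction, 1)
})

test_that("sheared cube scaled Jacobian matches the closed form", {
  m <- block_mesh(1, 1)
  shear <- 0.5
  m$nodes[, 1] <- m$nodes[, 1] + shear * m$nodes[, 3]
  q <- screen_quality(m)
  # corner frame: ex=(1,0,0), ey=(0,1,0), ez=(s,0,1): det 1, |ez|=sqrt(1+s^2)
  expect_equal(q$metrics$min_scaled_jacobian, 1 / sqrt(1 + shear^2),
               tolerance = 1e-12)
  expect_true(q$metrics$min_corner_jacobian > 0)
})

test_that("uniaxial patch test: sigma = -P and delta = PL/E to 1e-6 relative", {
  n <- 3L; L <- 9; E <- 100; nu <- 0.2
  m <- block_mesh(n, L)
  res <- solve_axial(m, material_set(), load_case(total_force = 360,
                                                  fixed_mode = "rollers"))
  P <- 360 / L^2
  top <- which(m$nodes[, 3] == L)
  expect_equal(mean(res$displacement[top, 3]), -P * L / E,
               tolerance = 1e-6)
  expect_equal(max(abs(res$displacement[top, 3] + P * L / E)), 0,
               tolerance = 1e-6 * P * L / E)
  # hydrostatic pressure of uniaxial stress is P/3 at every Gauss point
  expect_equal(res$idp, P / 3, tolerance = 1e-6)
})

test_that("global equilibrium: reactions balance the applied 400 N", {
  m <- block_mesh(3, 10)
  res <- solve_axial(m, material_set(), load_case(400, "encastre"))
  expect_equal(res$reaction_force, 400, tolerance = 1e-8 * 400)
})

test_that("zero load gives zero displacement and outputs", {
  m <- block_mesh(2, 10)
  res <- solve_axial(m, material_set(), load_case(0, "encastre"))
  expect_equal(max(abs(res$displacement)), 0, tolerance = 1e-12)
  expect_equal(res$idp, 0, tolerance = 1e-12)
})

test_that("unit-cube element stiffness is symmetric PSD with 6 rigid modes", {
  m <- block_mesh(1, 1)
  K <- as.matrix(fsusens:::assemble_stiffness(m, material_set()))
  expect_lt(max(abs(K - t(K))), 1e-10 * max(abs(K)))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-9 * max(ev)))
  expect_equal(sum(ev < 1e-9 * max(ev)), 6)
})

test_that("assembled stiffness is symmetric on a distorted mesh", {
  set.seed(8)
  m <- block_mesh(2, 10)
  m$nodes <- m$nodes + matrix(rnorm(length(m$nodes), sd = 0.3),
                              nrow(m$nodes), 3)
  K <- fsusens:::assemble_stiffness(m, material_set())
  asym <- max(abs(K - Matrix::t(K)))
  expect_lt(asym, 1e-10 * max(abs(K)))
})

test_that("outputs scale linearly with the applied load", {
  co <- tiny_cohort(t = 5, noise_sd = 0, size_sd = 0)
  mesh <- co$template$mesh
  r1 <- solve_axial(mesh, material_set(), load_case(400))
  r2 <- solve_axial(mesh, material_set(), load_case(800))
  expect_equal(r2$idp, 2 * r1$idp, tolerance = 1e-9)
  expect_equal(max(abs(r2$displacement - 2 * r1$displacement)), 0,
               tolerance = 1e-8 * max(abs(r1$displacement)))
  # the facet surrogate measures gap closure on the deformed geometry, so it
  # is only asymptotically linear in the load
  expect_equal(r2$fcp, 2 * r1$fcp, tolerance = 0.05)
})

test_that("mesh refinement converges the IDP proxy to the closed form", {
  P <- 400 / 100
  idp <- vapply(c(1L, 2L, 4L), function(n) {
    solve_axial(block_mesh(n, 10), material_set(),
                load_case(400, "rollers"))$idp
  }, 0)
  err <- abs(idp - P / 3)
  expect_lt(err[3], 1e-6)
  expect_true(all(diff(err) <= 1e-9))
})

test_that("phantom solve produces plausible positive outcomes", {
  co <- tiny_cohort(t = 5, noise_sd = 0, size_sd = 0)
  res <- solve_axial(co$template$mesh, material_set(), load_case())
  expect_true(res$valid)
  expect_gt(res$idp, 0.1); expect_lt(res$idp, 5)
  expect_gt(res$fcp, 0.1); expect_lt(res$fcp, 5)
})

test_that("screening-invalid meshes are refused with a status", {
  m <- block_mesh(2, 10)
  m$nodes[1, ] <- m$nodes[14, ]               # collapse a corner
  res <- solve_axial(m, material_set(), load_case())
  expect_false(res$valid)
  expect_match(res$failure_reason, "quality")
})

test_that("unknown structure labels are rejected", {
  m <- block_mesh(1, 1, label = "mystery_tissue")
  expect_error(solve_axial(m, material_set(), load_case(), screen = FALSE),
               "mystery_tissue")
})

test_that("batch simulation flags the bad subject and is deterministic", {
  co <- tiny_cohort(t = 5, noise_sd = 0, size_sd = 0)
  meshes <- co$meshes[1:3]
  bad <- meshes[[2]]
  bad$nodes[bad$hexes[1, 1], ] <- bad$nodes[bad$hexes[1, 7], ] + 5
  meshes[[2]] <- bad
  out <- batch_simulate(meshes, material_set(), load_case())
  expect_equal(nrow(out), 3)
  expect_equal(sum(!out$valid), 1)
  expect_match(out$failure_reason[2], "quality")
  expect_equal(attr(out, "failure_fraction"), 1 / 3)
  out2 <- batch_simulate(meshes, material_set(), load_case())
  expect_identical(out$idp, out2$idp)
  expect_identical(out$fcp, out2$fcp)
})

test_that("material set carries the full parameter table", {
  mats <- material_set()
  expect_equal(mats$linear$cancellous, c(E = 100, nu = 0.2))
  expect_equal(mats$linear$cortical, c(E = 12000, nu = 0.3))
  expect_equal(mats$linear$cep_upper, c(E = 23, nu = 0.4))
  expect_equal(mats$linear$facet_cartilage_left, c(E = 35, nu = 0.4))
  expect_equal(unname(mats$hyper$annulus),
               c(0.34, 0.306, 1.81, 11, 0))
  expect_equal(unname(mats$hyper$nucleus), c(0.16, 0.024))
  expect_equal(mats$fibre_angle, 30)
  over <- material_set(overrides = list(cancellous = c(E = 200, nu = 0.25)))
  expect_equal(over$linear$cancellous, c(E = 200, nu = 0.25))
})
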