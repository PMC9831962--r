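#' Specification of a synthetic FSU phantom cohort
#'
#' Defines the study conditions for generating a corresponded cohort of
#' two-vertebra + disc phantom geometries with known low-dimensional latent
#' shape structure. The phantom is the testbed that stands in for a real
#' corresponded training cohort: every subject shares one node ordering and
#' one hexahedral connectivity, so point `k` of every subject lies at the same
#' parametric location of the phantom.
#'
#' The phantom body is a superelliptical column: a lower vertebra (L5-like),
#' a cartilaginous endplate, a disc whose cross-section is a central nucleus
#' surrounded by exactly seven concentric annulus layers, a second endplate,
#' and an upper vertebra (L4-like), plus two posterior facet-cartilage pad
#' pairs separated by a small vertical gap. Vertebral cross-sections carry a
#' two-element-thick cortical shell around a cancellous core.
#'
#' Shape variation is generated by smooth global deformation fields (axial
#' squash with disc bulge, nucleus widening, facet gap/area change, lateral
#' shear, and optionally taper and axial torsion), each
#' normalised to 1 mm root-mean-square surface displacement per unit weight,
#' so latent weights are in millimetres.
#'
#' @param t Number of subjects (>= 3).
#' @param latent_sd Per-mode standard deviations of the latent weights (mm),
#'   non-increasing, length 1..6. The length sets `latent_dim`.
#' @param noise_sd Standard deviation of iid isotropic Gaussian point noise
#'   (mm) added to every node.
#' @param size_sd Standard deviation of the log of the multiplicative
#'   isotropic size factor applied per subject (dimensionless).
#' @param seed RNG seed controlling the cohort draw.
#' @param nc Cross-section subdivision count (even, >= 16 so that seven
#'   annulus layers plus a nucleus core fit). Controls the surface point
#'   count `p`.
#' @param disc_semiaxes Lateral and anteroposterior semi-axes of the
#'   superelliptical cross-section (mm).
#'
#' @return An object of class `phantom_spec`. Its `p` element records the
#'   number of corresponded surface points implied by `nc`, and
#'   `structure_fractions` the element-count fractions per structure.
#' @export
phantom_spec <- function(t = 152L,
                         latent_sd = c(2.2, 0.8, 0.6, 0.45),
                         noise_sd = 0.15,
                         size_sd = 0.05,
                         seed = 1L,
                         nc = 18L,
                         disc_semiaxes = c(24, 18)) {
  check_scalar(t, "t", lower = 3)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(size_sd, "size_sd", lower = 0)
  check_scalar(nc, "nc", lower = 16)
  if (nc %% 2 != 0) stopf("`nc` must be even (got %d)", nc)
  if (!is.numeric(latent_sd) || length(latent_sd) < 1 || length(latent_sd) > 6) {
    stopf("`latent_sd` must have length 1..6")
  }
  if (any(latent_sd < 0) || is.unsorted(rev(latent_sd))) {
    stopf("`latent_sd` must be non-negative and non-increasing")
  }
  if (length(latent_sd) >= t) stopf("latent_dim (%d) must be < t (%d)",
                                    length(latent_sd), t)
  tmpl <- phantom_template(nc = as.integer(nc), disc_semiaxes = disc_semiaxes)
  fractions <- prop.table(table(tmpl$mesh$labels))
  structure(
    list(t = as.integer(t), p = length(tmpl$mesh$surface_index),
         latent_dim = length(latent_sd), latent_sd = latent_sd,
         noise_sd = noise_sd, size_sd = size_sd, seed = as.integer(seed),
         nc = as.integer(nc), disc_semiaxes = disc_semiaxes,
         structure_fractions = fractions),
    class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> t = %d subjects, p = %d surface points, %d latent modes\n",
    x$t, x$p, x$latent_dim))
  cat(sprintf("  latent_sd = [%s] mm, noise_sd = %.3g mm, size_sd = %.3g\n",
              paste(format(x$latent_sd), collapse = ", "),
              x$noise_sd, x$size_sd))
  invisible(x)
}

# ---- geometry construction ---------------------------------------------------

# Map the unit square [-1,1]^2 onto a superellipse |x/a|^pw + |y/b|^pw = 1:
# square ring t maps to the scaled superellipse t * E, with the
# square-perimeter position mapped onto the superellipse parameter. The
# rounded-square boundary (pw = 4) keeps the grid's corner cells well-shaped
# while concentric square rings become nested convex rings (nucleus core,
# seven annulus layers, cortical shell).
square_to_superellipse <- function(u, v, a, b, pw = 4) {
  t <- pmax(abs(u), abs(v))
  ub <- ifelse(t > 0, u / t, 0)
  vb <- ifelse(t > 0, v / t, 0)
  # perimeter coordinate of (ub, vb) on the unit square, in [-1, 7)
  perim <- numeric(length(u))
  right <- abs(ub - 1) < 1e-12
  top <- abs(vb - 1) < 1e-12 & !right
  left <- abs(ub + 1) < 1e-12 & !right & !top
  bottom <- !right & !top & !left
  perim[right] <- vb[right]
  perim[top] <- 2 - ub[top]
  perim[left] <- 4 - vb[left]
  perim[bottom] <- 6 + ub[bottom]
  phi <- pi / 4 * perim
  # mild four-lobed bulge at the grid-corner directions keeps the cells that
  # straddle a grid corner well-shaped (they otherwise degenerate to slivers)
  bulge <- 1 + 0.08 * pmax(0, -cos(4 * phi))^2
  cbind(x = a * t * bulge * sign(cos(phi)) * abs(cos(phi))^(2 / pw),
        y = b * t * bulge * sign(sin(phi)) * abs(sin(phi))^(2 / pw))
}

# Build the mean phantom: hexahedral mesh with structure labels, surface-point
# index, facet-pad bookkeeping and the generative deformation fields.
phantom_template <- function(nc = 18L, disc_semiaxes = c(24, 18)) {
  a <- disc_semiaxes[1]; b <- disc_semiaxes[2]
  # z structure: 3 layers per vertebra, 1 per endplate, 2 for the disc
  z_slices <- c(0, 4, 8, 12, 13, 17, 21, 22, 26, 30, 34)
  layer_kind <- c("bone_l5", "bone_l5", "bone_l5", "cep_lower",
                  "disc", "disc", "cep_upper", "bone_l4", "bone_l4", "bone_l4")
  ns <- length(z_slices)                 # 11 node slices
  nl <- ns - 1L                          # 10 element layers
  npx <- nc + 1L                         # nodes per row
  half <- nc / 2

  ij <- expand.grid(i = 0:nc, j = 0:nc)
  u <- 2 * ij$i / nc - 1
  v <- 2 * ij$j / nc - 1
  xy <- square_to_superellipse(u, v, a, b)
  n_grid <- npx * npx * ns
  nodes <- matrix(0, n_grid, 3, dimnames = list(NULL, c("x", "y", "z")))
  for (s in seq_len(ns)) {
    idx <- (s - 1L) * npx * npx + seq_len(npx * npx)
    nodes[idx, 1:2] <- xy
    nodes[idx, 3] <- z_slices[s]
  }
  nid <- function(i, j, s) (s - 1L) * npx * npx + j * npx + i + 1L
  # normalised Chebyshev radius of each grid node (0 centre, 1 boundary)
  tn_grid <- pmax(abs(u), abs(v))
  tn <- rep(tn_grid, ns)

  # column elements
  cell <- expand.grid(i = 0:(nc - 1L), j = 0:(nc - 1L), l = seq_len(nl))
  ring <- pmax(abs(cell$i + 0.5 - half), abs(cell$j + 0.5 - half)) + 0.5
  kind <- layer_kind[cell$l]
  rnuc <- half - 7L                      # nucleus element rings
  lab <- character(nrow(cell))
  lab[kind %in% c("bone_l4", "bone_l5")] <-
    ifelse(ring[kind %in% c("bone_l4", "bone_l5")] > half - 2L,
           "cortical", "cancellous")
  lab[kind == "cep_lower"] <- "cep_lower"
  lab[kind == "cep_upper"] <- "cep_upper"
  disc_sel <- kind == "disc"
  lab[disc_sel] <- ifelse(ring[disc_sel] <= rnuc, "nucleus",
                          paste0("annulus_layer_", ring[disc_sel] - rnuc))
  hexes <- cbind(nid(cell$i,      cell$j,      cell$l),
                 nid(cell$i + 1L, cell$j,      cell$l),
                 nid(cell$i + 1L, cell$j + 1L, cell$l),
                 nid(cell$i,      cell$j + 1L, cell$l),
                 nid(cell$i,      cell$j,      cell$l + 1L),
                 nid(cell$i + 1L, cell$j,      cell$l + 1L),
                 nid(cell$i + 1L, cell$j + 1L, cell$l + 1L),
                 nid(cell$i,      cell$j + 1L, cell$l + 1L))

  # facet pads: posterior (j = 0) extrusions, two elements wide, one thick
  pad_depth <- 4; gap0 <- 0.6
  z_u_bot <- z_slices[8]; z_l_top <- z_slices[4]       # 22 and 12
  shift <- (z_u_bot - z_l_top - gap0) / 2              # 4.7
  pad_i0 <- c(left = 3L, right = nc - 5L)
  pads <- list()
  facet_info <- list()
  for (lev in c("upper", "lower")) {
    s_a <- if (lev == "upper") 8L else 3L
    dz <- if (lev == "upper") -shift else +shift
    for (side in c("left", "right")) {
      i0 <- pad_i0[[side]]
      attach_ids <- as.integer(outer(nid(i0:(i0 + 2L), 0L, s_a),
                                     c(0L, npx * npx), `+`))  # 3 x 2 slices
      free_xyz <- nodes[attach_ids, , drop = FALSE]
      free_xyz[, 2] <- free_xyz[, 2] - pad_depth
      free_xyz[, 3] <- free_xyz[, 3] + dz
      free_ids <- nrow(nodes) + seq_len(6L)
      nodes <- rbind(nodes, free_xyz)
      tn <- c(tn, rep(1, 6L))
      # two hexes per pad; free/attach ordering keeps the Jacobian positive
      A <- matrix(attach_ids, nrow = 3)  # [i, slice]
      FN <- matrix(free_ids, nrow = 3)
      pad_elems <- integer(0)
      for (k in 1:2) {
        hexes <- rbind(hexes, c(A[k, 1], FN[k, 1], FN[k + 1, 1], A[k + 1, 1],
                                A[k, 2], FN[k, 2], FN[k + 1, 2], A[k + 1, 2]))
        lab <- c(lab, paste0("facet_cartilage_", side))
        pad_elems <- c(pad_elems, nrow(hexes))
      }
      # facing rims: the free-node edge nearest the gap, plus the attach-side
      # edge at the same slice (used for the pad depth measurement)
      contact <- if (lev == "upper") FN[, 1] else FN[, 2]
      attach_rim <- if (lev == "upper") A[, 1] else A[, 2]
      facet_info[[paste(lev, side, sep = "_")]] <-
        list(attach = attach_ids, free = as.integer(FN),
             contact = as.integer(contact),
             attach_rim = as.integer(attach_rim),
             elems = pad_elems, level = lev)
    }
  }

  # surface points: exterior boundary, end slices, pad free nodes and the
  # internal nucleus interfaces (annulus-nucleus and CEP-nucleus)
  grid_sel <- function(pred_ij, slices) {
    out <- integer(0)
    keep <- which(pred_ij(ij$i, ij$j))
    for (s in slices) out <- c(out, (s - 1L) * npx * npx + keep)
    out
  }
  side_b <- grid_sel(function(i, j) i == 0 | i == nc | j == 0 | j == nc,
                     seq_len(ns))
  bot <- grid_sel(function(i, j) i > 0 & i < nc & j > 0 & j < nc, 1L)
  top <- grid_sel(function(i, j) i > 0 & i < nc & j > 0 & j < nc, ns)
  pad_free <- unlist(lapply(facet_info, `[[`, "free"), use.names = FALSE)
  cheb <- pmax(abs(ij$i - half), abs(ij$j - half))
  # internal interfaces sampled as surface points: the full CEP-disc
  # cross-sections (slices 5 and 7) and the annulus-nucleus interface ring
  # plus nucleus footprint at mid-disc
  nuc_foot <- grid_sel(function(i, j) i > 0 & i < nc & j > 0 & j < nc,
                       c(5L, 7L))
  nuc_ring <- grid_sel(function(i, j) pmax(abs(i - half), abs(j - half)) <= rnuc,
                       6L)
  surface_index <- c(sort(side_b), sort(bot), sort(top), sort(pad_free),
                     sort(nuc_foot), sort(nuc_ring))
  stopifnot(!anyDuplicated(surface_index))

  mesh <- new_fsu_mesh(nodes, hexes, lab, surface_index,
                       facet_info = facet_info,
                       meta = list(nc = nc, z_slices = z_slices,
                                   semiaxes = c(a, b), rnuc = rnuc,
                                   pad_depth = pad_depth, gap0 = gap0))

  fields <- phantom_fields(nodes, tn, a, b, z_slices, surface_index)
  ring_only <- grid_sel(function(i, j) pmax(abs(i - half), abs(j - half)) == rnuc,
                        6L)
  list(mesh = mesh, fields = fields, tn = tn,
       surf_sets = list(nuc_ring_mid = match(sort(ring_only), surface_index),
                        disc_top = match(sort(intersect(side_b,
                          grid_sel(function(i, j) i == 0 | i == nc | j == 0 | j == nc, 7L))),
                          surface_index),
                        disc_bot = match(sort(intersect(side_b,
                          grid_sel(function(i, j) i == 0 | i == nc | j == 0 | j == nc, 5L))),
                          surface_index),
                        pads = lapply(facet_info, function(fi)
                          list(contact = match(fi$contact, surface_index),
                               attach_rim = match(fi$attach_rim, surface_index),
                               all = match(c(fi$attach, fi$free), surface_index)))))
}

# Smooth global deformation fields, each normalised to 1 mm root-mean-square
# surface-point displacement, so a latent weight is interpretable as
# millimetres of RMS surface change and each mode's contribution to the shape
# covariance scales with its latent variance alone. Per unit (positive) weight:
#   1 dominant mode: segment height decreases while the disc, and the nucleus
#     in particular, widen and the facet pads approach slightly — the broad
#     co-varying pattern a leading PCA mode of a real cohort exhibits
#   2 nucleus width: annulus-nucleus interface pushed outward
#   3 facet gap    : pads approach (gap closes) and widen (area grows)
#   4 shear        : lateral shear; leaves height, gap, nucleus width and pad
#                    area unchanged, so its ground-truth response effect is zero
#   5 taper        : cross-section widens with height
#   6 torsion      : axial twist
phantom_fields <- function(nodes, tn, a, b, z_slices, surface_index) {
  zmid <- (z_slices[5] + z_slices[7]) / 2
  H <- diff(range(z_slices))
  x <- nodes[, 1]; y <- nodes[, 2]; z <- nodes[, 3]
  r <- sqrt(x^2 + y^2)
  ux <- ifelse(r > 0, x / r, 0); uy <- ifelse(r > 0, y / r, 0)
  zero <- numeric(length(x))

  gdisc <- exp(-((z - zmid) / 5)^2)
  pad_y <- -b - 2                      # pad band centre in y
  wpad <- exp(-((y - pad_y) / 4)^2)
  g_gap <- -wpad * tanh((z - zmid) / 3)

  # in-plane disc scaling (linear in position, smooth everywhere): the disc
  # and nucleus widen together while the segment shortens and the facet pads
  # approach slightly
  f1 <- cbind(0.35 * gdisc * x / a, 0.35 * gdisc * y / b,
              -(z - zmid) / (H / 2) + 0.3 * g_gap)

  # differential in-plane scaling with a column-wide carrier: the inner
  # cross-section expands more than the outer rim, most strongly at the
  # disc, changing the nucleus-annulus ratio
  gcol <- 0.4 + 0.6 * gdisc
  f2 <- cbind(gcol * (1 - tn^2) * x / a, gcol * (1 - tn^2) * y / b, zero)

  # facet gap/area: pads approach and widen, carried by a broad posterior
  # wedge so the pattern is not confined to the pad band
  wedge <- (y / b)^2 * tanh((z - zmid) / 6)
  f3 <- cbind(0.3 * wpad * x / a, zero, 0.25 * g_gap + 0.2 * wedge)

  f4 <- cbind((z - zmid) / (H / 2), zero, zero)

  g5 <- (z - zmid) / (H / 2)
  f5 <- cbind(0.8 * g5 * x / a, 0.8 * g5 * y / b, zero)

  th <- 0.04 * (z - zmid)
  f6 <- cbind(x * cos(th) - y * sin(th) - x, x * sin(th) + y * cos(th) - y, zero)

  # project out the similarity-transform tangent space (translations,
  # infinitesimal rotations, scaling) evaluated on the surface points, so the
  # injected variance is pure shape change that Procrustes alignment cannot
  # absorb; then normalise to unit RMS surface displacement
  ctr <- colMeans(nodes[surface_index, , drop = FALSE])
  vc <- sweep(nodes, 2, ctr)
  zero_n <- numeric(nrow(nodes))
  one_n <- rep(1, nrow(nodes))
  sim_basis <- list(
    cbind(one_n, zero_n, zero_n), cbind(zero_n, one_n, zero_n),
    cbind(zero_n, zero_n, one_n),
    cbind(zero_n, -vc[, 3], vc[, 2]),      # rotation about x
    cbind(vc[, 3], zero_n, -vc[, 1]),      # rotation about y
    cbind(-vc[, 2], vc[, 1], zero_n),      # rotation about z
    vc)                                    # scaling
  Bs <- vapply(sim_basis, function(g) as.numeric(g[surface_index, ]),
               numeric(3 * length(surface_index)))
  raw <- lapply(list(f1, f2, f3, f4, f5, f6), function(f) {
    fs <- as.numeric(f[surface_index, ])
    cf <- qr.coef(qr(Bs), fs)
    for (j in seq_along(sim_basis)) f <- f - cf[j] * sim_basis[[j]]
    f
  })
  # Gram-Schmidt on the surface inner product: mutually orthogonal modes put
  # each one's injected variance on its own covariance eigendirection
  out <- list()
  for (k in seq_along(raw)) {
    f <- raw[[k]]
    for (j in seq_len(k - 1)) {
      g <- out[[j]]
      num <- sum(f[surface_index, ] * g[surface_index, ])
      den <- sum(g[surface_index, ]^2)
      f <- f - (num / den) * g
    }
    out[[k]] <- f
  }
  lapply(out, function(f) {
    f / sqrt(mean(rowSums(f[surface_index, , drop = FALSE]^2)))
  })
}

# ---- core containers ---------------------------------------------------------

new_fsu_mesh <- function(nodes, hexes, labels, surface_index,
                         facet_info = NULL, meta = list()) {
  check_points(nodes, "nodes")
  storage.mode(hexes) <- "integer"
  if (ncol(hexes) != 8L) stopf("hexes must have 8 columns")
  if (length(labels) != nrow(hexes)) stopf("one label per element required")
  if (any(surface_index < 1L) || any(surface_index > nrow(nodes))) {
    stopf("surface_index out of node range")
  }
  structure(list(nodes = nodes, hexes = hexes, labels = labels,
                 surface_index = as.integer(surface_index),
                 facet_info = facet_info, meta = meta),
            class = "fsu_mesh")
}

#' @export
print.fsu_mesh <- function(x, ...) {
  cat(sprintf("<fsu_mesh> %d nodes, %d hexahedra, %d surface points\n",
              nrow(x$nodes), nrow(x$hexes), length(x$surface_index)))
  print(table(x$labels))
  invisible(x)
}

new_fsu_shape <- function(points, subject_id = NA_character_) {
  check_points(points)
  structure(list(points = points, subject_id = subject_id),
            class = "fsu_shape")
}

#' @export
print.fsu_shape <- function(x, ...) {
  cat(sprintf("<fsu_shape> '%s': %d corresponded points\n",
              x$subject_id, nrow(x$points)))
  invisible(x)
}

# ---- cohort generation -------------------------------------------------------

#' Generate a corresponded synthetic phantom cohort with known ground truth
#'
#' Draws `t` subjects as mean phantom + sum of latent-weighted generative
#' deformation fields + iid point noise, each scaled by a random isotropic
#' size factor, together with the matching labelled volumetric hexahedral
#' meshes (identical connectivity across subjects) and a ground-truth record
#' for parameter-recovery testing. Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `fsu_cohort` with elements `shapes` (list of
#'   `fsu_shape`), `meshes` (list of `fsu_mesh`), `truth` (ground truth:
#'   latent weights, response coefficients, true importance ranking) and
#'   `template` (the mean phantom).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stopf("`spec` must be a phantom_spec")
  if (spec$latent_dim >= spec$t) stopf("degenerate spec: latent_dim >= t")
  tmpl <- phantom_template(spec$nc, spec$disc_semiaxes)
  k <- spec$latent_dim
  fields <- tmpl$fields[seq_len(k)]
  n_nodes <- nrow(tmpl$mesh$nodes)

  truth <- phantom_truth(tmpl, spec)

  with_seed(spec$seed, {
    W <- matrix(rnorm(spec$t * k), spec$t, k) %*% diag(spec$latent_sd, k)
    sizes <- exp(rnorm(spec$t, 0, spec$size_sd))
    shapes <- vector("list", spec$t)
    meshes <- vector("list", spec$t)
    for (i in seq_len(spec$t)) {
      nodes <- tmpl$mesh$nodes
      for (m in seq_len(k)) nodes <- nodes + W[i, m] * fields[[m]]
      if (spec$noise_sd > 0) {
        nodes <- nodes + matrix(rnorm(3 * n_nodes, 0, spec$noise_sd),
                                n_nodes, 3)
      }
      ctr <- colMeans(nodes)
      nodes <- sweep(sweep(nodes, 2, ctr), 1, sizes[i], `*`)
      nodes <- sweep(nodes, 2, ctr, `+`)
      colnames(nodes) <- c("x", "y", "z")
      id <- sprintf("subj_%03d", i)
      meshes[[i]] <- new_fsu_mesh(nodes, tmpl$mesh$hexes, tmpl$mesh$labels,
                                  tmpl$mesh$surface_index,
                                  facet_info = tmpl$mesh$facet_info,
                                  meta = tmpl$mesh$meta)
      shapes[[i]] <- new_fsu_shape(nodes[tmpl$mesh$surface_index, , drop = FALSE],
                                   id)
    }
    truth$latent_weights <- W
    truth$size_factors <- sizes
  })
  structure(list(shapes = shapes, meshes = meshes, truth = truth,
                 template = tmpl, spec = spec),
            class = "fsu_cohort")
}

#' @export
print.fsu_cohort <- function(x, ...) {
  cat(sprintf("<fsu_cohort> %d subjects, p = %d points, latent_dim = %d\n",
              length(x$shapes), nrow(x$shapes[[1]]$points), x$spec$latent_dim))
  invisible(x)
}

# Geometric features of a phantom shape (surface points only), and the
# analytic ground-truth response built on them. Feature deviations are
# measured relative to the mean phantom.
phantom_features <- function(points, surf_sets) {
  nw <- mean(sqrt(points[surf_sets$nuc_ring_mid, 1]^2 +
                  points[surf_sets$nuc_ring_mid, 2]^2))
  dh <- mean(points[surf_sets$disc_top, 3]) - mean(points[surf_sets$disc_bot, 3])
  gap_side <- function(side) {
    up <- surf_sets$pads[[paste0("upper_", side)]]$contact
    lo <- surf_sets$pads[[paste0("lower_", side)]]$contact
    mean(points[up, 3]) - mean(points[lo, 3])
  }
  gap <- mean(c(gap_side("left"), gap_side("right")))
  area_side <- function(side) {
    pu <- surf_sets$pads[[paste0("upper_", side)]]
    width <- diff(range(points[pu$contact, 1]))
    depth <- abs(mean(points[pu$contact, 2]) - mean(points[pu$attach_rim, 2]))
    width * depth
  }
  area <- mean(c(area_side("left"), area_side("right")))
  c(nucleus_width = nw, disc_height = dh, facet_gap = gap, pad_area = area)
}

phantom_truth <- function(tmpl, spec) {
  surf_sets <- tmpl$surf_sets
  mean_pts <- tmpl$mesh$nodes[tmpl$mesh$surface_index, , drop = FALSE]
  f0 <- phantom_features(mean_pts, surf_sets)
  # response = intercept * (1 + linear combination of relative feature deviations)
  coefs <- list(
    idp = c(intercept = 0.50, nucleus_width = -0.4, disc_height = -1.0,
            facet_gap = 0, pad_area = 0),
    fcp = c(intercept = 0.80, nucleus_width = 0, disc_height = -0.5,
            facet_gap = -0.8, pad_area = -0.2))
  truth <- list(feature_baseline = f0, feature_coefficients = coefs,
                surf_sets = surf_sets, seed = spec$seed)
  # latent-space Jacobian by central differences along each generative field
  k <- spec$latent_dim
  J <- matrix(0, 2, k, dimnames = list(c("idp", "fcp"), NULL))
  h <- 0.5
  for (m in seq_len(k)) {
    fld <- tmpl$fields[[m]][tmpl$mesh$surface_index, , drop = FALSE]
    up <- phantom_response_points(mean_pts + h * fld, truth)
    dn <- phantom_response_points(mean_pts - h * fld, truth)
    J[, m] <- (c(up$idp, up$fcp) - c(dn$idp, dn$fcp)) / (2 * h)
  }
  truth$response_coefficients <- J
  contrib <- abs(J) %*% diag(spec$latent_sd, k)
  truth$true_importance_ranking <- list(
    idp = order(contrib["idp", ], decreasing = TRUE),
    fcp = order(contrib["fcp", ], decreasing = TRUE))
  truth
}

phantom_response_points <- function(points, truth) {
  f <- phantom_features(points, truth$surf_sets)
  f0 <- truth$feature_baseline
  rel <- (f - f0) / f0
  rel["facet_gap"] <- (f["facet_gap"] - f0["facet_gap"])  # mm, gap is ~0.6
  val <- function(cf) {
    unname(cf["intercept"] *
      (1 + sum(cf[names(f)] * rel[names(f)])))
  }
  list(idp = val(truth$feature_coefficients$idp),
       fcp = val(truth$feature_coefficients$fcp))
}

#' Analytic ground-truth response of a phantom shape
#'
#' Deterministic smooth function of interpretable geometric features of the
#' phantom surface: a wider nucleus and a taller disc lower the IDP-like
#' outcome; a closing facet gap and smaller pad area raise the FCP-like
#' outcome. At the mean phantom both outcomes equal their configured
#' intercepts.
#'
#' @param shape An `fsu_shape` from the phantom cohort (or reconstructed in
#'   its latent space).
#' @param truth The `truth` element of an [generate_cohort()] result.
#' @return A list with numeric elements `idp` and `fcp` (MPa).
#' @export
true_response <- function(shape, truth) {
  pts <- if (inherits(shape, "fsu_shape")) shape$points else shape
  check_points(pts, "shape points")
  phantom_response_points(pts, truth)
}
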