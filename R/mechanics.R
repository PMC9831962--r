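#' Material set for the FSU model
#'
#' Per-structure parameters: linear elastic moduli for the in-package solver,
#' plus the hyperelastic parameters (Holzapfel-Gasser-Ogden annulus with
#' +/-30 degree alternating fibre families, Neo-Hookean nucleus) that are
#' carried verbatim into the Abaqus INP export. For the in-package
#' linear-elastic proxy the hyperelastic structures are mapped to documented
#' linear surrogates: E = 6 C10 (1 + nu) at near-incompressible nu = 0.499.
#'
#' @param overrides Named list of `c(E, nu)` pairs overriding the per-label
#'   defaults (labels as in the mesh: `cancellous`, `cortical`, `cep_upper`,
#'   `cep_lower`, `annulus_layer_1` .. `7`, `nucleus`,
#'   `facet_cartilage_left/right`).
#' @return A list of class `material_set`.
#' @export
material_set <- function(overrides = NULL) {
  nu_incomp <- 0.499
  hyper <- list(
    annulus = c(C10 = 0.34, D = 0.306, K1 = 1.81, K2 = 11, kappa = 0),
    nucleus = c(C10 = 0.16, D = 0.024))
  lin <- list(
    cancellous = c(E = 100, nu = 0.2),
    cortical   = c(E = 12000, nu = 0.3),
    cep_upper  = c(E = 23, nu = 0.4),
    cep_lower  = c(E = 23, nu = 0.4),
    facet_cartilage_left  = c(E = 35, nu = 0.4),
    facet_cartilage_right = c(E = 35, nu = 0.4),
    nucleus = c(E = 6 * hyper$nucleus[["C10"]] * (1 + nu_incomp), nu = nu_incomp))
  for (k in paste0("annulus_layer_", 1:7)) {
    lin[[k]] <- c(E = 6 * hyper$annulus[["C10"]] * (1 + nu_incomp), nu = nu_incomp)
  }
  if (!is.null(overrides)) {
    for (k in names(overrides)) lin[[k]] <- overrides[[k]]
  }
  eltype <- c(cancellous = "C3D8R", cortical = "C3D8R",
              cep_upper = "C3D8R", cep_lower = "C3D8R",
              facet_cartilage_left = "C3D8R", facet_cartilage_right = "C3D8R",
              nucleus = "C3D8RH",
              setNames(rep("C3D8", 7), paste0("annulus_layer_", 1:7)))
  structure(list(linear = lin, hyper = hyper, fibre_angle = 30,
                 element_type = eltype),
            class = "material_set")
}

#' Axial load case
#'
#' A total resultant force applied as a uniformly distributed pressure on
#' the upper bony endplate, with the bottom endplate fixed. Face and node
#' sets are detected geometrically (outward normal direction and height
#' band) unless supplied.
#'
#' @param total_force Total resultant force in N (default 400).
#' @param fixed_mode `"encastre"` fixes all DOF of the bottom endplate
#'   nodes; `"rollers"` fixes only the axial DOF (plus the minimal in-plane
#'   constraints that remove rigid-body motion), which leaves uniaxial
#'   patch-test states exactly representable.
#' @return A list of class `load_case`.
#' @export
load_case <- function(total_force = 400, fixed_mode = c("encastre", "rollers")) {
  fixed_mode <- match.arg(fixed_mode)
  check_scalar(total_force, "total_force", lower = 0)
  structure(list(total_force = total_force, fixed_mode = fixed_mode),
            class = "load_case")
}

# trilinear hex: corner signs in the element's natural coordinates
hex_corners <- matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1,  -1, 1, -1,
                        -1, -1,  1,  1, -1,  1,  1, 1,  1,  -1, 1,  1),
                      ncol = 3, byrow = TRUE)

# shape-function gradient (8 x 3) w.r.t. natural coords at (xi, eta, ze)
hex_dN <- function(xi, eta, ze) {
  s <- hex_corners
  cbind(s[, 1] * (1 + s[, 2] * eta) * (1 + s[, 3] * ze),
        (1 + s[, 1] * xi) * s[, 2] * (1 + s[, 3] * ze),
        (1 + s[, 1] * xi) * (1 + s[, 2] * eta) * s[, 3]) / 8
}

#' Screen hexahedral element quality
#'
#' Computes corner Jacobian determinants and the scaled Jacobian (determinant
#' over the product of the three corner edge lengths) for every element. A
#' mesh is invalid if any corner Jacobian is non-positive or the minimum
#' scaled Jacobian falls below `floor`.
#'
#' @param mesh An `fsu_mesh`.
#' @param floor Minimum acceptable scaled Jacobian (default 0.05).
#' @return List: `valid` flag and `metrics` (min corner Jacobian, min scaled
#'   Jacobian, fraction of elements with non-positive corner Jacobians).
#' @export
screen_quality <- function(mesh, floor = 0.05) {
  dN_corners <- lapply(seq_len(8), function(k) {
    hex_dN(hex_corners[k, 1], hex_corners[k, 2], hex_corners[k, 3])
  })
  ne <- nrow(mesh$hexes)
  min_det <- rep(Inf, ne); min_scaled <- rep(Inf, ne)
  Xx <- matrix(mesh$nodes[mesh$hexes, 1], ne, 8)
  Xy <- matrix(mesh$nodes[mesh$hexes, 2], ne, 8)
  Xz <- matrix(mesh$nodes[mesh$hexes, 3], ne, 8)
  for (k in seq_len(8)) {
    dN <- dN_corners[[k]]
    # Jacobian rows for all elements at once: J = dN' X_e
    a1 <- Xx %*% dN[, 1]; a2 <- Xy %*% dN[, 1]; a3 <- Xz %*% dN[, 1]
    b1 <- Xx %*% dN[, 2]; b2 <- Xy %*% dN[, 2]; b3 <- Xz %*% dN[, 2]
    c1 <- Xx %*% dN[, 3]; c2 <- Xy %*% dN[, 3]; c3 <- Xz %*% dN[, 3]
    det <- a1 * (b2 * c3 - b3 * c2) - a2 * (b1 * c3 - b3 * c1) +
      a3 * (b1 * c2 - b2 * c1)
    la <- sqrt(a1^2 + a2^2 + a3^2)
    lb <- sqrt(b1^2 + b2^2 + b3^2)
    lc <- sqrt(c1^2 + c2^2 + c3^2)
    scaled <- det / pmax(la * lb * lc, 1e-300)
    min_det <- pmin(min_det, det)
    min_scaled <- pmin(min_scaled, scaled)
  }
  inv_frac <- mean(min_det <= 0)
  valid <- all(min_det > 0) && min(min_scaled) >= floor
  list(valid = valid,
       metrics = list(min_corner_jacobian = min(min_det),
                      min_scaled_jacobian = min(min_scaled),
                      inverted_fraction = inv_frac))
}

# isotropic linear elasticity matrix, Voigt order (xx,yy,zz,xy,yz,xz),
# engineering shear strains
elastic_D <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  D[1:3, 1:3] <- D[1:3, 1:3] + lam
  D
}

# boundary faces of a hex mesh: faces occurring exactly once, with outward
# orientation. Returns a list of 4-column node-index matrices + element ids.
hex_faces_local <- matrix(c(1, 4, 3, 2,   # -zeta (bottom), outward -z
                            5, 6, 7, 8,   # +zeta
                            1, 2, 6, 5,   # -eta
                            3, 4, 8, 7,   # +eta
                            2, 3, 7, 6,   # +xi
                            4, 1, 5, 8),  # -xi
                          ncol = 4, byrow = TRUE)

boundary_faces <- function(mesh) {
  ne <- nrow(mesh$hexes)
  faces <- do.call(rbind, lapply(seq_len(6), function(f) {
    mesh$hexes[, hex_faces_local[f, ], drop = FALSE]
  }))
  elem <- rep(seq_len(ne), times = 6)
  locf <- rep(seq_len(6), each = ne)
  key <- apply(faces, 1, function(r) paste(sort(r), collapse = "_"))
  once <- names(which(table(key) == 1))
  sel <- key %in% once
  list(nodes = faces[sel, , drop = FALSE], elem = elem[sel], face = locf[sel])
}

face_geometry <- function(nodes, face_nodes) {
  # area and unit outward normal of each bilinear quad face (2x2 Gauss)
  g <- 1 / sqrt(3)
  gp <- rbind(c(-g, -g), c(g, -g), c(g, g), c(-g, g))
  nf <- nrow(face_nodes)
  area <- numeric(nf); normal <- matrix(0, nf, 3)
  Xd <- lapply(1:3, function(d) matrix(nodes[face_nodes, d], nf, 4))
  s <- matrix(c(-1, -1, 1, -1, 1, 1, -1, 1), ncol = 2, byrow = TRUE)
  for (q in seq_len(4)) {
    xi <- gp[q, 1]; eta <- gp[q, 2]
    dNxi <- s[, 1] * (1 + s[, 2] * eta) / 4
    dNeta <- (1 + s[, 1] * xi) * s[, 2] / 4
    t1 <- vapply(Xd, function(Xc) as.numeric(Xc %*% dNxi), numeric(nf))
    t2 <- vapply(Xd, function(Xc) as.numeric(Xc %*% dNeta), numeric(nf))
    t1 <- matrix(t1, nf, 3); t2 <- matrix(t2, nf, 3)
    cr <- cbind(t1[, 2] * t2[, 3] - t1[, 3] * t2[, 2],
                t1[, 3] * t2[, 1] - t1[, 1] * t2[, 3],
                t1[, 1] * t2[, 2] - t1[, 2] * t2[, 1])
    w <- sqrt(rowSums(cr^2))
    area <- area + w
    normal <- normal + cr
  }
  normal <- normal / pmax(sqrt(rowSums(normal^2)), 1e-300)
  list(area = area, normal = normal)
}

# detect loaded (top) and fixed (bottom) boundary face/node sets by outward
# normal direction and height band
detect_axial_sets <- function(mesh, bone_only = TRUE) {
  bf <- boundary_faces(mesh)
  geo <- face_geometry(mesh$nodes, bf$nodes)
  zc <- rowMeans(matrix(mesh$nodes[bf$nodes, 3], nrow(bf$nodes), 4))
  zr <- range(mesh$nodes[, 3])
  on_bone <- if (bone_only && any(mesh$labels %in% c("cortical", "cancellous"))) {
    mesh$labels[bf$elem] %in% c("cortical", "cancellous")
  } else TRUE
  top <- which(geo$normal[, 3] > 0.7 & zc > zr[1] + 0.85 * diff(zr) & on_bone)
  bottom <- which(geo$normal[, 3] < -0.7 & zc < zr[1] + 0.15 * diff(zr) & on_bone)
  if (!length(top)) stopf("no loadable top endplate faces found")
  if (!length(bottom)) stopf("no bottom endplate faces found")
  list(load_faces = bf$nodes[top, , drop = FALSE],
       fixed_nodes = sort(unique(as.integer(bf$nodes[bottom, ]))))
}

#' Linear-elastic axial compression solve
#'
#' Assembles the trilinear 8-node hexahedral stiffness (full 2x2x2 Gauss
#' quadrature) with per-structure linear materials, applies the total force
#' as a uniform pressure over the upper bony endplate (consistent nodal
#' loads), fixes the bottom endplate and solves the sparse symmetric system.
#' The IDP proxy is the maximum hydrostatic pressure `-tr(sigma)/3` over
#' nucleus-element quadrature points. The FCP proxy is a penalty surrogate:
#' the post-deformation facet gap closure times a penalty stiffness, divided
#' by the deformed pad contact area, maximised over the left and right pads.
#'
#' @param mesh An `fsu_mesh` that passed [screen_quality()].
#' @param materials A [material_set()]. Meshes without structure labels known
#'   to the set raise an error.
#' @param load A [load_case()].
#' @param penalty_stiffness Facet penalty stiffness (N/mm) for the FCP
#'   surrogate.
#' @param screen Run the element-quality screen first (default TRUE) and
#'   refuse invalid meshes with a status instead of solving.
#' @param quality_floor Scaled-Jacobian floor passed to [screen_quality()].
#' @return A list of class `simulation_result`: `idp`, `fcp` (MPa), `valid`,
#'   `failure_reason`, `displacement` (n x 3), `reaction_force` (net applied
#'   force recovered at the fixed nodes), plus the detected sets.
#' @export
solve_axial <- function(mesh, materials = material_set(), load = load_case(),
                        penalty_stiffness = 140, screen = TRUE,
                        quality_floor = 0.05) {
  if (screen) {
    q <- screen_quality(mesh, floor = quality_floor)
    if (!q$valid) {
      return(structure(list(idp = NA_real_, fcp = NA_real_, valid = FALSE,
                            failure_reason = "element quality",
                            quality = q$metrics),
                       class = "simulation_result"))
    }
  }
  labs <- unique(mesh$labels)
  unknown <- setdiff(labs, names(materials$linear))
  if (length(unknown)) stopf("no material for labels: %s",
                             paste(unknown, collapse = ", "))

  sets <- detect_axial_sets(mesh)
  n <- nrow(mesh$nodes); ndof <- 3L * n
  K <- assemble_stiffness(mesh, materials)

  # consistent pressure loads on top faces; pressure set so the integrated
  # traction equals total_force exactly
  geo <- face_geometry(mesh$nodes, sets$load_faces)
  area_total <- sum(geo$area)
  P <- load$total_force / area_total
  f <- numeric(ndof)
  fl <- face_loads(mesh$nodes, sets$load_faces, P)
  agg <- rowsum(fl$value, fl$dof)            # accumulate shared-node entries
  f[as.integer(rownames(agg))] <- agg[, 1]

  fixed_dof <- fixed_dofs(mesh, sets$fixed_nodes, load$fixed_mode)
  free <- setdiff(seq_len(ndof), fixed_dof)
  u <- numeric(ndof)
  Kff <- K[free, free, drop = FALSE]
  u[free] <- as.numeric(Matrix::solve(Kff, f[free]))

  # reactions at fixed DOF: r = K u - f
  r <- as.numeric(K %*% u) - f
  reaction_z <- sum(r[fixed_dof[fixed_dof %% 3 == 0]])

  U <- matrix(u, ncol = 3, byrow = TRUE)
  idp <- nucleus_peak_pressure(mesh, materials, U)
  fcp <- facet_pressure(mesh, U, penalty_stiffness)

  structure(list(idp = idp, fcp = fcp, valid = TRUE,
                 failure_reason = NULL, displacement = U,
                 reaction_force = reaction_z, applied_force = load$total_force,
                 pressure = P, sets = sets),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<simulation_result> IDP = %.4f MPa, FCP = %.4f MPa\n",
                x$idp, x$fcp))
  } else {
    cat(sprintf("<simulation_result> INVALID (%s)\n", x$failure_reason))
  }
  invisible(x)
}

# assemble the global sparse stiffness (triplet accumulation)
assemble_stiffness <- function(mesh, materials) {
  g <- 1 / sqrt(3)
  gp <- as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), ze = c(-g, g)))
  dN_gp <- lapply(seq_len(8), function(q) hex_dN(gp[q, 1], gp[q, 2], gp[q, 3]))
  Dmats <- lapply(materials$linear, function(m) elastic_D(m[["E"]], m[["nu"]]))

  ne <- nrow(mesh$hexes)
  iidx <- vector("list", ne); jidx <- vector("list", ne); vals <- vector("list", ne)
  for (e in seq_len(ne)) {
    en <- mesh$hexes[e, ]
    Xe <- mesh$nodes[en, , drop = FALSE]
    D <- Dmats[[mesh$labels[e]]]
    ke <- matrix(0, 24, 24)
    for (q in seq_len(8)) {
      dN <- dN_gp[[q]]
      J <- crossprod(dN, Xe)                 # 3x3, J[i,j] = dx_j/dxi_i
      detJ <- det(J)
      if (detJ <= 0) stopf("non-positive Jacobian in element %d", e)
      dNx <- t(solve(J, t(dN)))              # 8x3 global gradients
      B <- matrix(0, 6, 24)
      ix <- seq(1, 24, by = 3)
      B[1, ix] <- dNx[, 1]
      B[2, ix + 1] <- dNx[, 2]
      B[3, ix + 2] <- dNx[, 3]
      B[4, ix] <- dNx[, 2]; B[4, ix + 1] <- dNx[, 1]
      B[5, ix + 1] <- dNx[, 3]; B[5, ix + 2] <- dNx[, 2]
      B[6, ix] <- dNx[, 3]; B[6, ix + 2] <- dNx[, 1]
      ke <- ke + crossprod(B, D %*% B) * detJ
    }
    dof <- as.integer(rbind(3 * en - 2, 3 * en - 1, 3 * en))
    iidx[[e]] <- rep(dof, times = 24)
    jidx[[e]] <- rep(dof, each = 24)
    vals[[e]] <- as.numeric(ke)
  }
  ndof <- 3L * nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(i = unlist(iidx), j = unlist(jidx),
                            x = unlist(vals), dims = c(ndof, ndof))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

# consistent nodal forces for uniform pressure P on quad faces (outward
# normals); traction = -P * n
face_loads <- function(nodes, face_nodes, P) {
  g <- 1 / sqrt(3)
  gp <- rbind(c(-g, -g), c(g, -g), c(g, g), c(-g, g))
  s <- matrix(c(-1, -1, 1, -1, 1, 1, -1, 1), ncol = 2, byrow = TRUE)
  nf <- nrow(face_nodes)
  F <- array(0, dim = c(nf, 4, 3))
  Xd <- lapply(1:3, function(d) matrix(nodes[face_nodes, d], nf, 4))
  for (q in seq_len(4)) {
    xi <- gp[q, 1]; eta <- gp[q, 2]
    N <- (1 + s[, 1] * xi) * (1 + s[, 2] * eta) / 4
    dNxi <- s[, 1] * (1 + s[, 2] * eta) / 4
    dNeta <- (1 + s[, 1] * xi) * s[, 2] / 4
    t1 <- matrix(vapply(Xd, function(Xc) as.numeric(Xc %*% dNxi),
                        numeric(nf)), nf, 3)
    t2 <- matrix(vapply(Xd, function(Xc) as.numeric(Xc %*% dNeta),
                        numeric(nf)), nf, 3)
    cr <- cbind(t1[, 2] * t2[, 3] - t1[, 3] * t2[, 2],
                t1[, 3] * t2[, 1] - t1[, 1] * t2[, 3],
                t1[, 1] * t2[, 2] - t1[, 2] * t2[, 1])   # n dA
    for (a in seq_len(4)) {
      F[, a, ] <- F[, a, ] - P * N[a] * cr
    }
  }
  vals <- numeric(12 * nf)
  dof <- integer(12 * nf)
  k <- 1L
  for (fidx in seq_len(nf)) {
    for (a in seq_len(4)) {
      nd <- face_nodes[fidx, a]
      vals[k:(k + 2)] <- F[fidx, a, ]
      dof[k:(k + 2)] <- c(3 * nd - 2, 3 * nd - 1, 3 * nd)
      k <- k + 3L
    }
  }
  list(dof = dof, value = vals)
}

fixed_dofs <- function(mesh, fixed_nodes, mode) {
  if (mode == "encastre") {
    as.integer(rbind(3 * fixed_nodes - 2, 3 * fixed_nodes - 1, 3 * fixed_nodes))
  } else {
    xz <- mesh$nodes[fixed_nodes, , drop = FALSE]
    tolx <- 1e-8 * max(diff(range(xz[, 1])), 1)
    toly <- 1e-8 * max(diff(range(xz[, 2])), 1)
    xmin_nodes <- fixed_nodes[xz[, 1] <= min(xz[, 1]) + tolx]
    ymin_nodes <- fixed_nodes[xz[, 2] <= min(xz[, 2]) + toly]
    sort(unique(c(3L * fixed_nodes,               # uz = 0 on bottom
                  3L * xmin_nodes - 2L,           # ux = 0 on one bottom edge
                  3L * ymin_nodes - 1L)))         # uy = 0 on one bottom edge
  }
}

# max hydrostatic pressure over nucleus-element Gauss points
nucleus_peak_pressure <- function(mesh, materials, U, label = "nucleus") {
  sel <- which(mesh$labels == label)
  if (!length(sel)) sel <- seq_len(nrow(mesh$hexes))   # homogeneous meshes
  g <- 1 / sqrt(3)
  gp <- as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), ze = c(-g, g)))
  dN_gp <- lapply(seq_len(8), function(q) hex_dN(gp[q, 1], gp[q, 2], gp[q, 3]))
  best <- -Inf
  for (e in sel) {
    en <- mesh$hexes[e, ]
    Xe <- mesh$nodes[en, , drop = FALSE]
    Ue <- U[en, , drop = FALSE]
    m <- materials$linear[[mesh$labels[e]]]
    lam <- m[["E"]] * m[["nu"]] / ((1 + m[["nu"]]) * (1 - 2 * m[["nu"]]))
    mu <- m[["E"]] / (2 * (1 + m[["nu"]]))
    for (q in seq_len(8)) {
      dN <- dN_gp[[q]]
      J <- crossprod(dN, Xe)
      dNx <- t(solve(J, t(dN)))
      G <- crossprod(Ue, dNx)                 # 3x3 displacement gradient'
      tr_eps <- sum(diag(G))
      # tr(sigma) = (3 lam + 2 mu) tr(eps)
      pressure <- -(3 * lam + 2 * mu) * tr_eps / 3
      if (pressure > best) best <- pressure
    }
  }
  best
}

# penalty facet-contact pressure from deformed pad gap closure
facet_pressure <- function(mesh, U, penalty_stiffness) {
  fi <- mesh$facet_info
  if (is.null(fi)) return(0)
  def <- mesh$nodes + U
  side_fcp <- vapply(c("left", "right"), function(side) {
    up <- fi[[paste0("upper_", side)]]; lo <- fi[[paste0("lower_", side)]]
    gap0 <- mean(mesh$nodes[up$contact, 3]) - mean(mesh$nodes[lo$contact, 3])
    gap_def <- mean(def[up$contact, 3]) - mean(def[lo$contact, 3])
    closure <- gap0 - gap_def
    width <- diff(range(def[up$contact, 1]))
    depth <- abs(mean(def[up$contact, 2]) - mean(def[up$attach_rim, 2]))
    area <- width * depth
    penalty_stiffness * max(closure, 0) / area
  }, 0)
  max(side_fcp)
}

#' Screen and solve a cohort of meshes
#'
#' Runs quality screening and the axial solve per subject; screening
#' failures carry `valid = FALSE` with the reason and are excluded from
#' downstream analysis. Deterministic: two runs on the same cohort give
#' identical results.
#'
#' @param meshes List of `fsu_mesh`.
#' @param materials A [material_set()].
#' @param load A [load_case()].
#' @param subject_ids Optional character vector of ids.
#' @param ... Passed to [solve_axial()].
#' @return A tibble: `subject_id`, `idp`, `fcp`, `valid`, `failure_reason`.
#' @export
batch_simulate <- function(meshes, materials = material_set(),
                           load = load_case(), subject_ids = NULL, ...) {
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("synth_%03d", seq_along(meshes))
  }
  rows <- lapply(seq_along(meshes), function(i) {
    res <- solve_axial(meshes[[i]], materials, load, ...)
    tibble::tibble(subject_id = subject_ids[i],
                   idp = res$idp, fcp = res$fcp, valid = res$valid,
                   failure_reason = res$failure_reason %||% NA_character_)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "failure_fraction") <- mean(!out$valid)
  out
}
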