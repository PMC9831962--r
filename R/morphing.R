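#' Build the mean volumetric template mesh
#'
#' Applies each subject's Procrustes transform (estimated on the surface
#' points) to all nodes of its volumetric mesh, then averages node positions.
#' Connectivity, labels and the surface index are carried over unchanged.
#'
#' @param volumes List of `fsu_mesh` sharing one connectivity.
#' @param aligned The `aligned_cohort` whose transforms are reused.
#' @return An `fsu_mesh` whose surface nodes coincide with the SSM mean shape
#'   of the aligned cohort.
#' @export
build_template <- function(volumes, aligned) {
  if (length(volumes) != length(aligned$transforms)) {
    stopf("cohort size mismatch: %d volumes vs %d transforms",
          length(volumes), length(aligned$transforms))
  }
  ref <- volumes[[1]]
  for (v in volumes[-1]) {
    if (!identical(dim(v$hexes), dim(ref$hexes)) ||
        !identical(v$hexes, ref$hexes)) {
      stopf("volumetric meshes do not share connectivity")
    }
  }
  acc <- matrix(0, nrow(ref$nodes), 3)
  for (i in seq_along(volumes)) {
    acc <- acc + apply_transform(volumes[[i]], aligned$transforms[[i]])$nodes
  }
  nodes <- acc / length(volumes)
  colnames(nodes) <- c("x", "y", "z")
  new_fsu_mesh(nodes, ref$hexes, ref$labels, ref$surface_index,
               facet_info = ref$facet_info, meta = ref$meta)
}

#' Select TPS control points among the surface points
#'
#' Draws `c` distinct surface-point indices uniformly at random, once per
#' pipeline run; the same control set is reused for every synthetic subject.
#' With `stratify_by` a per-point structure factor, the draw is stratified
#' proportionally per structure instead.
#'
#' @param p Total surface point count.
#' @param c Number of control points (<= p). `c = p` returns the identity
#'   index set.
#' @param seed RNG seed.
#' @param stratify_by Optional factor of length `p` for per-structure
#'   stratified sampling.
#' @return Sorted integer vector of `c` distinct indices.
#' @export
select_control_points <- function(p, c, seed = 1L, stratify_by = NULL) {
  if (c > p) stopf("cannot select %d control points from %d surface points", c, p)
  if (c == p) return(seq_len(p))
  with_seed(seed, {
    if (is.null(stratify_by)) {
      sort(sample.int(p, c))
    } else {
      stopifnot(length(stratify_by) == p)
      grp <- split(seq_len(p), stratify_by)
      quota <- round(c * lengths(grp) / p)
      # fix rounding so quotas sum to c
      while (sum(quota) > c) quota[which.max(quota)] <- quota[which.max(quota)] - 1L
      while (sum(quota) < c) quota[which.max(lengths(grp) - quota)] <-
          quota[which.max(lengths(grp) - quota)] + 1L
      sort(unlist(Map(function(ids, q) sample(ids, min(q, length(ids))),
                      grp, quota), use.names = FALSE))
    }
  })
}

#' Fit a 3-D thin-plate-spline deformation field
#'
#' Solves the standard TPS linear system with the 3-D biharmonic kernel
#' `U(r) = r` plus an affine part, mapping `source` control points onto
#' `target` control points. At zero regularisation the field interpolates
#' the controls exactly; the kernel weights satisfy the side conditions
#' (zero sum and zero first moments).
#'
#' @param source,target c x 3 control point matrices (>= 4 non-coplanar
#'   points).
#' @param regularisation Smoothing scalar added to the kernel diagonal
#'   (default 0 = exact interpolation).
#' @return A list of class `tps_field`: `control_source`, `kernel_weights`
#'   (c x 3), `affine` (4 x 3: intercept + linear map), `regularisation`.
#' @export
tps_fit <- function(source, target, regularisation = 0) {
  check_points(source, "source"); check_points(target, "target")
  if (nrow(source) != nrow(target)) stopf("control point counts differ")
  ncp <- nrow(source)
  if (ncp < 4) stopf("need at least 4 control points")
  dup <- duplicated(round(source, 10))
  if (any(dup)) {
    stopf("duplicate control points at rows: %s",
          paste(which(dup), collapse = ", "))
  }
  if (qr(sweep(source, 2, colMeans(source)))$rank < 3) {
    stopf("control points are coplanar: TPS system singular")
  }
  K <- as.matrix(dist(source))          # U(r) = r
  if (regularisation > 0) K <- K + diag(regularisation, ncp)
  P <- cbind(1, source)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(target, matrix(0, 4, 3))
  sol <- solve(A, rhs)
  sol <- sol + solve(A, rhs - A %*% sol)   # one iterative-refinement step
  structure(list(control_source = source,
                 kernel_weights = sol[seq_len(ncp), , drop = FALSE],
                 affine = sol[ncp + 1:4, , drop = FALSE],
                 regularisation = regularisation),
            class = "tps_field")
}

#' Evaluate a TPS field at arbitrary points
#'
#' @param field A `tps_field`.
#' @param points n x 3 matrix.
#' @return n x 3 matrix of mapped points.
#' @export
tps_apply <- function(field, points) {
  check_points(points)
  n <- nrow(points); cs <- field$control_source
  # n x c distance matrix in blocks to bound memory
  out <- cbind(1, points) %*% field$affine
  block <- max(1L, floor(2e7 / nrow(cs)))
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(n, start + block - 1L)
    # per-coordinate differences: exact at control points (no cancellation)
    U <- sqrt(outer(points[idx, 1], cs[, 1], `-`)^2 +
              outer(points[idx, 2], cs[, 2], `-`)^2 +
              outer(points[idx, 3], cs[, 3], `-`)^2)
    out[idx, ] <- out[idx, ] + U %*% field$kernel_weights
  }
  colnames(out) <- c("x", "y", "z")
  out
}

#' Morph a volumetric template through a TPS field
#'
#' Maps every node (surface and interior) of the template through the field,
#' preserving connectivity and labels, and reports the surface RMSE between
#' the morphed surface nodes and the target surface along with the fraction
#' of hexahedra whose corner Jacobians turned non-positive.
#'
#' @param template An `fsu_mesh` (typically from [build_template()]).
#' @param field A `tps_field` fitted on template surface control points.
#' @param target_surface Optional p x 3 matrix (or `fsu_shape`) of the full
#'   target surface for the warp-error report.
#' @return A list of class `morph_result`: `mesh` (morphed `fsu_mesh`),
#'   `surface_rmse` (mm, `NA` if no target given), `inverted_fraction`.
#' @export
morph_mesh <- function(template, field, target_surface = NULL) {
  nodes <- tps_apply(field, template$nodes)
  mesh <- new_fsu_mesh(nodes, template$hexes, template$labels,
                       template$surface_index,
                       facet_info = template$facet_info, meta = template$meta)
  srms <- NA_real_
  if (!is.null(target_surface)) {
    tgt <- if (inherits(target_surface, "fsu_shape")) target_surface$points
           else target_surface
    srms <- rmse_between(nodes[template$surface_index, , drop = FALSE], tgt)
  }
  q <- screen_quality(mesh)
  structure(list(mesh = mesh, surface_rmse = srms,
                 inverted_fraction = q$metrics$inverted_fraction),
            class = "morph_result")
}

#' Morph the template to a set of SSM-generated surfaces
#'
#' Convenience driver for a synthetic cohort: reconstructs each subject's
#' surface from its weight row, fits the TPS on the shared control set and
#' morphs the template, returning meshes plus a warp-error report.
#'
#' @param template An `fsu_mesh`.
#' @param model An `fsu_ssm`.
#' @param weights A `weight_matrix`.
#' @param control Integer index of control points among surface points (from
#'   [select_control_points()]).
#' @param regularisation TPS regularisation.
#' @return A list: `meshes` (list of `fsu_mesh`), `report` (tibble:
#'   subject, surface_rmse, inverted_fraction).
#' @export
morph_cohort <- function(template, model, weights, control,
                         regularisation = 0) {
  src <- template$nodes[template$surface_index, , drop = FALSE]
  n <- nrow(weights$values)
  meshes <- vector("list", n)
  rep_rows <- vector("list", n)
  for (i in seq_len(n)) {
    tgt <- ssm_reconstruct(model, weights$values[i, ],
                           subject_id = sprintf("synth_%03d", i))
    fld <- tps_fit(src[control, , drop = FALSE],
                   tgt$points[control, , drop = FALSE],
                   regularisation = regularisation)
    mr <- morph_mesh(template, fld, target_surface = tgt)
    meshes[[i]] <- mr$mesh
    rep_rows[[i]] <- tibble::tibble(subject = tgt$subject_id,
                                    surface_rmse = mr$surface_rmse,
                                    inverted_fraction = mr$inverted_fraction)
  }
  list(meshes = meshes, report = dplyr::bind_rows(rep_rows))
}
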