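#' Similarity (Procrustes) fit of one corresponded point set onto another
#'
#' Least-squares similarity registration of `source` onto `target` over
#' rotation, translation and (optionally) isotropic scale, for point sets in
#' known one-to-one correspondence. The rotation is the orthogonal Procrustes
#' (Kabsch/SVD) solution with reflections forbidden (`det(R) = +1`): anatomy
#' must not mirror. Scaling, when enabled, normalises the source centroid
#' size to the target centroid size.
#'
#' @param source,target `fsu_shape` objects or p x 3 matrices with equal
#'   point counts (>= 3 non-collinear points).
#' @param with_scaling Estimate an isotropic scale factor as well?
#' @return A list of class `similarity_transform` with fields `rotation`
#'   (3 x 3, `det = +1`), `translation` (length 3, mm), `scale` (positive
#'   scalar) and `rmse` (mm, the per-point root mean squared Euclidean
#'   distance after transformation).
#' @export
procrustes_fit <- function(source, target, with_scaling = TRUE) {
  A <- if (inherits(source, "fsu_shape")) source$points else source
  B <- if (inherits(target, "fsu_shape")) target$points else target
  check_points(A, "source"); check_points(B, "target")
  if (nrow(A) != nrow(B)) stopf("point counts differ (%d vs %d)", nrow(A), nrow(B))
  if (nrow(A) < 3) stopf("need at least 3 points")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  sa <- sqrt(sum(A0^2)); sb <- sqrt(sum(B0^2))
  if (sa < 1e-12 || sb < 1e-12) stopf("degenerate point set (zero centroid size)")
  H <- crossprod(A0, B0)
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * sv$d[1]) {
    stopf("collinear/degenerate point configuration: rotation not identifiable")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  s <- if (with_scaling) sb / sa else 1
  # x -> s * R x + t, with t chosen so centroids map onto each other
  tr <- cb - s * as.numeric(R %*% ca)
  mapped <- s * A %*% t(R) + matrix(tr, nrow(A), 3, byrow = TRUE)
  rmse <- rmse_between(mapped, B)
  structure(list(rotation = R, translation = tr, scale = s, rmse = rmse),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf(
    "<similarity_transform> rotation %.2f deg, scale %.4f, |t| = %.3f mm, rmse %.4g mm\n",
    ang, x$scale, sqrt(sum(x$translation^2)), x$rmse))
  invisible(x)
}

#' Apply a similarity transform to points or a volumetric mesh
#'
#' @param x An `fsu_shape`, `fsu_mesh`, or an n x 3 coordinate matrix.
#' @param transform A `similarity_transform` from [procrustes_fit()].
#' @return `x` with all coordinates mapped through
#'   `scale * rotation %*% x + translation`.
#' @export
apply_transform <- function(x, transform) {
  map <- function(P) {
    out <- transform$scale * P %*% t(transform$rotation) +
      matrix(transform$translation, nrow(P), 3, byrow = TRUE)
    colnames(out) <- c("x", "y", "z")
    out
  }
  if (inherits(x, "fsu_shape")) {
    new_fsu_shape(map(x$points), x$subject_id)
  } else if (inherits(x, "fsu_mesh")) {
    new_fsu_mesh(map(x$nodes), x$hexes, x$labels, x$surface_index,
                 facet_info = x$facet_info, meta = x$meta)
  } else {
    map(x)
  }
}

identity_transform <- function() {
  structure(list(rotation = diag(3), translation = numeric(3), scale = 1,
                 rmse = 0),
            class = "similarity_transform")
}

#' Align a corresponded cohort by Procrustes analysis
#'
#' Aligns every shape to a reference subject (by default the first sample) in
#' a single pass, removing rotation, translation and — when `with_scaling` is
#' on — size differences. The per-subject transforms are retained so they can
#' later be re-applied to the full volumetric meshes when building the mean
#' template. An optional iterative mode re-aligns to the evolving mean shape
#' until convergence.
#'
#' @param shapes A list of `fsu_shape` (or an `fsu_cohort`, whose shapes are
#'   used) with identical point counts.
#' @param reference Index or subject id of the alignment target. The
#'   reference itself is left untouched.
#' @param with_scaling Remove size differences (centroid-size normalisation)?
#' @param iterative If `TRUE`, iterate alignment against the evolving mean
#'   (generalised Procrustes); default is the single-pass
#'   align-to-first-sample procedure.
#' @param max_iter,tol Iteration controls for `iterative = TRUE`.
#' @return A list of class `aligned_cohort`: `shapes` (aligned), `transforms`
#'   (per subject `similarity_transform`), `reference_id`.
#' @export
align_cohort <- function(shapes, reference = 1L, with_scaling = TRUE,
                         iterative = FALSE, max_iter = 10L, tol = 1e-10) {
  if (inherits(shapes, "fsu_cohort")) shapes <- shapes$shapes
  if (length(shapes) < 2) stopf("need at least 2 shapes to align")
  pts <- lapply(shapes, function(s) if (inherits(s, "fsu_shape")) s$points else s)
  p <- nrow(pts[[1]])
  if (!all(vapply(pts, nrow, 0L) == p)) stopf("mismatched point counts across shapes")
  ids <- vapply(seq_along(shapes), function(i) {
    s <- shapes[[i]]
    if (inherits(s, "fsu_shape") && !is.na(s$subject_id)) s$subject_id
    else sprintf("shape_%03d", i)
  }, "")
  ref <- if (is.character(reference)) match(reference, ids) else as.integer(reference)
  if (is.na(ref) || ref < 1 || ref > length(shapes)) stopf("invalid reference")

  target <- pts[[ref]]
  fit_all <- function(target) {
    lapply(seq_along(pts), function(i) {
      if (!iterative && i == ref) identity_transform()
      else procrustes_fit(pts[[i]], target, with_scaling = with_scaling)
    })
  }
  transforms <- fit_all(target)
  aligned <- Map(function(P, tf) apply_transform(P, tf), pts, transforms)
  if (iterative) {
    for (it in seq_len(max_iter)) {
      mean_shape <- Reduce(`+`, aligned) / length(aligned)
      transforms_new <- lapply(pts, procrustes_fit, target = mean_shape,
                               with_scaling = with_scaling)
      aligned_new <- Map(function(P, tf) apply_transform(P, tf), pts,
                         transforms_new)
      delta <- max(mapply(function(a, b) max(abs(a - b)), aligned_new, aligned))
      transforms <- transforms_new; aligned <- aligned_new
      if (delta < tol) break
    }
  }
  structure(
    list(shapes = Map(new_fsu_shape, aligned, ids),
         transforms = transforms, reference_id = ids[ref],
         with_scaling = with_scaling),
    class = "aligned_cohort")
}

#' @export
print.aligned_cohort <- function(x, ...) {
  cat(sprintf("<aligned_cohort> %d shapes aligned to '%s' (%s scaling)\n",
              length(x$shapes), x$reference_id,
              if (x$with_scaling) "with" else "without"))
  invisible(x)
}

#' Serialise similarity transforms to JSON
#'
#' Writes rotations row-major with translation and scale, one record per
#' subject, so transforms can be re-applied outside R.
#'
#' @param aligned An `aligned_cohort`.
#' @param path Output file path.
#' @export
write_transforms_json <- function(aligned, path) {
  recs <- lapply(seq_along(aligned$transforms), function(i) {
    tf <- aligned$transforms[[i]]
    list(subject_id = aligned$shapes[[i]]$subject_id,
         rotation_row_major = as.numeric(t(tf$rotation)),
         translation = as.numeric(tf$translation),
         scale = tf$scale)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
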