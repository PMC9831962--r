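#' Write a hexahedral mesh as a legacy-ASCII VTK unstructured grid
#'
#' Cell data carries the structure label as an integer code; the legend is
#' written as a comment in the title line.
#'
#' @param mesh An `fsu_mesh`.
#' @param path Output `.vtk` path.
#' @export
write_vtk_mesh <- function(mesh, path) {
  labs <- sort(unique(mesh$labels))
  code <- match(mesh$labels, labs) + 100L   # offset clear of VTK cell-type ids
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               paste("fsu mesh; labels:", paste(labs, collapse = ",")),
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(mesh$nodes))), con)
  writeLines(apply(mesh$nodes, 1, function(r) paste(sprintf("%.17g", r),
                                                    collapse = " ")), con)
  ne <- nrow(mesh$hexes)
  writeLines(sprintf("CELLS %d %d", ne, 9L * ne), con)
  writeLines(apply(mesh$hexes - 1L, 1, function(r) paste(c(8L, r),
                                                         collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("12", ne), con)
  writeLines(c(sprintf("CELL_DATA %d", ne), "SCALARS structure int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(code), con)
  invisible(path)
}

#' Write a corresponded surface as an ASCII PLY point cloud
#'
#' @param shape An `fsu_shape` or p x 3 matrix.
#' @param path Output `.ply` path.
#' @export
write_ply_points <- function(shape, path) {
  P <- if (inherits(shape, "fsu_shape")) shape$points else shape
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(P)),
               "property double x", "property double y", "property double z",
               "end_header"), con)
  writeLines(apply(P, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = " ")), con)
  invisible(path)
}

# local hex face index -> Abaqus C3D8 face name
abaqus_face <- c("S1", "S2", "S3", "S5", "S4", "S6")

#' Export a labelled mesh as a complete Abaqus INP model
#'
#' Writes the full model of the axial-compression study: node and element
#' blocks (1-based, ascending), one element set per structure with its
#' element type (reduced-integration bone/cartilage, full-integration
#' annulus, hybrid nucleus), the complete material set — linear-elastic
#' bone and cartilage, Neo-Hookean nucleus, Holzapfel-Gasser-Ogden annulus
#' with alternating +/-30 degree fibre orientations per layer —, hard
#' frictionless surface-to-surface contact at the facet pads, the pressure
#' amplitude realising the total axial force on the upper bony endplate,
#' and the fully fixed bottom endplate. Structures share merged nodes, so
#' bonded interfaces need no tie constraints (noted in the deck).
#'
#' @param mesh An `fsu_mesh` with structure labels.
#' @param materials A [material_set()].
#' @param load A [load_case()].
#' @param path Output `.inp` path.
#' @return The path, invisibly.
#' @export
export_inp <- function(mesh, materials = material_set(), load = load_case(),
                       path) {
  if (any(!nzchar(mesh$labels)) || anyNA(mesh$labels)) {
    stopf("mesh has unlabelled elements")
  }
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("*HEADING", "L4/L5 FSU axial compression model (mm, N, MPa)")
  w("*NODE")
  w(sprintf("%d, %.17g, %.17g, %.17g", seq_len(nrow(mesh$nodes)),
            mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]))
  labs <- sort(unique(mesh$labels))
  for (lb in labs) {
    els <- which(mesh$labels == lb)
    type <- materials$element_type[[lb]] %||% "C3D8"
    w(sprintf("*ELEMENT, TYPE=%s, ELSET=%s", type, toupper(lb)))
    w(sprintf("%d, %s", els,
              apply(mesh$hexes[els, , drop = FALSE], 1, paste, collapse = ", ")))
  }
  # orientations for the fibre-reinforced annulus layers (alternating sign)
  w("*ORIENTATION, NAME=ORI_PLUS, SYSTEM=RECTANGULAR",
    "1, 0, 0, 0, 1, 0", "3, 30.",
    "*ORIENTATION, NAME=ORI_MINUS, SYSTEM=RECTANGULAR",
    "1, 0, 0, 0, 1, 0", "3, -30.")
  # sections
  for (lb in labs) {
    up <- toupper(lb)
    if (grepl("^annulus_layer_", lb)) {
      layer <- as.integer(sub("annulus_layer_", "", lb))
      ori <- if (layer %% 2 == 1) "ORI_PLUS" else "ORI_MINUS"
      w(sprintf("*SOLID SECTION, ELSET=%s, MATERIAL=ANNULUS, ORIENTATION=%s",
                up, ori))
    } else if (lb == "nucleus") {
      w(sprintf("*SOLID SECTION, ELSET=%s, MATERIAL=NUCLEUS", up))
    } else {
      w(sprintf("*SOLID SECTION, ELSET=%s, MATERIAL=%s", up, up))
    }
  }
  # materials
  lin_only <- setdiff(labs, c("nucleus", paste0("annulus_layer_", 1:7)))
  for (lb in lin_only) {
    m <- materials$linear[[lb]]
    w(sprintf("*MATERIAL, NAME=%s", toupper(lb)),
      "*ELASTIC", sprintf("%g, %g", m[["E"]], m[["nu"]]))
  }
  if ("nucleus" %in% labs) {
    hn <- materials$hyper$nucleus
    w("*MATERIAL, NAME=NUCLEUS", "*HYPERELASTIC, NEO HOOKE",
      sprintf("%g, %g", hn[["C10"]], hn[["D"]]))
  }
  if (any(grepl("^annulus_layer_", labs))) {
    ha <- materials$hyper$annulus
    w("*MATERIAL, NAME=ANNULUS",
      "*ANISOTROPIC HYPERELASTIC, HOLZAPFEL, LOCAL DIRECTIONS=1",
      sprintf("%g, %g, %g, %g, %g", ha[["C10"]], ha[["D"]], ha[["K1"]],
              ha[["K2"]], ha[["kappa"]]))
  }
  w("** bonded structures share merged nodes; no tie constraints required")
  # facet contact (hard, frictionless)
  fi <- mesh$facet_info
  if (!is.null(fi)) {
    upper_elems <- sort(unlist(lapply(fi[grepl("^upper", names(fi))],
                                      `[[`, "elems")))
    lower_elems <- sort(unlist(lapply(fi[grepl("^lower", names(fi))],
                                      `[[`, "elems")))
    if (length(upper_elems) && length(lower_elems)) {
      w("*ELSET, ELSET=FACET_UPPER_PADS")
      w(paste(upper_elems, collapse = ", "))
      w("*ELSET, ELSET=FACET_LOWER_PADS")
      w(paste(lower_elems, collapse = ", "))
      w("*SURFACE, NAME=FACET_UPPER_SURF, TYPE=ELEMENT",
        "FACET_UPPER_PADS, S1",
        "*SURFACE, NAME=FACET_LOWER_SURF, TYPE=ELEMENT",
        "FACET_LOWER_PADS, S2",
        "*SURFACE INTERACTION, NAME=FACET_CONTACT",
        "*SURFACE BEHAVIOR, PRESSURE-OVERCLOSURE=HARD",
        "*CONTACT PAIR, INTERACTION=FACET_CONTACT, TYPE=SURFACE TO SURFACE",
        "FACET_UPPER_SURF, FACET_LOWER_SURF")
    }
  }
  # boundary and load sets (geometric detection, as in the solver)
  sets <- detect_axial_sets(mesh)
  geo <- face_geometry(mesh$nodes, sets$load_faces)
  pressure <- load$total_force / sum(geo$area)
  w("*NSET, NSET=FIXED_BOTTOM")
  fx <- sets$fixed_nodes
  for (k in seq(1, length(fx), by = 12)) {
    w(paste(fx[k:min(k + 11, length(fx))], collapse = ", "))
  }
  # identify loaded faces as element/face pairs
  bf <- boundary_faces(mesh)
  w("*STEP", "*STATIC")
  lf_keys <- apply(sets$load_faces, 1, function(r) paste(sort(r), collapse = "_"))
  all_keys <- apply(bf$nodes, 1, function(r) paste(sort(r), collapse = "_"))
  idx <- match(lf_keys, all_keys)
  w("*DSLOAD")
  w(sprintf("%d, P%s, %.17g", bf$elem[idx], abaqus_face[bf$face[idx]], pressure))
  w("*BOUNDARY", "FIXED_BOTTOM, 1, 3, 0.")
  w("*OUTPUT, FIELD", "*ELEMENT OUTPUT", "S,", "*NODE OUTPUT", "U,",
    "*END STEP")
  invisible(path)
}

#' Read nodes, connectivity and labels back from an Abaqus INP file
#'
#' Minimal reader for decks written by [export_inp()]: parses `*NODE` and
#' `*ELEMENT` blocks. Used for round-trip verification.
#'
#' @param path INP file path.
#' @return A list: `nodes` (n x 3), `hexes` (ne x 8, ordered by element id),
#'   `labels` (lower-case elset names).
#' @export
read_inp <- function(path) {
  lines <- readLines(path)
  nodes <- NULL; elems <- list(); labels <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^\\*NODE\\s*$", ln, ignore.case = TRUE)) {
      j <- i + 1L
      while (j <= length(lines) && !startsWith(lines[j], "*")) j <- j + 1L
      block <- lines[(i + 1L):(j - 1L)]
      m <- do.call(rbind, strsplit(block, ",\\s*"))
      ids <- as.integer(m[, 1])
      nodes <- matrix(NA_real_, max(ids), 3)
      nodes[ids, ] <- apply(m[, 2:4, drop = FALSE], 2, as.numeric)
      i <- j
    } else if (grepl("^\\*ELEMENT\\s*,", ln, ignore.case = TRUE)) {
      elset <- sub(".*ELSET=([^,]+).*", "\\1", ln)
      j <- i + 1L
      while (j <= length(lines) && !startsWith(lines[j], "*")) j <- j + 1L
      block <- lines[(i + 1L):(j - 1L)]
      m <- do.call(rbind, strsplit(block, ",\\s*"))
      ids <- as.integer(m[, 1])
      conn <- matrix(as.integer(m[, 2:9]), ncol = 8)
      for (k in seq_along(ids)) {
        elems[[ids[k]]] <- conn[k, ]
        labels[[ids[k]]] <- tolower(elset)
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  ne <- length(elems)
  hexes <- do.call(rbind, elems)
  colnames(nodes) <- c("x", "y", "z")
  list(nodes = nodes, hexes = hexes,
       labels = unlist(labels))
}

#' Write a cohort to disk (surfaces, volumes, manifest, ground truth)
#'
#' @param cohort An `fsu_cohort`.
#' @param dir Output directory (created if needed).
#' @param volumes Write volumetric VTK meshes too? (surfaces are always
#'   written as PLY).
#' @export
write_cohort <- function(cohort, dir, volumes = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$shapes) {
    write_ply_points(s, file.path(dir, paste0(s$subject_id, ".ply")))
  }
  if (volumes) {
    for (i in seq_along(cohort$meshes)) {
      write_vtk_mesh(cohort$meshes[[i]],
                     file.path(dir, paste0(cohort$shapes[[i]]$subject_id, ".vtk")))
    }
  }
  manifest <- list(
    t = cohort$spec$t, p = cohort$spec$p,
    latent_dim = cohort$spec$latent_dim,
    latent_sd = cohort$spec$latent_sd,
    noise_sd = cohort$spec$noise_sd, size_sd = cohort$spec$size_sd,
    seed = cohort$spec$seed,
    subjects = vapply(cohort$shapes, `[[`, "", "subject_id"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  truth <- cohort$truth
  jsonlite::write_json(
    list(latent_weights = truth$latent_weights,
         response_coefficients = truth$response_coefficients,
         true_importance_ranking = truth$true_importance_ranking,
         feature_baseline = as.list(truth$feature_baseline)),
    file.path(dir, "ground_truth.json"), digits = NA)
  invisible(dir)
}
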