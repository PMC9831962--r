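#' Pipeline configuration
#'
#' Bundles every stage's settings with a single global seed. The
#' `"paper"` scale reproduces the study conditions of the full workflow
#' (152 training subjects, 500 synthetic subjects sampled within +/-2 SD,
#' 1000 TPS control points, 400 N axial load, 1000 bootstrap iterations,
#' 1024 SHAP coalitions, 0.05 significance); the `"test"` scale runs the
#' identical pipeline on a smaller phantom cohort sized for minutes-scale
#' desk runs.
#'
#' @param scale `"test"` or `"paper"`.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param ... Named overrides of any top-level config entry.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(scale = c("test", "paper"), seed = 1L, ...) {
  scale <- match.arg(scale)
  base <- list(
    scale = scale,
    seed = as.integer(seed),
    phantom = if (scale == "paper") {
      list(t = 152L, nc = 46L, latent_sd = c(2.2, 0.8, 0.6, 0.45),
           noise_sd = 0.15, size_sd = 0.05)
    } else {
      list(t = 30L, nc = 18L, latent_sd = c(2.2, 0.8, 0.6, 0.45),
           noise_sd = 0.15, size_sd = 0.05)
    },
    alignment = list(reference = 1L, with_scaling = TRUE, iterative = FALSE),
    ssm = list(kaiser_factor = 0.7, n_specificity_samples = 500L,
               sd_trunc = 2),
    power = list(predictors = 30L, rho2 = 0.15, alpha = 0.05, power = 0.95),
    sampling = list(n_samples = if (scale == "paper") 500L else 60L,
                    sd_range = 2, criterion = "correlation_min"),
    morphing = list(n_control = if (scale == "paper") 1000L else 300L,
                    regularisation = 0),
    mechanics = list(total_force = 400, fixed_mode = "encastre",
                     penalty_stiffness = 140, quality_floor = 0.02,
                     material_overrides = NULL),
    uq = list(iterations = 1000L, level = 0.95, n_sizes = 8L),
    shap = list(n_coalitions = 1024L),
    significance_level = 0.05)
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      base[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  structure(base, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with top-level keys as in [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  scale <- y$scale %||% "test"
  seed <- y$seed %||% 1L
  y$scale <- NULL; y$seed <- NULL
  do.call(pipeline_config, c(list(scale = scale, seed = seed), y))
}

# deterministic per-stage seed derived from the global seed
stage_seed <- function(config, offset) {
  (config$seed * 1009L + offset * 9973L) %% 2147483647L
}

pipeline_stages <- c("generate-cohort", "align", "train-ssm", "evaluate-ssm",
                     "power", "sample", "morph", "simulate", "uq",
                     "sensitivity")

stage_artifacts <- list(
  "generate-cohort" = "cohort.rds",
  "align" = "aligned.rds",
  "train-ssm" = "ssm.rds",
  "evaluate-ssm" = "ssm_performance.rds",
  "power" = "power.json",
  "sample" = "weights.rds",
  "morph" = "morphed.rds",
  "simulate" = "sim_results.csv",
  "uq" = "uq_curves.rds",
  "sensitivity" = "sensitivity.rds")

stage_requires <- list(
  "generate-cohort" = character(0),
  "align" = "generate-cohort",
  "train-ssm" = "align",
  "evaluate-ssm" = "align",
  "power" = character(0),
  "sample" = "train-ssm",
  "morph" = c("generate-cohort", "align", "train-ssm", "sample"),
  "simulate" = "morph",
  "uq" = "simulate",
  "sensitivity" = c("sample", "simulate"))

load_artifact <- function(out_dir, stage) {
  f <- file.path(out_dir, stage_artifacts[[stage]])
  if (!file.exists(f)) {
    stopf("missing artifact for stage '%s' (%s): run stage '%s' first",
          stage, f, stage)
  }
  if (grepl("\\.rds$", f)) readRDS(f)
  else if (grepl("\\.json$", f)) jsonlite::read_json(f, simplifyVector = TRUE)
  else utils::read.csv(f, stringsAsFactors = FALSE)
}

write_manifest <- function(out_dir, stage, config, extra = list()) {
  man <- c(list(stage = stage,
                config_hash = rlang::hash(unclass(config)),
                seed = config$seed,
                package_version = as.character(utils::packageVersion("fsusens"))),
           extra)
  jsonlite::write_json(man,
                       file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA)
}

#' Run one pipeline stage
#'
#' Stages: `generate-cohort`, `align`, `train-ssm`, `evaluate-ssm`, `power`,
#' `sample`, `morph`, `simulate`, `uq`, `sensitivity`. Each stage reads its
#' upstream artifacts from `out_dir` (erroring with the name of the stage to
#' run first if missing), writes its own artifact plus a manifest (config
#' hash, seed, package version), and is bitwise reproducible given an
#' identical config.
#'
#' @param name Stage name.
#' @param config A [pipeline_config()].
#' @param out_dir Artifact directory (created if needed).
#' @return The stage's main result, invisibly.
#' @export
run_stage <- function(name, config, out_dir) {
  name <- match.arg(name, pipeline_stages)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (req in stage_requires[[name]]) {
    f <- file.path(out_dir, stage_artifacts[[req]])
    if (!file.exists(f)) {
      stopf("stage '%s' requires artifact of stage '%s': run '%s' first",
            name, req, req)
    }
  }
  res <- switch(
    name,
    "generate-cohort" = {
      ph <- config$phantom
      spec <- phantom_spec(t = ph$t, latent_sd = ph$latent_sd,
                           noise_sd = ph$noise_sd, size_sd = ph$size_sd,
                           seed = stage_seed(config, 1L), nc = ph$nc)
      cohort <- generate_cohort(spec)
      saveRDS(cohort, file.path(out_dir, "cohort.rds"))
      cohort
    },
    "align" = {
      cohort <- load_artifact(out_dir, "generate-cohort")
      al <- align_cohort(cohort$shapes,
                         reference = config$alignment$reference,
                         with_scaling = config$alignment$with_scaling,
                         iterative = config$alignment$iterative)
      saveRDS(al, file.path(out_dir, "aligned.rds"))
      write_transforms_json(al, file.path(out_dir, "transforms.json"))
      al
    },
    "train-ssm" = {
      al <- load_artifact(out_dir, "align")
      model <- ssm_fit(al, retain = "kaiser",
                       kaiser_factor = config$ssm$kaiser_factor)
      saveRDS(model, file.path(out_dir, "ssm.rds"))
      model
    },
    "evaluate-ssm" = {
      al <- load_artifact(out_dir, "align")
      perf <- ssm_evaluate(al,
                           n_specificity_samples = config$ssm$n_specificity_samples,
                           sd_trunc = config$ssm$sd_trunc,
                           seed = stage_seed(config, 4L))
      saveRDS(perf, file.path(out_dir, "ssm_performance.rds"))
      utils::write.csv(perf$per_mode_generalisation,
                       file.path(out_dir, "generalisation_curve.csv"),
                       row.names = FALSE)
      perf
    },
    "power" = {
      ps <- power_spec(predictors = config$power$predictors,
                       rho2 = config$power$rho2,
                       alpha = config$power$alpha,
                       power = config$power$power)
      n_min <- min_sample_size(ps)
      jsonlite::write_json(list(n_min = n_min, spec = unclass(ps)),
                           file.path(out_dir, "power.json"),
                           auto_unbox = TRUE, digits = NA)
      n_min
    },
    "sample" = {
      model <- load_artifact(out_dir, "train-ssm")
      w <- latin_hypercube(config$sampling$n_samples, model,
                           sd_range = config$sampling$sd_range,
                           criterion = config$sampling$criterion,
                           seed = stage_seed(config, 6L))
      saveRDS(w, file.path(out_dir, "weights.rds"))
      write_weights_csv(w, file.path(out_dir, "weights.csv"))
      w
    },
    "morph" = {
      cohort <- load_artifact(out_dir, "generate-cohort")
      al <- load_artifact(out_dir, "align")
      model <- load_artifact(out_dir, "train-ssm")
      w <- load_artifact(out_dir, "sample")
      template <- build_template(cohort$meshes, al)
      control <- select_control_points(length(template$surface_index),
                                       min(config$morphing$n_control,
                                           length(template$surface_index)),
                                       seed = stage_seed(config, 7L))
      mo <- morph_cohort(template, model, w, control,
                         regularisation = config$morphing$regularisation)
      saveRDS(list(meshes = mo$meshes, template = template,
                   control = control),
              file.path(out_dir, "morphed.rds"))
      utils::write.csv(mo$report, file.path(out_dir, "warp_report.csv"),
                       row.names = FALSE)
      mo
    },
    "simulate" = {
      mo <- load_artifact(out_dir, "morph")
      mats <- material_set(config$mechanics$material_overrides)
      lc <- load_case(config$mechanics$total_force,
                      config$mechanics$fixed_mode)
      res <- batch_simulate(mo$meshes, mats, lc,
                            penalty_stiffness = config$mechanics$penalty_stiffness,
                            quality_floor = config$mechanics$quality_floor)
      utils::write.csv(res, file.path(out_dir, "sim_results.csv"),
                       row.names = FALSE)
      res
    },
    "uq" = {
      res <- load_artifact(out_dir, "simulate")
      ok <- res[res$valid, , drop = FALSE]
      n_ok <- nrow(ok)
      sizes <- unique(round(seq(max(4, ceiling(n_ok / config$uq$n_sizes)),
                                n_ok, length.out = config$uq$n_sizes)))
      curves <- list(
        idp = ci_vs_sample_size(ok$idp, sizes,
                                iterations = config$uq$iterations,
                                level = config$uq$level,
                                seed = stage_seed(config, 9L)),
        fcp = ci_vs_sample_size(ok$fcp, sizes,
                                iterations = config$uq$iterations,
                                level = config$uq$level,
                                seed = stage_seed(config, 10L)))
      saveRDS(curves, file.path(out_dir, "uq_curves.rds"))
      write_bootstrap_curve(curves$idp, file.path(out_dir, "uq_idp.csv"),
                            file.path(out_dir, "uq_idp_density.json"))
      write_bootstrap_curve(curves$fcp, file.path(out_dir, "uq_fcp.csv"),
                            file.path(out_dir, "uq_fcp_density.json"))
      curves
    },
    "sensitivity" = {
      w <- load_artifact(out_dir, "sample")
      res <- load_artifact(out_dir, "simulate")
      rep <- sensitivity_report(
        w, res,
        config = shap_config(n_coalitions = config$shap$n_coalitions,
                             seed = stage_seed(config, 11L)),
        significance_level = config$significance_level)
      saveRDS(rep, file.path(out_dir, "sensitivity.rds"))
      utils::write.csv(rep$correlations,
                       file.path(out_dir, "correlations.csv"),
                       row.names = FALSE)
      utils::write.csv(rep$contributions,
                       file.path(out_dir, "contributions.csv"),
                       row.names = FALSE)
      rep
    })
  write_manifest(out_dir, name, config)
  invisible(res)
}

#' Run the full pipeline
#'
#' Executes every stage in order (cohort generation, alignment, SSM training
#' and evaluation, power analysis, Latin hypercube sampling, TPS morphing,
#' FE simulation, bootstrap UQ, sensitivity analysis) and returns the key
#' results.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Artifact directory.
#' @param stages Subset of stages to run (default all, in order).
#' @return Named list of stage results, invisibly.
#' @export
run_pipeline <- function(config, out_dir, stages = pipeline_stages) {
  out <- list()
  for (s in stages) out[[s]] <- run_stage(s, config, out_dir)
  invisible(out)
}
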