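#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_ribbon geom_tile labs scale_fill_gradient2 facet_wrap
#'   scale_y_continuous theme_minimal
#' @export
generics::tidy
#' @export
generics::glance
#' @export
ggplot2::autoplot

#' @describeIn ssm_fit Tidy per-mode summary: eigenvalue, explained and
#'   cumulative variance fraction, retention flag.
#' @param x An `fsu_ssm`.
#' @param ... Unused.
#' @export
tidy.fsu_ssm <- function(x, ...) {
  lam <- x$eigenvalues
  tibble::tibble(
    mode = seq_along(lam),
    eigenvalue = lam,
    variance_fraction = lam / x$lambda_total,
    cumulative_variance = cumsum(lam) / x$lambda_total,
    retained = seq_along(lam) <= x$retained)
}

#' @describeIn ssm_fit One-row model summary.
#' @export
glance.fsu_ssm <- function(x, ...) {
  tibble::tibble(
    n_shapes = x$t, n_points = x$p, n_modes = length(x$eigenvalues),
    retained = x$retained,
    lambda_total = x$lambda_total, lambda_bar = x$lambda_bar,
    compactness_retained = compactness(x, x$retained))
}

#' @describeIn ssm_fit Compactness curve (explained variance vs number of
#'   modes).
#' @param object An `fsu_ssm`.
#' @export
autoplot.fsu_ssm <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$mode, y = 100 * .data$cumulative_variance)) +
    geom_line() +
    geom_point(aes(shape = .data$retained)) +
    labs(x = "number of shape modes", y = "explained shape variation (%)",
         shape = "retained") +
    theme_minimal()
}

#' @describeIn ssm_evaluate Tidy metric table (mean and SD per measure).
#' @param x An `ssm_performance`.
#' @param ... Unused.
#' @export
tidy.ssm_performance <- function(x, ...) {
  tibble::tibble(
    measure = c("accuracy", "specificity", "generalisation"),
    mean_rmse = c(x$accuracy["mean"], x$specificity["mean"],
                  x$generalisation["mean"]),
    sd_rmse = c(x$accuracy["sd"], x$specificity["sd"],
                x$generalisation["sd"]),
    modes = x$M)
}

#' @describeIn ssm_evaluate Generalisation RMSE vs number of modes.
#' @param object An `ssm_performance`.
#' @export
autoplot.ssm_performance <- function(object, ...) {
  ggplot(object$per_mode_generalisation,
         aes(x = .data$modes, y = .data$rmse)) +
    geom_line() + geom_point() +
    labs(x = "number of shape modes", y = "generalisation RMSE (mm)") +
    theme_minimal()
}

#' @describeIn ci_vs_sample_size CI bounds and mean estimate vs sample size.
#' @param object A `bootstrap_curve`.
#' @param ... Unused.
#' @export
autoplot.bootstrap_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$size, y = .data$mean_estimate)) +
    geom_ribbon(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                alpha = 0.25) +
    geom_line() + geom_point() +
    labs(x = "sample size", y = "outcome mean (MPa)",
         title = sprintf("%d%% bootstrap CI of the mean",
                         round(100 * (attr(object, "level") %||% 0.95)))) +
    theme_minimal()
}

#' @describeIn sensitivity_report Tidy per-mode, per-outcome table combining
#'   correlations and SHAP contributions.
#' @param x A `sensitivity_report`.
#' @param ... Unused.
#' @export
tidy.sensitivity_report <- function(x, ...) {
  dplyr::left_join(x$correlations, x$contributions,
                   by = c("mode", "outcome"))
}

#' @describeIn sensitivity_report One row per outcome: valid n, top mode and
#'   its contribution, size of the important set.
#' @export
glance.sensitivity_report <- function(x, ...) {
  top <- dplyr::filter(x$contributions, .data$rank == 1L)
  tibble::tibble(
    outcome = top$outcome,
    n_valid = x$meta$n_valid,
    top_mode = top$mode,
    top_contribution_pct = top$contribution_pct,
    n_important = vapply(x$important[top$outcome], length, 0L))
}

#' @describeIn sensitivity_report Correlation heat map (insignificant cells
#'   blank) or contribution bars, per outcome.
#' @param object A `sensitivity_report`.
#' @param type `"correlation"` or `"contribution"`.
#' @export
autoplot.sensitivity_report <- function(object,
                                        type = c("correlation", "contribution"),
                                        ...) {
  type <- match.arg(type)
  if (type == "correlation") {
    d <- object$correlations
    d$r_shown <- ifelse(d$significant, d$pearson_r, NA_real_)
    ggplot(d, aes(x = .data$mode, y = .data$outcome, fill = .data$r_shown)) +
      geom_tile(colour = "grey80") +
      scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                           na.value = "white", limits = c(-1, 1)) +
      labs(x = "shape mode", y = NULL, fill = "r") +
      theme_minimal()
  } else {
    ggplot(object$contributions,
           aes(x = stats::reorder(.data$mode, .data$rank),
               y = .data$contribution_pct)) +
      geom_col() +
      facet_wrap(~outcome, scales = "free_x") +
      labs(x = "shape mode", y = "contribution (%)") +
      theme_minimal()
  }
}

#' @describeIn latin_hypercube Tidy long-format weight table.
#' @param x A `weight_matrix`.
#' @param ... Unused.
#' @export
tidy.weight_matrix <- function(x, ...) {
  d <- tibble::as_tibble(as.data.frame(x$values))
  d$sample <- seq_len(nrow(d))
  tidyr::pivot_longer(d, -"sample", names_to = "mode", values_to = "weight")
}

#' @importFrom rlang .data
NULL
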