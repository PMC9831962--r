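#' Percentile bootstrap confidence interval of the mean
#'
#' Resamples the data with replacement (`iterations` resamples of the
#' original size) and returns the percentile interval of the resampled
#' means. Deterministic given `seed`.
#'
#' @param values Numeric outcome vector (>= 2 values).
#' @param iterations Bootstrap iterations (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed RNG seed.
#' @return A list: `mean`, `ci_low`, `ci_high`, `boot_means` (the resampled
#'   means, for density summaries).
#' @export
bootstrap_ci <- function(values, iterations = 1000L, level = 0.95, seed = 1L) {
  values <- as.numeric(values)
  if (length(values) < 2) stopf("need at least 2 values")
  if (level <= 0 || level >= 1) stopf("level must be in (0, 1)")
  n <- length(values)
  boot_means <- with_seed(seed, {
    vapply(seq_len(iterations), function(b) {
      mean(values[sample.int(n, n, replace = TRUE)])
    }, 0)
  })
  alpha <- (1 - level) / 2
  ci <- unname(quantile(boot_means, c(alpha, 1 - alpha), type = 7))
  list(mean = mean(values), ci_low = ci[1], ci_high = ci[2],
       boot_means = boot_means)
}

#' Bootstrap confidence intervals over increasing sample sizes
#'
#' For each size, draws a fresh subsample without replacement from the
#' outcome vector and bootstraps the mean of that subsample, tracing how the
#' uncertainty of the mean estimate shrinks with sample size. When a size
#' equals the full sample size the subsample is the full sample, so the
#' endpoint matches [bootstrap_ci()] on the full data.
#'
#' @param values Numeric outcome vector.
#' @param sizes Increasing sample sizes, all `<= length(values)`.
#' @param iterations Bootstrap iterations per size.
#' @param level Confidence level.
#' @param seed RNG seed.
#' @return A tibble of class `bootstrap_curve`: `size`, `mean_estimate`,
#'   `ci_low`, `ci_high`, `ci_width`, plus a `densities` attribute (list of
#'   per-size kernel-density summaries of the bootstrap means).
#' @export
ci_vs_sample_size <- function(values, sizes, iterations = 1000L,
                              level = 0.95, seed = 1L) {
  values <- as.numeric(values)
  sizes <- as.integer(sizes)
  if (any(sizes > length(values))) {
    stopf("sizes exceed available data (%d)", length(values))
  }
  if (any(sizes < 2)) stopf("all sizes must be >= 2")
  rows <- vector("list", length(sizes))
  dens <- vector("list", length(sizes))
  with_seed(seed, {
    for (k in seq_along(sizes)) {
      nsub <- sizes[k]
      sub <- if (nsub == length(values)) values
             else values[sample.int(length(values), nsub)]
      bc <- bootstrap_ci(sub, iterations = iterations, level = level,
                         seed = sample.int(.Machine$integer.max, 1))
      rows[[k]] <- tibble::tibble(size = nsub, mean_estimate = bc$mean,
                                  ci_low = bc$ci_low, ci_high = bc$ci_high,
                                  ci_width = bc$ci_high - bc$ci_low)
      d <- stats::density(bc$boot_means)
      dens[[k]] <- list(size = nsub, x = d$x, y = d$y)
    }
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "densities") <- dens
  attr(out, "level") <- level
  class(out) <- c("bootstrap_curve", class(out))
  out
}

#' Write a bootstrap curve and its density summaries to disk
#'
#' @param curve A `bootstrap_curve`.
#' @param csv_path CSV output for the curve table.
#' @param json_path Optional JSON output for the per-size density summaries.
#' @export
write_bootstrap_curve <- function(curve, csv_path, json_path = NULL) {
  utils::write.csv(as.data.frame(curve), csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(attr(curve, "densities"), json_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
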