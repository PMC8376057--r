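# Accelerated (BCa) bootstrap for per-habitat mean electivity, the sign-based
# significance rule, and the minimum-sample gate.
#
# The per-habitat statistic is the mean of unit-level electivities. Unit
# vectors are resampled with replacement B times (default 1500); the interval
# is bias-corrected (z0, from the fraction of resampled means below the
# observed mean, ties weighted 0.5) and accelerated (a, from the jackknife
# third-moment formula), with adjusted percentiles read off the resampled
# means by linear interpolation between order statistics.

#' Bootstrap specification
#'
#' @param n_resamples number of bootstrap resamples (default 1500).
#' @param level confidence level (default 0.95).
#' @param seed integer master seed.
#' @param min_units minimum number of units for an interval to be computed
#'   (default 7): habitats observed in fewer units are reported untested, as
#'   smaller samples give unreliable intervals.
#' @return A list of class `bootstrap_spec`.
#' @export
bootstrap_spec <- function(n_resamples = 1500, level = 0.95, seed = 1L, min_units = 7) {
  stopifnot(n_resamples >= 1, level > 0, level < 1, min_units >= 2)
  structure(list(n_resamples = as.integer(n_resamples), level = level,
                 seed = as.integer(seed), min_units = as.integer(min_units)),
            class = "bootstrap_spec")
}

#' BCa confidence interval for a mean
#'
#' @param values numeric vector of unit-level statistics (e.g. electivities of
#'   one habitat across units).
#' @param spec a [bootstrap_spec()].
#' @return List of class `bootstrap_result`: `point_estimate`, `ci_low`,
#'   `ci_high`, `z0`, `a`, `n_units`, `tested`. With fewer than `min_units`
#'   values, `tested = FALSE` and the interval is `NA`. A zero-variance sample
#'   returns a point interval.
#' @export
bca_interval <- function(values, spec = bootstrap_spec()) {
  stopifnot(is.numeric(values), inherits(spec, "bootstrap_spec"))
  # sorted so the interval depends only on the multiset of values, not their
  # order (unit order in a table must not change a seeded resample)
  values <- sort(values[is.finite(values)])
  n <- length(values)
  obs <- mean(values)
  if (n < spec$min_units) {
    return(structure(list(point_estimate = obs, ci_low = NA_real_, ci_high = NA_real_,
                          z0 = NA_real_, a = NA_real_, n_units = n, tested = FALSE),
                     class = "bootstrap_result"))
  }
  if (stats::sd(values) == 0) {
    return(structure(list(point_estimate = obs, ci_low = obs, ci_high = obs,
                          z0 = 0, a = 0, n_units = n, tested = TRUE),
                     class = "bootstrap_result"))
  }
  B <- spec$n_resamples
  boot_means <- with_seed(spec$seed, {
    idx <- sample.int(n, n * B, replace = TRUE)
    rowMeans(matrix(values[idx], nrow = B, ncol = n))
  })
  # bias correction: ties with the observed mean count 0.5 to avoid z0 = +/-Inf
  # on discrete electivity sets; the fraction is clamped away from 0/1.
  p0 <- (sum(boot_means < obs) + 0.5 * sum(boot_means == obs)) / B
  p0 <- min(max(p0, 0.5 / B), 1 - 0.5 / B)
  z0 <- stats::qnorm(p0)
  # acceleration from jackknife leave-one-out means
  loo <- (sum(values) - values) / (n - 1)
  d <- mean(loo) - loo
  denom <- sum(d^2)^1.5
  a <- if (denom == 0) 0 else sum(d^3) / (6 * denom)
  alpha2 <- (1 - spec$level) / 2
  zlo <- stats::qnorm(alpha2)
  zhi <- stats::qnorm(1 - alpha2)
  adj <- function(z) stats::pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  ci <- unname(stats::quantile(boot_means, probs = c(adj(zlo), adj(zhi)), type = 7))
  structure(list(point_estimate = obs, ci_low = ci[1], ci_high = ci[2],
                 z0 = z0, a = a, n_units = n, tested = TRUE),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  if (x$tested) {
    cat(sprintf("mean %.4f, 95%% BCa CI [%.4f, %.4f] (n = %d, z0 = %.3f, a = %.3f)\n",
                x$point_estimate, x$ci_low, x$ci_high, x$n_units, x$z0, x$a))
  } else {
    cat(sprintf("mean %.4f, not tested (n = %d below the minimum-unit gate)\n",
                x$point_estimate, x$n_units))
  }
  invisible(x)
}

#' Significance from the signs of the confidence-interval endpoints
#'
#' A habitat's selection is significant only when both endpoints of the 95%
#' interval share a sign: both positive means preferred, both negative means
#' avoided; endpoints of opposite sign (or an endpoint exactly at 0,
#' conservatively) mean not significant.
#'
#' @param ci_low,ci_high interval endpoints.
#' @return `"preferred"`, `"avoided"` or `"not_significant"`.
#' @export
classify_significance <- function(ci_low, ci_high) {
  stopifnot(length(ci_low) == length(ci_high))
  if (any(ci_low > ci_high, na.rm = TRUE)) stop("ci_low must be <= ci_high", call. = FALSE)
  out <- ifelse(ci_low > 0 & ci_high > 0, "preferred",
         ifelse(ci_low < 0 & ci_high < 0, "avoided", "not_significant"))
  out[is.na(ci_low) | is.na(ci_high)] <- NA_character_
  out
}

#' Bootstrap all habitats of a long electivity table
#'
#' Runs [bca_interval()] on each habitat's unit-level electivities. Each
#' habitat draws from its own substream derived from the master seed and the
#' habitat code, so results are reproducible and independent of habitat order.
#'
#' @param long_table data.frame from [electivity_table()] (columns `habitat`,
#'   `epsilon`, `unit_id`).
#' @param spec a [bootstrap_spec()].
#' @return data.frame with one row per habitat: `habitat`, `mean_epsilon`,
#'   `ci_low`, `ci_high`, `n_units`, `tested`, `significance`
#'   (`not_tested` for gated habitats).
#' @export
bootstrap_all_habitats <- function(long_table, spec = bootstrap_spec()) {
  stopifnot(is.data.frame(long_table), all(c("habitat", "epsilon") %in% names(long_table)))
  if (!nrow(long_table)) stop("empty electivity table", call. = FALSE)
  habitats <- sort(unique(long_table$habitat))
  rows <- lapply(habitats, function(h) {
    vals <- long_table$epsilon[long_table$habitat == h]
    hspec <- spec
    hspec$seed <- substream_seed(spec$seed, paste0("bca/", h))
    res <- bca_interval(vals, hspec)
    data.frame(
      habitat = h, mean_epsilon = res$point_estimate,
      ci_low = res$ci_low, ci_high = res$ci_high, n_units = res$n_units,
      tested = res$tested,
      significance = if (res$tested) classify_significance(res$ci_low, res$ci_high) else "not_tested",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Bootstrap standard error of the median
#'
#' Percentile-method bootstrap: the SE is the standard deviation of the
#' resampled medians (1000 resamples by default). Undefined (returns `NA`)
#' for samples of fewer than 2 values.
#'
#' @param values numeric vector.
#' @param n_resamples number of resamples.
#' @param seed integer seed.
#' @return Standard error of the median, or `NA_real_`.
#' @export
boot_median_se <- function(values, n_resamples = 1000, seed = 1L) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) return(NA_real_)
  meds <- with_seed(seed, {
    idx <- sample.int(n, n * n_resamples, replace = TRUE)
    apply(matrix(values[idx], nrow = n_resamples), 1L, stats::median)
  })
  stats::sd(meds)
}
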