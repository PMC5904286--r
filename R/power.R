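# Exact power of the two-sided t test via the noncentral t distribution.
# For the two-sample pooled test with n per group, df = 2n - 2 and the
# noncentrality is (delta/sigma) * sqrt(n/2); for the paired test df = n - 1
# and ncp = (delta/sigma) * sqrt(n).
t_test_power <- function(n, effect_size, alpha = 0.05,
                         type = c("two.sample", "paired")) {
  type <- match.arg(type)
  if (type == "two.sample") {
    df <- 2 * n - 2
    ncp <- effect_size * sqrt(n / 2)
  } else {
    df <- n - 1
    ncp <- effect_size * sqrt(n)
  }
  tcrit <- qt(1 - alpha / 2, df)
  pt(-tcrit, df, ncp = ncp) + 1 - pt(tcrit, df, ncp = ncp)
}

#' Smallest detectable mean difference for a replicate design
#'
#' Given `n` replicates per group and a between-replicate variability of
#' `rsd_pct` (standard deviation as percent of the mean), returns the
#' smallest true mean difference — also as percent of the mean — that a
#' two-sided t test detects with the requested power. Power is evaluated
#' exactly through the noncentral t distribution and the difference solved by
#' root finding to 1e-6 relative tolerance. Because both the difference and
#' the SD are percentages of the same mean, the result is proportional to
#' `rsd_pct`.
#'
#' @param n Replicates per group (per pair for `type = "paired"`).
#' @param rsd_pct Replicate relative standard deviation, percent of mean.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @param type `"two.sample"` (pooled, default) or `"paired"`.
#'
#' @return Detectable difference as percent of the mean.
#' @examples
#' detectable_difference(n = 3, rsd_pct = 15) # ~46% of the mean
#' detectable_difference(n = 3, rsd_pct = 5)  # ~15%: the dPCR advantage
#' @export
detectable_difference <- function(n, rsd_pct, alpha = 0.05, power = 0.80,
                                  type = c("two.sample", "paired")) {
  type <- match.arg(type)
  if (n < 2 || n != round(n)) abort("`n` must be an integer >= 2.")
  if (rsd_pct <= 0) abort("`rsd_pct` must be positive.")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    abort("`alpha` and `power` must be in (0, 1).")
  }
  if (t_test_power(n, 1e6, alpha, type) < power) {
    abort("Requested power is unattainable at this design.")
  }
  # solve on the standardized effect-size scale, then rescale by the SD
  f <- function(d) t_test_power(n, d, alpha, type) - power
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  d <- uniroot(f, c(1e-12, upper), tol = 1e-10)$root
  d * rsd_pct
}

#' Replicates needed to detect a mean difference
#'
#' The smallest integer number of replicates per group for which the exact
#' noncentral-t power of the two-sided test reaches the target, for a
#' difference of `delta_pct` percent of the mean at a replicate variability
#' of `rsd_pct` percent. This is the planning question behind comparing
#' enumeration methods: high-variability methods (plate counts at ~15% RSD)
#' need many more replicates than digital PCR (~4–5% RSD) to resolve the
#' same difference.
#'
#' @param delta_pct True mean difference to detect, percent of mean.
#' @inheritParams detectable_difference
#'
#' @return Integer replicates per group (>= 2).
#' @examples
#' required_replicates(15, 15)  # plate count: 17 replicates
#' required_replicates(15, 10)  # flow cytometry: 9
#' @export
required_replicates <- function(delta_pct, rsd_pct, alpha = 0.05,
                                power = 0.80, type = c("two.sample", "paired")) {
  type <- match.arg(type)
  if (delta_pct <= 0 || rsd_pct <= 0) {
    abort("`delta_pct` and `rsd_pct` must be positive.")
  }
  d <- delta_pct / rsd_pct
  n <- 2L
  while (t_test_power(n, d, alpha, type) < power) {
    n <- n + 1L
    if (n > 1e6) abort("More than 1e6 replicates required; check inputs.")
  }
  n
}

#' Build a power-curve table across measurement methods
#'
#' For each row of `specs`, fills in whichever of `n_replicates` /
#' `detectable_difference_pct` is missing, so methods with different
#' replicate variability can be compared on equal footing.
#'
#' @param specs Data frame with columns `method`, `rsd_pct`, and at least
#'   one of `n_replicates` or `detectable_difference_pct` per row (the other
#'   `NA`). Rows with both present are checked for consistency.
#' @inheritParams detectable_difference
#'
#' @return A tibble with columns `method`, `n_replicates`, `rsd_pct`,
#'   `detectable_difference_pct`, `alpha`, `power`.
#' @examples
#' power_table(tibble::tibble(
#'   method = c("Plate Count", "cdPCR"),
#'   rsd_pct = c(15, 5),
#'   n_replicates = c(3, 3)
#' ))
#' @export
power_table <- function(specs, alpha = 0.05, power = 0.80,
                        type = c("two.sample", "paired")) {
  type <- match.arg(type)
  specs <- as_tibble(specs)
  if (nrow(specs) == 0) abort("`specs` has no rows.")
  if (!all(c("method", "rsd_pct") %in% names(specs))) {
    abort("`specs` needs `method` and `rsd_pct` columns.")
  }
  if (!"n_replicates" %in% names(specs)) specs$n_replicates <- NA_integer_
  if (!"detectable_difference_pct" %in% names(specs)) {
    specs$detectable_difference_pct <- NA_real_
  }
  purrr::pmap_dfr(
    specs[c("method", "rsd_pct", "n_replicates", "detectable_difference_pct")],
    function(method, rsd_pct, n_replicates, detectable_difference_pct) {
      if (is.na(n_replicates) && is.na(detectable_difference_pct)) {
        abort(paste0("Row for '", method,
                     "' needs n_replicates or detectable_difference_pct."))
      }
      if (is.na(detectable_difference_pct)) {
        detectable_difference_pct <-
          detectable_difference(n_replicates, rsd_pct, alpha, power, type)
      } else if (is.na(n_replicates)) {
        n_replicates <- required_replicates(detectable_difference_pct, rsd_pct,
                                            alpha, power, type)
      }
      tibble(method = method, n_replicates = as.integer(n_replicates),
             rsd_pct = rsd_pct,
             detectable_difference_pct = detectable_difference_pct,
             alpha = alpha, power = power)
    }
  )
}

#' Compare two sets of enumeration measurements
#'
#' Pooled two-sided two-sample t test plus per-group dispersion, for
#' comparing enumeration methods (e.g. plate counts vs cdPCR) or operators.
#' If both groups have zero variance the convention is t = 0, p = 1 for
#' equal means and p = 0 otherwise.
#'
#' @param a,b Numeric vectors of measurements, at least 2 each.
#' @param alpha Significance level for the `significant` call.
#'
#' @return A `cdpcr_comparison` object; [tidy()] gives per-group summaries,
#'   [glance()] the test result.
#' @examples
#' compare_methods(c(7.7e11, 7.0e11, 8.4e11), c(7.55e11, 7.3e11, 7.8e11))
#' @export
compare_methods <- function(a, b, alpha = 0.05) {
  if (length(a) < 2 || length(b) < 2) {
    abort("Both groups need at least 2 measurements.")
  }
  if (!is.numeric(a) || !is.numeric(b)) abort("Measurements must be numeric.")
  grp <- function(x) {
    c(n = length(x), mean = mean(x), sd = sd(x),
      rsd_pct = if (mean(x) != 0) 100 * sd(x) / mean(x) else NA_real_)
  }
  if (sd(a) == 0 && sd(b) == 0) {
    tstat <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
    pval <- if (mean(a) == mean(b)) 1 else 0
    df <- length(a) + length(b) - 2
  } else {
    tt <- t.test(a, b, var.equal = TRUE)
    tstat <- unname(tt$statistic)
    pval <- tt$p.value
    df <- unname(tt$parameter)
  }
  structure(
    list(group_a = grp(a), group_b = grp(b), t_statistic = tstat, df = df,
         p_value = pval, alpha = alpha, significant = pval < alpha),
    class = "cdpcr_comparison"
  )
}

#' @export
print.cdpcr_comparison <- function(x, ...) {
  cat("Two-sample comparison (pooled t test)\n")
  cat(sprintf("  group A: n=%d mean %.4g (RSD %.1f%%)\n",
              x$group_a["n"], x$group_a["mean"], x$group_a["rsd_pct"]))
  cat(sprintf("  group B: n=%d mean %.4g (RSD %.1f%%)\n",
              x$group_b["n"], x$group_b["mean"], x$group_b["rsd_pct"]))
  cat(sprintf("  t = %.3f, df = %d, p = %.4g -> %s at alpha = %.2g\n",
              x$t_statistic, x$df, x$p_value,
              ifelse(x$significant, "significant", "not significant"),
              x$alpha))
  invisible(x)
}

#' @export
tidy.cdpcr_comparison <- function(x, ...) {
  tibble(
    group = c("a", "b"),
    n = c(x$group_a["n"], x$group_b["n"]),
    mean = c(x$group_a["mean"], x$group_b["mean"]),
    sd = c(x$group_a["sd"], x$group_b["sd"]),
    rsd_pct = c(x$group_a["rsd_pct"], x$group_b["rsd_pct"])
  )
}

#' @export
glance.cdpcr_comparison <- function(x, ...) {
  tibble(t_statistic = x$t_statistic, df = x$df, p_value = x$p_value,
         alpha = x$alpha, significant = x$significant)
}

#' qPCR amplification efficiency from a standard-curve slope
#'
#' For a standard curve of Ct against log10 concentration with slope `m`
#' (necessarily negative), the per-cycle amplification factor is
#' \eqn{10^{-1/m}} and the efficiency is \eqn{(10^{-1/m} - 1) \times 100}
#' percent; a slope of −3.32 corresponds to perfect doubling (100%).
#'
#' @param slope Standard-curve slope (Ct per log10 concentration), < 0.
#' @return Efficiency in percent.
#' @examples
#' qpcr_efficiency(-3.3219)
#' @export
qpcr_efficiency <- function(slope) {
  if (!is.numeric(slope) || any(!is.finite(slope)) || any(slope >= 0)) {
    abort("`slope` must be negative (Ct decreases with concentration).")
  }
  (10^(-1 / slope) - 1) * 100
}
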