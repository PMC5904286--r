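#' Mean copies per well from positive and qualified well counts
#'
#' Under Poisson partitioning of template molecules across wells, the
#' probability that a well holds no copy is \eqn{e^{-\lambda}}, so the mean
#' occupancy is recovered from the observed positive fraction
#' \eqn{p = P/N} as \eqn{\hat\lambda = -\ln(1 - p)}. This is the maximum
#' likelihood estimator and the core of digital PCR quantification.
#'
#' @param positive_wells Number of positive wells, `P` (vectorised).
#' @param qualified_wells Number of qualified wells, `N` (positive +
#'   negative wells that passed the reader's quality filter).
#'
#' @return Estimated mean copies per well (dimensionless), same length as
#'   the inputs.
#' @examples
#' poisson_lambda(1024, 17265)
#' @export
poisson_lambda <- function(positive_wells, qualified_wells) {
  check_well_counts(positive_wells, qualified_wells)
  if (any(qualified_wells == 0)) {
    abort("Empty chip: `qualified_wells` must be positive.")
  }
  if (any(positive_wells == qualified_wells)) {
    abort(paste(
      "Saturated chip: every qualified well is positive, so the mean",
      "occupancy is unbounded. Dilute the template and rerun."
    ))
  }
  -log1p(-positive_wells / qualified_wells)
}

check_well_counts <- function(P, N) {
  if (!is.numeric(P) || !is.numeric(N) || any(!is.finite(P)) ||
      any(!is.finite(N))) {
    abort("Well counts must be finite numerics.")
  }
  if (any(P < 0) || any(N < 0) || any(P != round(P)) || any(N != round(N))) {
    abort("Well counts must be non-negative integers.")
  }
  if (any(P > N)) {
    abort("`positive_wells` cannot exceed `qualified_wells`.")
  }
  invisible(TRUE)
}

# Binomial CI on the positive fraction p, then transformed through
# lambda = -log(1 - p). Returns list(lo, hi) on the lambda scale.
lambda_interval <- function(P, N, level, method) {
  alpha <- 1 - level
  z <- qnorm(1 - alpha / 2)
  p <- P / N
  if (method == "normal") {
    se <- sqrt(p * (1 - p) / N)
    p_lo <- pmax(0, p - z * se)
    p_hi <- pmin(1, p + z * se)
  } else if (method == "wilson") {
    denom <- 1 + z^2 / N
    centre <- (p + z^2 / (2 * N)) / denom
    half <- z * sqrt(p * (1 - p) / N + z^2 / (4 * N^2)) / denom
    p_lo <- pmax(0, centre - half)
    p_hi <- pmin(1, centre + half)
  } else { # exact (Clopper-Pearson)
    p_lo <- ifelse(P == 0, 0, qbeta(alpha / 2, P, N - P + 1))
    p_hi <- ifelse(P == N, 1, qbeta(1 - alpha / 2, P + 1, N - P))
  }
  # a chip with zero positives has a degenerate normal/Wilson interval;
  # fall back to the exact upper bound so [0, hi] is still informative
  zero <- P == 0 & method != "exact"
  if (any(zero)) {
    p_hi[zero] <- qbeta(1 - alpha / 2, 1, N[zero])
    p_lo[zero] <- 0
  }
  list(lo = -log1p(-p_lo), hi = -log1p(-pmin(p_hi, 1 - 1e-12)))
}

#' Quantify digital PCR chips
#'
#' Converts per-chip well counts into absolute template concentrations. For
#' each chip the positive fraction is transformed to mean copies per well
#' (\eqn{\hat\lambda = -\ln(1 - P/N)}), scaled by the well volume to
#' copies/µl of reaction, and by the template dilution factor to copies/µl
#' of template — the concentration of the material pipetted into the
#' reaction. A binomial confidence interval on the positive fraction is
#' propagated through the same transform; `precision_pct` is the upper
#' bound's excess over the point estimate,
#' \eqn{(\lambda_{hi}/\hat\lambda - 1) \times 100}.
#'
#' QC flags (semicolon-separated in `qc_flags`):
#' * `LOW_WELLS` — fewer qualified wells than `assay$min_qualified_wells`;
#' * `UNDER_SATURATED` / `OVER_SATURATED` — positive fraction outside the
#'   recommended saturation window;
#' * `SATURATED_FULL` — every qualified well positive: \eqn{\lambda}
#'   undefined, estimates are `NA`;
#' * `ZERO_POSITIVE` — no positive well: the point estimate is 0 and
#'   precision is undefined, but the CI upper bound is still reported.
#'
#' No-template control chips are quantified exactly like sample chips; their
#' apparent concentration is the false-positive floor used for the limit of
#' detection.
#'
#' @param chips Data frame with columns `qualified_wells` and
#'   `positive_wells`; columns `chip_id`, `target_id`,
#'   `theoretical_copies_per_ul` and `is_ntc` are carried through when
#'   present.
#' @param assay An [assay_config()].
#'
#' @return The input as a tibble with columns `lambda_hat`, `saturation`,
#'   `copies_per_ul_reaction`, `copies_per_ul_template`, `ci_low`, `ci_high`
#'   (template scale), `precision_pct` and `qc_flags` appended.
#' @examples
#' chips <- tibble::tibble(
#'   chip_id = c("A", "B"),
#'   qualified_wells = c(17265, 16814),
#'   positive_wells = c(1024, 567)
#' )
#' quantify_chips(chips)
#' @export
quantify_chips <- function(chips, assay = assay_config()) {
  stopifnot(inherits(assay, "cdpcr_assay"))
  chips <- as_tibble(chips)
  req <- c("qualified_wells", "positive_wells")
  missing_cols <- setdiff(req, names(chips))
  if (length(missing_cols)) {
    abort(paste0("`chips` is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  if (nrow(chips) == 0) abort("`chips` has no rows.")
  P <- chips$positive_wells
  N <- chips$qualified_wells
  check_well_counts(P, N)
  if (any(N == 0)) abort("Empty chip: `qualified_wells` must be positive.")
  if (any(N > assay$total_wells)) {
    abort("`qualified_wells` cannot exceed the chip's total wells.")
  }

  sat <- P / N
  full <- P == N
  lam <- ifelse(full, NA_real_, -log1p(-sat))
  scale <- assay$dilution_factor / assay$well_volume_ul

  ci <- lambda_interval(P, N, assay$confidence_level, assay$ci_method)
  ci$lo[full] <- NA_real_
  ci$hi[full] <- NA_real_
  precision <- ifelse(P == 0 | full, NA_real_, (ci$hi / lam - 1) * 100)

  flags <- purrr::pmap_chr(
    list(P, N, sat, full),
    function(p, n, s, f) {
      fl <- character()
      if (n < assay$min_qualified_wells) fl <- c(fl, "LOW_WELLS")
      if (f) {
        fl <- c(fl, "SATURATED_FULL")
      } else {
        if (s < assay$saturation_bounds[1]) fl <- c(fl, "UNDER_SATURATED")
        if (s > assay$saturation_bounds[2]) fl <- c(fl, "OVER_SATURATED")
      }
      if (p == 0) fl <- c(fl, "ZERO_POSITIVE")
      paste(fl, collapse = ";")
    }
  )

  chips %>%
    mutate(
      lambda_hat = lam,
      saturation = sat,
      copies_per_ul_reaction = lam / assay$well_volume_ul,
      copies_per_ul_template = lam * scale,
      ci_low = ci$lo * scale,
      ci_high = ci$hi * scale,
      precision_pct = precision,
      qc_flags = flags
    )
}
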