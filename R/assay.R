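#' Assay configuration for a digital PCR chip
#'
#' Bundles the chip geometry, liquid-handling volumes and quality-control
#' thresholds that convert a per-well occupancy \eqn{\lambda} into template
#' copies/µl and decide which chips are trustworthy. Defaults describe a
#' 20,000-well nanofluidic chip loaded with 14.5 µl of a 20 µl reaction that
#' received 1 µl of template, i.e. a template dilution factor of 20.
#'
#' @param total_wells Number of wells on the chip.
#' @param well_volume_ul Volume of a single well, in µl (default 7.55e-4 µl
#'   = 0.755 nl).
#' @param loaded_volume_ul Volume of reaction mix loaded onto the chip, µl.
#' @param reaction_volume_ul Total PCR reaction volume, µl.
#' @param template_volume_ul Template volume added to the reaction, µl. The
#'   dilution factor `reaction_volume_ul / template_volume_ul` rescales
#'   reaction-level concentrations back to the template.
#' @param min_qualified_wells QC threshold: minimum qualified (readable)
#'   wells for a chip to count towards the limit of quantification.
#' @param saturation_bounds Length-2 numeric, the recommended range of the
#'   positive fraction for reliable quantification (default 5%–90%).
#' @param confidence_level Confidence level for per-chip intervals.
#' @param max_precision_pct QC threshold on per-chip precision (upper CI
#'   bound as percent above the point estimate).
#' @param max_group_rsd_pct QC threshold on the relative standard deviation
#'   across replicate chips of one dilution.
#' @param ci_method Binomial interval on the positive fraction before the
#'   Poisson transform: `"normal"` (delta-method default), `"wilson"`, or
#'   `"exact"` (Clopper–Pearson).
#'
#' @return An object of class `cdpcr_assay` (a validated list).
#' @examples
#' assay_config()
#' assay_config(confidence_level = 0.99, ci_method = "wilson")
#' @export
assay_config <- function(total_wells = 20000L,
                         well_volume_ul = 7.55e-4,
                         loaded_volume_ul = 14.5,
                         reaction_volume_ul = 20,
                         template_volume_ul = 1,
                         min_qualified_wells = 10000L,
                         saturation_bounds = c(0.05, 0.90),
                         confidence_level = 0.95,
                         max_precision_pct = 10,
                         max_group_rsd_pct = 15,
                         ci_method = c("normal", "wilson", "exact")) {
  ci_method <- match.arg(ci_method)
  if (!is.numeric(total_wells) || length(total_wells) != 1 || total_wells < 1) {
    abort("`total_wells` must be a single positive integer.")
  }
  for (nm in c("well_volume_ul", "loaded_volume_ul", "reaction_volume_ul",
               "template_volume_ul")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort(paste0("`", nm, "` must be a single positive number."))
    }
  }
  if (loaded_volume_ul > reaction_volume_ul) {
    abort("`loaded_volume_ul` cannot exceed `reaction_volume_ul`.")
  }
  if (template_volume_ul > reaction_volume_ul) {
    abort("`template_volume_ul` cannot exceed `reaction_volume_ul`.")
  }
  if (length(saturation_bounds) != 2 ||
      !all(is.finite(saturation_bounds)) ||
      saturation_bounds[1] <= 0 || saturation_bounds[2] >= 1 ||
      saturation_bounds[1] >= saturation_bounds[2]) {
    abort("`saturation_bounds` must satisfy 0 < low < high < 1.")
  }
  if (confidence_level <= 0 || confidence_level >= 1) {
    abort("`confidence_level` must be in (0, 1).")
  }
  structure(
    list(
      total_wells = as.integer(total_wells),
      well_volume_ul = well_volume_ul,
      loaded_volume_ul = loaded_volume_ul,
      reaction_volume_ul = reaction_volume_ul,
      template_volume_ul = template_volume_ul,
      dilution_factor = reaction_volume_ul / template_volume_ul,
      min_qualified_wells = as.integer(min_qualified_wells),
      saturation_bounds = saturation_bounds,
      confidence_level = confidence_level,
      max_precision_pct = max_precision_pct,
      max_group_rsd_pct = max_group_rsd_pct,
      ci_method = ci_method
    ),
    class = "cdpcr_assay"
  )
}

#' @export
print.cdpcr_assay <- function(x, ...) {
  cat("<cdpcr_assay>\n")
  cat(sprintf("  chip: %d wells x %.3g nl (%.4g ul loaded of %.4g ul reaction)\n",
              x$total_wells, x$well_volume_ul * 1e3, x$loaded_volume_ul,
              x$reaction_volume_ul))
  cat(sprintf("  template dilution factor: %.3g\n", x$dilution_factor))
  cat(sprintf("  QC: >= %d qualified wells, saturation %.0f%%-%.0f%%, precision <= %.3g%%, group RSD <= %.3g%%\n",
              x$min_qualified_wells, 100 * x$saturation_bounds[1],
              100 * x$saturation_bounds[2], x$max_precision_pct,
              x$max_group_rsd_pct))
  cat(sprintf("  CI: %s, %.0f%% confidence\n", x$ci_method,
              100 * x$confidence_level))
  invisible(x)
}

#' Theoretical dynamic range of a chip
#'
#' The quantifiable range implied by the number of loaded wells the reader
#' can work with: with one target copy per loaded well, `wells` copies in the
#' loaded volume correspond to `dilution_factor * wells / loaded_volume_ul`
#' copies/µl of template. Defaults take the well bounds from the recommended
#' saturation range (5%–90% of a 20,000-well chip, i.e. 1,000–18,000 wells).
#'
#' @param assay An [assay_config()].
#' @param min_loaded_wells,max_loaded_wells Occupied-well bounds defining the
#'   range. Defaults derive from `assay$saturation_bounds`.
#' @param poisson_corrected If `TRUE`, treat the well bounds as saturation
#'   levels and apply the Poisson correction
#'   \eqn{\lambda = -\ln(1 - s)} instead of the one-copy-per-well linear
#'   model. The linear default matches the usual back-of-envelope range.
#'
#' @return A tibble with columns `bound` (`"low"`, `"high"`) and
#'   `copies_per_ul_template`.
#' @examples
#' theoretical_dynamic_range(assay_config())
#' @export
theoretical_dynamic_range <- function(assay = assay_config(),
                                      min_loaded_wells = NULL,
                                      max_loaded_wells = NULL,
                                      poisson_corrected = FALSE) {
  stopifnot(inherits(assay, "cdpcr_assay"))
  if (is.null(min_loaded_wells)) {
    min_loaded_wells <- assay$saturation_bounds[1] * assay$total_wells
  }
  if (is.null(max_loaded_wells)) {
    max_loaded_wells <- assay$saturation_bounds[2] * assay$total_wells
  }
  if (!(min_loaded_wells > 0 && min_loaded_wells < max_loaded_wells &&
        max_loaded_wells <= assay$total_wells)) {
    abort("Need 0 < min_loaded_wells < max_loaded_wells <= total_wells.")
  }
  wells <- c(min_loaded_wells, max_loaded_wells)
  if (poisson_corrected) {
    lambda <- -log1p(-wells / assay$total_wells)
    conc <- assay$dilution_factor * lambda / assay$well_volume_ul
  } else {
    conc <- assay$dilution_factor * wells / assay$loaded_volume_ul
  }
  tibble(bound = c("low", "high"), copies_per_ul_template = conc)
}

#' Convert a template concentration to copies per gram of sample
#'
#' Scales a measured copies/µl back through the sample-preparation chain: a
#' mass of product suspended in a diluent volume, optionally followed by
#' further dilution steps. The chain is multiplicative, so step order does
#' not matter.
#'
#' @param copies_per_ul_template Measured concentration, copies/µl.
#' @param sample_mass_g Mass of sample suspended, grams.
#' @param suspension_volume_ul Volume the sample was suspended in, µl.
#' @param dilution_factors Numeric vector of subsequent fold-dilutions
#'   (e.g. `c(10, 10)` for two serial 1:10 steps). May be empty.
#'
#' @return Copies per gram (numeric).
#' @examples
#' copies_per_gram(1000, sample_mass_g = 1, suspension_volume_ul = 1e6)
#' copies_per_gram(2000, 11, 99e3, dilution_factors = 10)
#' @export
copies_per_gram <- function(copies_per_ul_template, sample_mass_g,
                            suspension_volume_ul, dilution_factors = numeric()) {
  if (!is.numeric(copies_per_ul_template) || any(copies_per_ul_template < 0)) {
    abort("`copies_per_ul_template` must be non-negative.")
  }
  if (!is.numeric(sample_mass_g) || length(sample_mass_g) != 1 ||
      sample_mass_g <= 0) {
    abort("`sample_mass_g` must be a single positive number.")
  }
  if (!is.numeric(suspension_volume_ul) || length(suspension_volume_ul) != 1 ||
      suspension_volume_ul <= 0) {
    abort("`suspension_volume_ul` must be a single positive number.")
  }
  if (length(dilution_factors) && any(dilution_factors <= 0)) {
    abort("`dilution_factors` must all be positive.")
  }
  copies_per_ul_template * suspension_volume_ul * prod(dilution_factors) /
    sample_mass_g
}
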