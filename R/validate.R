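#' Summarise replicate chips by dilution group
#'
#' Groups quantified chips by target and theoretical concentration and
#' reports the replicate mean, sample standard deviation (n − 1 denominator)
#' and relative standard deviation of the template-scale estimates. Groups
#' with a single chip get `NA` sd/RSD.
#'
#' @param estimates Output of [quantify_chips()]; rows lacking a
#'   `theoretical_copies_per_ul` column are treated as one unlabelled group,
#'   and an `is_ntc` column (when present) keeps no-template controls in
#'   their own group.
#'
#' @return A tibble with one row per group: `target_id` (if present),
#'   `theoretical_copies_per_ul`, `is_ntc`, `n_chips`, `mean_copies_per_ul`,
#'   `sd_copies_per_ul`, `rsd_pct`.
#' @export
summarize_groups <- function(estimates) {
  estimates <- as_tibble(estimates)
  if (!"copies_per_ul_template" %in% names(estimates)) {
    abort("`estimates` must come from quantify_chips() (missing `copies_per_ul_template`).")
  }
  if (nrow(estimates) == 0) abort("`estimates` has no rows.")
  if (!"theoretical_copies_per_ul" %in% names(estimates)) {
    estimates$theoretical_copies_per_ul <- NA_real_
  }
  if (!"is_ntc" %in% names(estimates)) estimates$is_ntc <- FALSE
  keys <- intersect(c("target_id", "theoretical_copies_per_ul", "is_ntc"),
                    names(estimates))
  estimates %>%
    group_by(!!!syms(keys)) %>%
    summarise(
      n_chips = dplyr::n(),
      mean_copies_per_ul = mean(.data$copies_per_ul_template),
      sd_copies_per_ul = ifelse(dplyr::n() > 1,
                                sd(.data$copies_per_ul_template), NA_real_),
      .groups = "drop"
    ) %>%
    mutate(
      rsd_pct = ifelse(.data$mean_copies_per_ul > 0,
                       100 * .data$sd_copies_per_ul / .data$mean_copies_per_ul,
                       NA_real_)
    ) %>%
    arrange(.data$is_ntc, desc(.data$theoretical_copies_per_ul))
}

#' False-positive rate from no-template control chips
#'
#' The assay's false-positive floor: positive wells observed on chips that
#' received water instead of template. The default pools wells across all
#' NTC chips (total positives / total qualified); `method = "mean"` averages
#' the per-chip percentages instead.
#'
#' @param ntc_chips Data frame of NTC chip records with `positive_wells` and
#'   `qualified_wells`. If an `is_ntc` column is present, every row must be
#'   flagged `TRUE`.
#' @param method `"pooled"` (default) or `"mean"`.
#'
#' @return Percentage of qualified wells reading positive (full precision;
#'   reports round to two decimals).
#' @examples
#' ntc <- tibble::tibble(
#'   qualified_wells = c(17167, 16677, 16288),
#'   positive_wells = c(201, 173, 197),
#'   is_ntc = TRUE
#' )
#' false_positive_rate(ntc)
#' @export
false_positive_rate <- function(ntc_chips, method = c("pooled", "mean")) {
  method <- match.arg(method)
  ntc_chips <- as_tibble(ntc_chips)
  if (nrow(ntc_chips) == 0) abort("No NTC chips supplied.")
  if ("is_ntc" %in% names(ntc_chips) && !all(ntc_chips$is_ntc)) {
    abort("All rows passed to false_positive_rate() must be NTC chips.")
  }
  check_well_counts(ntc_chips$positive_wells, ntc_chips$qualified_wells)
  if (any(ntc_chips$qualified_wells == 0)) {
    abort("NTC chips must have qualified wells.")
  }
  if (method == "pooled") {
    100 * sum(ntc_chips$positive_wells) / sum(ntc_chips$qualified_wells)
  } else {
    mean(100 * ntc_chips$positive_wells / ntc_chips$qualified_wells)
  }
}

#' Limit of detection from no-template controls
#'
#' The LoD is defined as the apparent concentration of the no-template
#' controls: sample measurements are only called detected above this level.
#' The default is the arithmetic mean of the NTC template-scale estimates; a
#' conservative `mean + k * sd` variant is available.
#'
#' @param ntc_estimates NTC rows of a [quantify_chips()] result.
#' @param method `"mean"` (default) or `"mean_sd"`.
#' @param k Multiplier on the NTC standard deviation for `"mean_sd"`.
#'
#' @return LoD in copies/µl of template (full precision; reports round to
#'   integer).
#' @export
determine_lod <- function(ntc_estimates, method = c("mean", "mean_sd"), k = 1.645) {
  method <- match.arg(method)
  ntc_estimates <- as_tibble(ntc_estimates)
  if (nrow(ntc_estimates) == 0) abort("No NTC estimates supplied.")
  if (!"copies_per_ul_template" %in% names(ntc_estimates)) {
    abort("`ntc_estimates` must come from quantify_chips().")
  }
  x <- ntc_estimates$copies_per_ul_template
  if (method == "mean" || length(x) < 2) mean(x) else mean(x) + k * sd(x)
}

# Per-group LoQ criteria for one set of quantified replicate chips.
loq_diagnostics <- function(estimates, assay) {
  if (!"theoretical_copies_per_ul" %in% names(estimates)) {
    abort("LoQ determination needs a `theoretical_copies_per_ul` column.")
  }
  estimates %>%
    group_by(.data$theoretical_copies_per_ul) %>%
    summarise(
      n_chips = dplyr::n(),
      mean_copies_per_ul = mean(.data$copies_per_ul_template),
      rsd_pct = ifelse(dplyr::n() > 1,
                       100 * sd(.data$copies_per_ul_template) /
                         mean(.data$copies_per_ul_template), NA_real_),
      precision_ok = all(!is.na(.data$precision_pct) &
                           .data$precision_pct <= assay$max_precision_pct),
      wells_ok = all(.data$qualified_wells >= assay$min_qualified_wells),
      .groups = "drop"
    ) %>%
    mutate(
      rsd_ok = !is.na(.data$rsd_pct) & .data$rsd_pct <= assay$max_group_rsd_pct,
      passes = .data$precision_ok & .data$wells_ok & .data$rsd_ok
    ) %>%
    arrange(desc(.data$theoretical_copies_per_ul))
}

#' Limit of quantification from a dilution series
#'
#' The LoQ is the mean measured concentration of the lowest dilution group in
#' which every replicate chip meets the per-chip criteria (precision at most
#' `assay$max_precision_pct`, at least `assay$min_qualified_wells` qualified
#' wells) and the group's replicate RSD is at most
#' `assay$max_group_rsd_pct`. Groups failing any criterion are diagnosed in
#' the returned table.
#'
#' @param estimates Non-NTC rows of a [quantify_chips()] result carrying
#'   `theoretical_copies_per_ul`. NTC rows (per an `is_ntc` column) are
#'   dropped automatically.
#' @param assay An [assay_config()].
#'
#' @return A list with `loq_copies_per_ul` (`NA` if no group qualifies) and
#'   `diagnostics`, a tibble of per-group criteria.
#' @export
determine_loq <- function(estimates, assay = assay_config()) {
  estimates <- as_tibble(estimates)
  if (nrow(estimates) == 0) abort("`estimates` has no rows.")
  if ("is_ntc" %in% names(estimates)) {
    estimates <- filter(estimates, !.data$is_ntc)
  }
  if (nrow(estimates) == 0) abort("Only NTC chips supplied; LoQ needs dilution groups.")
  diag <- loq_diagnostics(estimates, assay)
  passing <- filter(diag, .data$passes)
  loq <- if (nrow(passing) == 0) {
    NA_real_
  } else {
    passing$mean_copies_per_ul[which.min(passing$theoretical_copies_per_ul)]
  }
  list(loq_copies_per_ul = loq, diagnostics = diag)
}

#' Empirical dynamic range of a dilution series
#'
#' The measured range the assay actually covered: from the smallest group
#' mean strictly above the limit of detection up to the largest group mean.
#'
#' @param groups A [summarize_groups()] table (NTC rows are dropped).
#' @param lod Limit of detection, copies/µl.
#'
#' @return A tibble with columns `bound` and `copies_per_ul_template`
#'   (`NA` values if no group mean exceeds the LoD).
#' @export
empirical_dynamic_range <- function(groups, lod) {
  groups <- as_tibble(groups)
  if ("is_ntc" %in% names(groups)) groups <- filter(groups, !.data$is_ntc)
  above <- groups$mean_copies_per_ul[groups$mean_copies_per_ul > lod]
  if (length(above) == 0) {
    warn("No dilution group mean exceeds the LoD; dynamic range undetermined.")
    return(tibble(bound = c("low", "high"),
                  copies_per_ul_template = c(NA_real_, NA_real_)))
  }
  tibble(bound = c("low", "high"),
         copies_per_ul_template = c(min(above), max(above)))
}

#' Linearity and efficiency of a dilution series
#'
#' Ordinary least squares of measured group means against the theoretical
#' design concentrations, on log10–log10 axes by default. A perfectly
#' proportional assay has slope 1; the cdPCR efficiency is reported as
#' `slope * 100`.
#'
#' @param groups A [summarize_groups()] table with at least three non-NTC
#'   groups.
#' @param log_scale Regress on log10 of both axes (default `TRUE`).
#'
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`,
#'   `efficiency_pct`, `n_groups`.
#' @export
assay_linearity <- function(groups, log_scale = TRUE) {
  groups <- as_tibble(groups)
  if ("is_ntc" %in% names(groups)) groups <- filter(groups, !.data$is_ntc)
  groups <- filter(groups, !is.na(.data$theoretical_copies_per_ul),
                   .data$theoretical_copies_per_ul > 0)
  if (nrow(groups) < 3) {
    abort("Linearity needs at least 3 dilution groups.")
  }
  x <- groups$theoretical_copies_per_ul
  y <- groups$mean_copies_per_ul
  if (log_scale) {
    if (any(y <= 0)) abort("Log-scale linearity needs positive group means.")
    x <- log10(x)
    y <- log10(y)
  }
  fit <- lm(y ~ x)
  tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    efficiency_pct = unname(coef(fit)[2]) * 100,
    n_groups = nrow(groups)
  )
}

#' Validate a digital PCR dilution series
#'
#' Runs the full assay-validation workflow on the chip records of one
#' target's dilution series: per-chip quantification, replicate-group
#' summaries, false-positive rate and limit of detection from the NTC chips,
#' limit of quantification from the QC criteria, empirical and theoretical
#' dynamic range, and linearity/efficiency.
#'
#' @param chips Data frame of chip records for a single target:
#'   `qualified_wells`, `positive_wells`, `theoretical_copies_per_ul`,
#'   `is_ntc`, and optionally `chip_id`/`target_id`.
#' @param assay An [assay_config()].
#'
#' @return A `cdpcr_validation` object; see [tidy()] and [glance()] methods,
#'   [autoplot.cdpcr_validation()], and [write_validation_report()].
#' @examples
#' chips <- read_chip_table(
#'   system.file("extdata", "bl04_dilution_series.csv", package = "cdpcr")
#' )
#' validate_series(chips)
#' @export
validate_series <- function(chips, assay = assay_config()) {
  chips <- as_tibble(chips)
  if (nrow(chips) == 0) abort("`chips` has no rows.")
  if (!"is_ntc" %in% names(chips)) chips$is_ntc <- FALSE
  target <- if ("target_id" %in% names(chips)) unique(chips$target_id) else "unknown"
  if (length(target) > 1) {
    abort(paste0("validate_series() expects a single target; got: ",
                 paste(target, collapse = ", "),
                 ". Split the table and validate each target separately."))
  }
  non_ntc <- filter(chips, !.data$is_ntc)
  if (length(unique(non_ntc$theoretical_copies_per_ul)) < 2) {
    abort("Need at least 2 dilution groups to validate a series.")
  }

  est <- quantify_chips(chips, assay)
  groups <- summarize_groups(est)
  ntc_est <- filter(est, .data$is_ntc)

  if (nrow(ntc_est) == 0) {
    warn("No NTC chips in the series; LoD and false-positive rate undetermined.")
    fp <- NA_real_
    lod <- NA_real_
  } else {
    fp <- false_positive_rate(ntc_est)
    lod <- determine_lod(ntc_est)
  }

  loq <- determine_loq(filter(est, !.data$is_ntc), assay)
  emp <- if (is.na(lod)) {
    tibble(bound = c("low", "high"),
           copies_per_ul_template = c(NA_real_, NA_real_))
  } else {
    empirical_dynamic_range(groups, lod)
  }
  lin <- tryCatch(assay_linearity(groups), error = function(e) NULL)

  structure(
    list(
      target_id = target,
      n_chips = nrow(chips),
      assay = assay,
      estimates = est,
      groups = groups,
      false_positive_rate_pct = fp,
      lod_copies_per_ul = lod,
      loq_copies_per_ul = loq$loq_copies_per_ul,
      loq_diagnostics = loq$diagnostics,
      empirical_range = emp,
      theoretical_range = theoretical_dynamic_range(assay),
      linearity = lin
    ),
    class = "cdpcr_validation"
  )
}

#' @export
print.cdpcr_validation <- function(x, ...) {
  fmt_int <- function(v) ifelse(is.na(v), "ND", format(round(v), big.mark = ",", trim = TRUE))
  cat(sprintf("cdPCR assay validation: %s (%d chips)\n", x$target_id, x$n_chips))
  tr <- signif(x$theoretical_range$copies_per_ul_template, 2)
  cat(sprintf("  theoretical dynamic range: %s - %s copies/ul\n",
              format(tr[1], big.mark = ","), format(tr[2], big.mark = ",")))
  er <- x$empirical_range$copies_per_ul_template
  cat(sprintf("  empirical dynamic range:   %s - %s copies/ul\n",
              fmt_int(er[1]), fmt_int(er[2])))
  cat(sprintf("  LoD: %s copies/ul   LoQ: %s copies/ul\n",
              fmt_int(x$lod_copies_per_ul), fmt_int(x$loq_copies_per_ul)))
  cat(sprintf("  false-positive rate: %s\n",
              ifelse(is.na(x$false_positive_rate_pct), "ND",
                     sprintf("%.2f%%", x$false_positive_rate_pct))))
  if (!is.null(x$linearity)) {
    cat(sprintf("  linearity: slope %.3f (efficiency %.0f%%), r^2 %.4f\n",
                x$linearity$slope, x$linearity$efficiency_pct,
                x$linearity$r_squared))
  }
  cat("\n  dilution groups:\n")
  g <- x$groups
  lab <- ifelse(g$is_ntc, "NTC", format(round(g$theoretical_copies_per_ul),
                                        big.mark = ",", trim = TRUE))
  for (i in seq_len(nrow(g))) {
    cat(sprintf("    %10s : n=%d  mean %s  RSD %s\n",
                lab[i], g$n_chips[i], fmt_int(g$mean_copies_per_ul[i]),
                ifelse(is.na(g$rsd_pct[i]), "ND",
                       sprintf("%.0f%%", g$rsd_pct[i]))))
  }
  invisible(x)
}

#' Tidy a cdPCR validation report
#'
#' @param x A `cdpcr_validation` object.
#' @param ... Unused.
#' @return One row per dilution group with the LoQ criteria diagnostics
#'   joined on.
#' @export
tidy.cdpcr_validation <- function(x, ...) {
  diag <- select(x$loq_diagnostics, "theoretical_copies_per_ul",
                 "precision_ok", "wells_ok", "rsd_ok", "passes")
  dplyr::left_join(x$groups, diag, by = "theoretical_copies_per_ul")
}

#' Headline metrics of a cdPCR validation report
#'
#' @param x A `cdpcr_validation` object.
#' @param ... Unused.
#' @return A one-row tibble: target, chip count, FP rate, LoD, LoQ,
#'   empirical and theoretical range bounds, linearity slope/efficiency/r².
#' @export
glance.cdpcr_validation <- function(x, ...) {
  tibble(
    target_id = x$target_id,
    n_chips = x$n_chips,
    false_positive_rate_pct = x$false_positive_rate_pct,
    lod_copies_per_ul = x$lod_copies_per_ul,
    loq_copies_per_ul = x$loq_copies_per_ul,
    empirical_low = x$empirical_range$copies_per_ul_template[1],
    empirical_high = x$empirical_range$copies_per_ul_template[2],
    theoretical_low = x$theoretical_range$copies_per_ul_template[1],
    theoretical_high = x$theoretical_range$copies_per_ul_template[2],
    slope = if (is.null(x$linearity)) NA_real_ else x$linearity$slope,
    efficiency_pct = if (is.null(x$linearity)) NA_real_ else x$linearity$efficiency_pct,
    r_squared = if (is.null(x$linearity)) NA_real_ else x$linearity$r_squared
  )
}
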