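#' Parameters for the stochastic chip simulator
#'
#' Describes one simulated sample: its true template concentration plus the
#' processes that distort a real chip readout. Viability-PCR effects are
#' modelled at the concentration level: a fraction `dead_fraction` of the
#' template comes from membrane-compromised cells whose amplification the
#' PMA dye suppresses with efficacy `pma_efficacy` (0.9 means a 10-fold
#' signal knockdown of dead-cell DNA), while `lysis_efficiency` scales how
#' much intact-cell DNA the mechanical lysis liberated. The effective
#' amplifiable concentration is therefore
#' `true * (lysis_efficiency * (1 - dead_fraction) + dead_fraction * (1 - pma_efficacy))`.
#'
#' @param true_copies_per_ul_template True template concentration, copies/µl.
#' @param dead_fraction Fraction of template from dead/compromised cells.
#' @param pma_efficacy Fraction of dead-cell DNA amplification suppressed.
#' @param lysis_efficiency Fraction of intact-cell DNA liberated.
#' @param false_positive_rate_per_well Probability an empty well still reads
#'   positive (default 0.0114, typical of a Bl-04-style assay; an NCFM-style
#'   assay is closer to 0.0052).
#' @param false_negative_rate_per_well Probability an occupied well reads
#'   negative.
#' @param qualified_wells_range Integer range the number of qualified wells
#'   is drawn from, uniformly (default 15,000–18,200, the span seen on real
#'   20,000-well chips).
#'
#' @return A `cdpcr_sim_params` list.
#' @examples
#' sim_params(7500)
#' sim_params(7500, dead_fraction = 0.5, pma_efficacy = 0.95)
#' @export
sim_params <- function(true_copies_per_ul_template,
                       dead_fraction = 0,
                       pma_efficacy = 0.90,
                       lysis_efficiency = 1,
                       false_positive_rate_per_well = 0.0114,
                       false_negative_rate_per_well = 0,
                       qualified_wells_range = c(15000L, 18200L)) {
  if (!is.numeric(true_copies_per_ul_template) ||
      true_copies_per_ul_template < 0) {
    abort("`true_copies_per_ul_template` must be >= 0.")
  }
  for (nm in c("dead_fraction", "pma_efficacy", "lysis_efficiency",
               "false_positive_rate_per_well", "false_negative_rate_per_well")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
      abort(paste0("`", nm, "` must be a fraction in [0, 1]."))
    }
  }
  if (length(qualified_wells_range) != 2 ||
      qualified_wells_range[1] > qualified_wells_range[2] ||
      qualified_wells_range[1] < 1) {
    abort("`qualified_wells_range` must be an increasing positive pair.")
  }
  structure(
    list(
      true_copies_per_ul_template = true_copies_per_ul_template,
      dead_fraction = dead_fraction,
      pma_efficacy = pma_efficacy,
      lysis_efficiency = lysis_efficiency,
      false_positive_rate_per_well = false_positive_rate_per_well,
      false_negative_rate_per_well = false_negative_rate_per_well,
      qualified_wells_range = as.integer(round(qualified_wells_range))
    ),
    class = "cdpcr_sim_params"
  )
}

# Amplifiable template concentration after viability/lysis effects.
effective_concentration <- function(params) {
  params$true_copies_per_ul_template *
    (params$lysis_efficiency * (1 - params$dead_fraction) +
       params$dead_fraction * (1 - params$pma_efficacy))
}

sim_chips_impl <- function(n_chips, params, assay, target_id, id_prefix,
                           theoretical, is_ntc) {
  lambda <- effective_concentration(params) / assay$dilution_factor *
    assay$well_volume_ul
  N <- as.integer(round(runif(n_chips, params$qualified_wells_range[1] - 0.5,
                              params$qualified_wells_range[2] + 0.5)))
  N <- pmin(pmax(N, 1L), assay$total_wells)
  occupied <- rbinom(n_chips, N, 1 - exp(-lambda))
  true_pos <- rbinom(n_chips, occupied,
                     1 - params$false_negative_rate_per_well)
  false_pos <- rbinom(n_chips, N - occupied,
                      params$false_positive_rate_per_well)
  tibble(
    chip_id = paste0(id_prefix, seq_len(n_chips)),
    target_id = target_id,
    theoretical_copies_per_ul = theoretical,
    qualified_wells = N,
    positive_wells = true_pos + false_pos,
    is_ntc = is_ntc,
    true_lambda = lambda,
    true_occupied_wells = occupied
  )
}

#' Simulate digital PCR chip readouts
#'
#' Draws chip readouts from the generative model: qualified wells uniform
#' over the configured range, well occupancy Poisson at the effective
#' per-well rate (so the number of occupied wells among `N` qualified wells
#' is binomial with probability \eqn{1 - e^{-\lambda}}), false negatives
#' thinning the occupied wells and false positives adding to the empty ones.
#' The returned tibble carries the ground truth (`true_lambda`,
#' `true_occupied_wells`) alongside the observable columns, and its
#' observable part is exactly the chip-record format [quantify_chips()] and
#' [read_chip_table()] use.
#'
#' @param n_chips Number of chips to draw.
#' @param params A [sim_params()].
#' @param assay An [assay_config()].
#' @param seed Optional integer; when given the draw is reproducible and the
#'   caller's RNG state is left untouched.
#' @param target_id,id_prefix Labels for the generated records.
#'
#' @return A tibble of `n_chips` chip records with ground-truth columns.
#' @examples
#' simulate_chips(3, sim_params(7500), seed = 1)
#' @export
simulate_chips <- function(n_chips, params, assay = assay_config(),
                           seed = NULL, target_id = "SIM",
                           id_prefix = "chip") {
  stopifnot(inherits(params, "cdpcr_sim_params"),
            inherits(assay, "cdpcr_assay"))
  if (n_chips < 1) abort("`n_chips` must be >= 1.")
  theo <- params$true_copies_per_ul_template
  run <- function() {
    sim_chips_impl(n_chips, params, assay, target_id, paste0(id_prefix, "_"),
                   theoretical = if (theo > 0) theo else NA_real_,
                   is_ntc = theo == 0)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a single chip
#'
#' Convenience wrapper around [simulate_chips()] for one chip.
#'
#' @inheritParams simulate_chips
#' @return A one-row tibble.
#' @export
simulate_chip <- function(params, assay = assay_config(), seed = NULL) {
  simulate_chips(1, params, assay, seed = seed)
}

#' Simulate a serial dilution series with no-template controls
#'
#' Generates the input of a full validation experiment: `replicates` chips
#' at each dilution of the stock concentration in `params`, plus `n_ntc`
#' no-template control chips (true concentration zero, false positives still
#' active). `theoretical_copies_per_ul` records each chip's design
#' concentration.
#'
#' @param params A [sim_params()]; its concentration is the undiluted stock.
#' @param assay An [assay_config()].
#' @param dilution_factors Fold-dilutions relative to the stock; the default
#'   is seven two-fold steps starting at the stock itself.
#' @param replicates Chips per dilution.
#' @param n_ntc Number of NTC chips.
#' @param seed Optional integer for reproducibility.
#' @param target_id Label for the generated records.
#'
#' @return A tibble of chip records with ground-truth columns.
#' @examples
#' series <- simulate_dilution_series(sim_params(20000), seed = 42)
#' validate_series(series)
#' @export
simulate_dilution_series <- function(params, assay = assay_config(),
                                     dilution_factors = 2^(0:6),
                                     replicates = 3, n_ntc = 3, seed = NULL,
                                     target_id = "SIM") {
  stopifnot(inherits(params, "cdpcr_sim_params"))
  if (replicates < 1) abort("`replicates` must be >= 1.")
  if (any(dilution_factors < 1)) abort("`dilution_factors` must be >= 1.")
  run <- function() {
    per_dilution <- purrr::imap(dilution_factors, function(f, i) {
      p <- params
      p$true_copies_per_ul_template <- params$true_copies_per_ul_template / f
      sim_chips_impl(replicates, p, assay, target_id,
                     paste0("D", i, "_R"),
                     theoretical = p$true_copies_per_ul_template,
                     is_ntc = FALSE)
    })
    ntc <- if (n_ntc > 0) {
      p0 <- params
      p0$true_copies_per_ul_template <- 0
      sim_chips_impl(n_ntc, p0, assay, target_id, "NTC_",
                     theoretical = NA_real_, is_ntc = TRUE)
    }
    bind_rows(c(per_dilution, list(ntc)))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Estimator recovery experiment
#'
#' Closes the loop between the simulator and the estimator: simulates many
#' chips at a known true concentration, quantifies each with
#' [quantify_chips()], and reports the relative bias, root-mean-square
#' error, and the fraction of confidence intervals covering the truth. With
#' error processes off this checks the Poisson estimator's calibration; with
#' them on it quantifies their impact.
#'
#' @param true_copies_per_ul_template True template concentration.
#' @param n_chips Number of simulated chips (>= 100 for stable summaries).
#' @param assay An [assay_config()].
#' @param params Optional [sim_params()] carrying error processes; by
#'   default all error processes are off and the concentration is taken from
#'   `true_copies_per_ul_template`.
#' @param seed Optional integer for reproducibility.
#'
#' @return A one-row tibble: `true_copies_per_ul_template`, `n_chips`,
#'   `mean_estimate`, `bias_pct`, `rmse`, `ci_coverage_pct`.
#' @examples
#' recovery_experiment(7500, n_chips = 100, seed = 1)
#' @export
recovery_experiment <- function(true_copies_per_ul_template, n_chips = 500,
                                assay = assay_config(), params = NULL,
                                seed = NULL) {
  if (n_chips < 2) abort("`n_chips` must be >= 2.")
  if (is.null(params)) {
    params <- sim_params(true_copies_per_ul_template,
                         false_positive_rate_per_well = 0)
  } else {
    params$true_copies_per_ul_template <- true_copies_per_ul_template
  }
  chips <- simulate_chips(n_chips, params, assay, seed = seed)
  est <- quantify_chips(chips, assay)
  truth <- true_copies_per_ul_template
  tibble(
    true_copies_per_ul_template = truth,
    n_chips = n_chips,
    mean_estimate = mean(est$copies_per_ul_template),
    bias_pct = 100 * (mean(est$copies_per_ul_template) - truth) / truth,
    rmse = sqrt(mean((est$copies_per_ul_template - truth)^2)),
    ci_coverage_pct = 100 * mean(est$ci_low <= truth & truth <= est$ci_high)
  )
}
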