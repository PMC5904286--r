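---
title: "Methods: Poisson quantification, assay validation and power analysis for chip digital PCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Poisson quantification, assay validation and power analysis for chip digital PCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdpcr)
```

## The estimation model

Chip digital PCR distributes a reaction across ~20,000 wells of ~0.755 nl
and reads each qualified well as positive or negative after end-point
amplification. Under the Poisson partitioning assumption — template
molecules settle into wells independently and uniformly — the fraction of
negative wells estimates `exp(-λ)`, so the mean copies per well is
`λ̂ = −ln(1 − P/N)` for `P` positives among `N` qualified wells. This is
the binomial maximum-likelihood estimator; no standard curve is involved.
Two deterministic scalings convert occupancy to concentration: division by
the well volume gives copies/µl of reaction, and the dilution factor `D`
(reaction volume over template volume, 20 by default) returns to the
template scale on which results are reported.

The assumptions that matter in practice: molecules must be monodisperse
(aggregated or cell-bound template violates Poisson), a single genomic
target locus must map one-to-one to one genome, and amplification must be
all-or-nothing per well. The well-count arithmetic is agnostic to why a
well failed to qualify; we treat qualified wells as a simple random
subsample of the chip.

### Confidence intervals and precision

Uncertainty enters through the binomial positive fraction. The default
interval is the normal approximation on `p = P/N` transformed through
`λ = −ln(1−p)` — equivalent to the delta method with
`se_λ = se_p / (1 − p)` to first order — with Wilson and Clopper–Pearson
exact intervals available via `assay_config(ci_method=)` for low-count
work. Precision is reported the way chip readers report it, as the upper
bound's excess over the estimate, `(λ_hi/λ̂ − 1) × 100%`. Vendor software
computes a proprietary variant that includes terms we cannot reconstruct;
on published chip tables our delta-method values track the vendor column
within about 10% relative for chips with at least ~100 positive wells, and
the package documents precision as an approximation, not a reproduction,
of vendor output. For a chip with zero positives the point estimate is 0
and precision is undefined (flagged `ZERO_POSITIVE`); the interval upper
bound falls back to the exact binomial bound so the chip still carries
information. A fully saturated chip (`P = N`) has no finite estimate and is
flagged `SATURATED_FULL` rather than returning infinity; the scalar
`poisson_lambda()` treats the same condition as an error because there is
no row to flag.

### Key parameters

| parameter | default | units | why |
|---|---|---|---|
| `well_volume_ul` | 7.55e-4 | µl | chip well volume; fixed by the chip hardware. Reproduces published chip tables from their well counts to within 0.5% on internally consistent rows |
| `reaction/template volume` | 20 / 1 | µl | defines `D = 20`, the factor from reaction scale back to template scale |
| `loaded_volume_ul` | 14.5 | µl | volume actually pushed onto the chip; note 20,000 × 0.755 nl = 15.1 µl > 14.5 µl, which is why a sizeable minority of wells never fill or qualify |
| `min_qualified_wells` | 10,000 | wells | LoQ criterion: below this the binomial `N` is too small for the advertised precision |
| `saturation_bounds` | 0.05–0.90 | fraction | outside this occupancy window the estimator's variance explodes (low end) or the log transform amplifies count noise (high end) |
| `max_precision_pct` | 10 | % | per-chip LoQ criterion |
| `max_group_rsd_pct` | 15 | % | replicate-consistency LoQ criterion |

## The validation workflow

`validate_series()` runs, in order: per-chip quantification; replicate
grouping by design concentration (mean, sample SD, %RSD); false-positive
rate and limit of detection from the no-template controls; limit of
quantification from the three QC criteria; empirical dynamic range;
log–log linearity.

**LoD** is the mean apparent concentration of the NTC chips — the
convention that a sample is detected only above the blank's signal. A
`mean + k·sd` variant exists (`determine_lod(method = "mean_sd")`) but is
off by default, matching the plain-mean convention. **False-positive
rate** pools wells across NTC chips (total positives over total
qualified); per-chip averaging is available but the pooled form is the one
consistent with published summaries to two decimals. **LoQ** requires
*every* replicate chip of a group to meet the precision and well-count
criteria and the group to meet the RSD criterion; the paper-style
pass/fail pattern across dilution groups is consistent with this
all-chips reading, and it is the conservative choice. The LoQ is then the
lowest-concentration passing group's mean measured concentration.
**Linearity** regresses log10 mean measured on log10 theoretical
concentration by OLS and reports `slope × 100` as efficiency. The
log–log convention weights each decade equally and makes proportional
biases visible as intercept, not slope; a linear-axes switch is provided.
Regression conventions differ across published reports and a group-level
outlier can move the slope appreciably, so efficiency is best read
alongside `r²`.

## Power analysis for replicate planning

To compare enumeration methods with very different dispersion (plate
counts at ~15% RSD, flow cytometry ~10%, cdPCR ~4–5%), both the detectable
difference and the SD are expressed as percent of the common mean, so the
standardized effect is `δ/σ = delta_pct/rsd_pct`. Power of the two-sided
two-sample pooled t test is evaluated exactly through the noncentral t
distribution (df `2n−2`, noncentrality `(δ/σ)√(n/2)`);
`detectable_difference()` inverts it by root finding and
`required_replicates()` walks n upward. The defaults — two-sample model,
α = 0.05, power = 0.80 — are the convention under which the published
replicate table (17 plate-count replicates, 25 at 12.2%, 9 for flow
cytometry) is reproduced exactly; a paired-design option is provided but
does not reproduce those counts. One rounding ambiguity is inherent: at
`δ = 15%, σ = 10%`, n = 9 is the smallest design whose detectable
difference drops to 15%, but its achieved detectable difference is 14.1%,
so tables quoting the difference at the chosen n will disagree slightly
with tables quoting the n for a target difference.

## The chip simulator

`simulate_chips()` draws what an instrument would report, given truth:

1. qualified wells `N ~ uniform{15,000, …, 18,200}` — the span observed on
   real chips; dropout is independent of occupancy since no mechanism
   links the two in available data;
2. occupied wells `~ Binomial(N, 1 − exp(−λ_eff))`, the exact consequence
   of per-well Poisson occupancy;
3. false negatives thin the occupied wells; false positives add
   `Binomial(N − occupied, fp_rate)` (defaults 0 and 0.0114 — the latter
   matching a published assay's NTC floor);
4. viability effects act on concentration:
   `λ_eff ∝ true × (lysis × (1 − dead) + dead × (1 − pma_efficacy))`.
   Dead-cell DNA is a concentration multiplier, not a per-molecule state —
   sufficient for testing monotonicity and the ~1-log PMA knockdown, and
   nothing downstream distinguishes the two.

What the simulator deliberately omits: amplification kinetics and partial
inhibition, spatial structure in well dropout, aggregation/chained cells,
and inter-target competition in multiplexed runs. Consequently, passing
round-trip tests demonstrates that the estimator inverts the partitioning
model correctly and that the validation criteria behave as designed — not
that real chips satisfy Poisson partitioning; that is an experimental
claim the wet-lab dilution series itself has to support.

`recovery_experiment()` closes the loop: at 500 chips with error processes
off, relative bias of simulate→estimate stays below 1% across the
theoretical dynamic range and 95% CI coverage lands in [92%, 98%]. The
test suite runs these at 200–500 chips and a handful of concentrations;
the acceptance script uses 500 chips — sizes at which the binomial Monte
Carlo error is comfortably below the tolerances being asserted.

## Numerical choices and degenerate inputs

* `log1p(-p)` rather than `log(1-p)` for small-`p` accuracy; at
  `p < 0.02` the estimator agrees with naive counting (`λ ≈ p`) within 1%.
* Root finding for the detectable difference runs on the standardized
  effect scale to 1e-10 absolute tolerance, then rescales by the SD — this
  makes linearity in `rsd_pct` exact, not approximate.
* Replicate search starts at n = 2 (the smallest design with positive df)
  and is capped at 1e6.
* Zero-variance groups in `compare_methods()` follow the convention
  t = 0, p = 1 when means are equal, p = 0 otherwise.
* Group summaries use the sample SD (n−1); single-chip groups report `NA`
  dispersion and cannot pass the LoQ RSD criterion.
* Reported tables round the way laboratory reports do — integer copies/µl,
  integer %RSD, two-decimal false-positive percent, two-significant-figure
  theoretical range — while machine-readable outputs keep full precision.

## Known limitations

* The vendor's chip-precision formula is not public; our delta-method
  value is a faithful approximation except at extreme low counts (a
  2-positive chip), where no binomial approximation applies.
* LoD from a mean of three NTC chips inherits their large relative spread;
  with NTC chips as discordant as 2 vs 139 positives the mean is a blunt
  summary, which is why the `mean_sd` variant exists.
* Efficiency/linearity depends on the regression convention when a
  dilution group is an outlier; we report the convention used rather than
  claiming uniqueness.
* The simulator validates statistics, not chemistry: inhibition,
  sub-lethal injury, and PMA's dependence on membrane state are outside
  its scope.
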