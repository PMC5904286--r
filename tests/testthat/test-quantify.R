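test_that("poisson_lambda matches direct evaluation and handles edge cases", {
  expect_identical(poisson_lambda(0, 17000), 0)
  expect_equal(poisson_lambda(1024, 17265), 0.0611424216, tolerance = 1e-8)
  # recomputed with high-precision arithmetic from the well counts
  expect_equal(poisson_lambda(12655, 16079), 1.5467046145, tolerance = 1e-8)
  expect_error(poisson_lambda(100, 100), "Saturated")
  expect_error(poisson_lambda(0, 0), "Empty chip")
  expect_error(poisson_lambda(5, 3), "cannot exceed")
  expect_error(poisson_lambda(2.5, 10), "integers")
})

test_that("lambda estimate is increasing in P and depends only on P/N", {
  N <- 12000
  lam <- poisson_lambda(seq(100, 11000, by = 500), N)
  expect_true(all(diff(lam) > 0))
  for (p in c(0.01, 0.2, 0.75)) {
    lams <- vapply(c(1e3, 1e4, 1e5), function(n) poisson_lambda(p * n, n),
                   numeric(1))
    expect_equal(max(lams) - min(lams), 0, tolerance = 1e-12)
  }
})

test_that("lambda agrees with the linear counting limit at low occupancy", {
  for (p in c(0.001, 0.005, 0.019)) {
    N <- 20000
    lam <- poisson_lambda(round(p * N), N)
    frac <- round(p * N) / N
    expect_lt(abs(lam - frac) / frac, 0.01)
  }
})

test_that("brute-force partition enumeration agrees with the Poisson estimator", {
  # All molecule-to-well assignments of m molecules in W wells enumerated
  # exactly; the estimator applied at the exact expected positive fraction
  # must equal -m*log(1 - 1/W), the closed-form occupancy rate.
  for (W in c(3, 6, 12)) {
    for (m in 1:4) {
      enum <- enumerate_occupancy(W, m)
      lam_enum <- poisson_lambda(enum$total_occupied, enum$total_wells)
      expect_equal(lam_enum, -m * log(1 - 1 / W), tolerance = 1e-9)
    }
  }
})

test_that("quantify_chips reproduces published concentrations on anchor chips", {
  est <- quantify_chips(make_chips(c(1024, 567, 201),
                                   c(17265, 16814, 17167)))
  expect_equal(est$copies_per_ul_template, c(1620, 909, 312),
               tolerance = 0.005)
  # reaction/template scales differ by exactly the dilution factor
  expect_equal(est$copies_per_ul_template, 20 * est$copies_per_ul_reaction)
})

test_that("template concentration is equivariant in the dilution factor", {
  chips <- make_chips(1500, 16000)
  e1 <- quantify_chips(chips, assay_config(template_volume_ul = 1))
  e2 <- quantify_chips(chips, assay_config(template_volume_ul = 0.5))
  expect_equal(e2$copies_per_ul_template, 2 * e1$copies_per_ul_template)
  expect_equal(e2$copies_per_ul_reaction, e1$copies_per_ul_reaction)
})

test_that("confidence interval brackets the estimate and tightens with N", {
  for (method in c("normal", "wilson", "exact")) {
    assay <- assay_config(ci_method = method, total_wells = 200000L)
    p <- 0.3
    est <- quantify_chips(make_chips(p * c(1e3, 1e4, 1e5),
                                     c(1e3, 1e4, 1e5)), assay)
    expect_true(all(est$ci_low <= est$copies_per_ul_template))
    expect_true(all(est$copies_per_ul_template <= est$ci_high))
    width <- est$ci_high - est$ci_low
    expect_true(all(diff(width) < 0))
    expect_true(all(diff(est$precision_pct) < 0))
  }
})

test_that("precision approximates the published chip-precision column", {
  # Delta-method (and the published vendor value) within 15% relative on
  # every chip with >= 100 positives; the 2-positive NTC chip is excluded
  # because a binomial normal approximation is meaningless at P = 2 and the
  # vendor formula for that regime is undocumented.
  for (tbl in list(list(chips = bl04_chips, pub = bl04_published),
                   list(chips = ncfm_chips, pub = ncfm_published))) {
    keep <- tbl$chips$positive_wells >= 100
    est <- quantify_chips(tbl$chips)
    rel <- abs(est$precision_pct[keep] / tbl$pub$precision_pct[keep] - 1)
    expect_lt(max(rel), 0.15)
  }
})

test_that("degenerate chips are flagged, not dropped", {
  assay <- assay_config()
  est <- quantify_chips(make_chips(c(0, 16000, 100, 15000),
                                   c(16000, 16000, 8000, 16000)), assay)
  expect_match(est$qc_flags[1], "ZERO_POSITIVE")
  expect_identical(est$copies_per_ul_template[1], 0)
  expect_true(est$ci_high[1] > 0)          # upper bound still informative
  expect_true(is.na(est$precision_pct[1]))
  expect_identical(est$qc_flags[2], "SATURATED_FULL")
  expect_true(is.na(est$copies_per_ul_template[2]))
  expect_match(est$qc_flags[3], "LOW_WELLS")
  expect_match(est$qc_flags[3], "UNDER_SATURATED")
  expect_identical(est$qc_flags[4], "OVER_SATURATED")
})

test_that("theoretical dynamic range reproduces the loading arithmetic", {
  rng <- theoretical_dynamic_range(assay_config(), 1000, 18000)
  expect_equal(rng$copies_per_ul_template, c(20000 / 14.5, 360000 / 14.5))
  expect_equal(signif(rng$copies_per_ul_template, 2), c(1400, 25000))
  # defaults derive the same bounds from the saturation window
  expect_equal(theoretical_dynamic_range(assay_config()), rng)
  # unit-dilution sanity: no template dilution, 1450 wells in 14.5 ul
  unit <- assay_config(reaction_volume_ul = 20, template_volume_ul = 20)
  expect_equal(
    theoretical_dynamic_range(unit, 1450, 18000)$copies_per_ul_template[1],
    100)
  expect_error(theoretical_dynamic_range(assay_config(), 0, 18000))
  # Poisson-corrected variant is strictly wider at the top end
  pc <- theoretical_dynamic_range(assay_config(), poisson_corrected = TRUE)
  expect_gt(pc$copies_per_ul_template[2], rng$copies_per_ul_template[2])
})

test_that("copies_per_gram applies the preparation chain multiplicatively", {
  expect_equal(copies_per_gram(1000, 1, 1e6), 1e9)
  expect_equal(copies_per_gram(2000, 11, 99e3, dilution_factors = 10), 1.8e8)
  expect_equal(
    copies_per_gram(123, 2, 5e4, dilution_factors = c(10, 4)),
    copies_per_gram(123, 2, 5e4, dilution_factors = c(4, 10)))
  expect_error(copies_per_gram(100, 0, 1e3), "positive")
})
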