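test_that("group summaries use sample SD and %RSD of the mean", {
  # published replicate trio: mean 1974, sd 107, RSD 5%
  est <- tibble::tibble(copies_per_ul_template = c(2024, 2047, 1852),
                        theoretical_copies_per_ul = 2657, is_ntc = FALSE)
  g <- summarize_groups(est)
  expect_equal(round(g$mean_copies_per_ul), 1974)
  expect_equal(round(g$sd_copies_per_ul), 107)
  expect_equal(round(g$rsd_pct), 5)

  same <- summarize_groups(tibble::tibble(copies_per_ul_template = rep(500, 3)))
  expect_equal(same$sd_copies_per_ul, 0)
  expect_equal(same$rsd_pct, 0)

  low <- summarize_groups(tibble::tibble(copies_per_ul_template = c(388, 393, 392)))
  expect_equal(round(low$mean_copies_per_ul), 391)
  expect_equal(low$sd_copies_per_ul, sd(c(388, 393, 392)))

  single <- summarize_groups(tibble::tibble(copies_per_ul_template = 100))
  expect_true(is.na(single$sd_copies_per_ul))
})

test_that("%RSD is scale invariant", {
  x <- c(388, 393, 392, 512)
  for (k in c(0.01, 3, 1e4)) {
    expect_equal(
      summarize_groups(tibble::tibble(copies_per_ul_template = k * x))$rsd_pct,
      summarize_groups(tibble::tibble(copies_per_ul_template = x))$rsd_pct)
  }
})

test_that("false-positive rate reproduces both published NTC panels", {
  bl04_ntc <- make_chips(c(201, 173, 197), c(17167, 16677, 16288), is_ntc = TRUE)
  ncfm_ntc <- make_chips(c(120, 139, 2), c(17520, 15634, 17515), is_ntc = TRUE)
  expect_equal(round(false_positive_rate(bl04_ntc), 2), 1.14)
  expect_equal(round(false_positive_rate(ncfm_ntc), 2), 0.52)
  expect_equal(false_positive_rate(make_chips(c(0, 0, 0), rep(17000, 3),
                                              is_ntc = TRUE)), 0)
  # per-chip averaging variant stays close but is not the default
  expect_equal(round(false_positive_rate(bl04_ntc, method = "mean"), 2), 1.14)
  expect_error(false_positive_rate(make_chips(1, 10, is_ntc = FALSE)), "NTC")
  expect_error(false_positive_rate(bl04_ntc[0, ]), "No NTC")
})

test_that("LoD is the mean apparent NTC concentration", {
  bl04 <- quantify_chips(make_chips(c(201, 173, 197), c(17167, 16677, 16288),
                                    is_ntc = TRUE))
  ncfm <- quantify_chips(make_chips(c(120, 139, 2), c(17520, 15634, 17515),
                                    is_ntc = TRUE))
  expect_equal(determine_lod(bl04), 303, tolerance = 0.01)
  expect_equal(determine_lod(ncfm), 141, tolerance = 0.01)
  zeros <- quantify_chips(make_chips(c(0, 0), c(17000, 17000), is_ntc = TRUE))
  expect_equal(determine_lod(zeros), 0)
  expect_gt(determine_lod(bl04, method = "mean_sd"), determine_lod(bl04))
  expect_error(determine_lod(bl04[0, ]), "No NTC")
})

test_that("LoQ picks the lowest group passing all three criteria", {
  est <- quantify_chips(bl04_chips)
  res <- determine_loq(est)
  # the 2,657-target group passes; every lower group fails on precision
  expect_equal(res$loq_copies_per_ul, 1974, tolerance = 0.005)
  d <- res$diagnostics
  expect_true(d$passes[d$theoretical_copies_per_ul == 2657])
  expect_false(any(d$passes[d$theoretical_copies_per_ul < 2657]))
  expect_false(all(d$precision_ok[d$theoretical_copies_per_ul == 664]))

  # all groups failing -> undetermined, with diagnostics intact
  strict <- assay_config(max_precision_pct = 0.5)
  res2 <- determine_loq(est, strict)
  expect_true(is.na(res2$loq_copies_per_ul))
  expect_false(any(res2$diagnostics$passes))
})

test_that("tightening the precision criterion can only raise the LoQ", {
  est <- quantify_chips(bl04_chips)
  loqs <- vapply(c(12, 10, 8, 5, 3), function(pmax) {
    determine_loq(est, assay_config(max_precision_pct = pmax))$loq_copies_per_ul
  }, numeric(1))
  loqs <- loqs[!is.na(loqs)]
  expect_true(all(diff(loqs) >= 0))
})

test_that("LoQ distinguishes an engineered pass/fail boundary", {
  # two groups: plenty of wells (tight precision) vs few wells (loose)
  assay <- assay_config(min_qualified_wells = 0)
  hi <- make_chips(rep(1500, 3), rep(17000, 3), theoretical = 2000)
  lo <- make_chips(rep(15, 3), rep(170, 3), theoretical = 2000 / 2)
  lo$chip_id <- paste0("lo", 1:3)
  res <- determine_loq(quantify_chips(rbind(hi, lo), assay), assay)
  d <- res$diagnostics
  expect_true(d$passes[d$theoretical_copies_per_ul == 2000])
  expect_false(d$passes[d$theoretical_copies_per_ul == 1000])
  expect_equal(res$loq_copies_per_ul,
               mean(quantify_chips(hi, assay)$copies_per_ul_template))
})

test_that("empirical dynamic range spans group means above the LoD", {
  groups <- summarize_groups(quantify_chips(bl04_chips))
  rng <- empirical_dynamic_range(groups, lod = 303.5)
  expect_equal(rng$copies_per_ul_template[1], 391, tolerance = 0.005)
  expect_equal(rng$copies_per_ul_template[2], 42512, tolerance = 0.02)
  # all means below LoD -> undetermined
  expect_warning(
    rng0 <- empirical_dynamic_range(groups, lod = 1e7), "undetermined")
  expect_true(all(is.na(rng0$copies_per_ul_template)))
  # a single group above the LoD collapses the range to a point
  one <- groups[groups$theoretical_copies_per_ul %in% 42512, ]
  rng1 <- empirical_dynamic_range(one, lod = 303.5)
  expect_equal(rng1$copies_per_ul_template[1], rng1$copies_per_ul_template[2])
})

test_that("linearity recovers proportional series exactly", {
  mk <- function(y, x) tibble::tibble(theoretical_copies_per_ul = x,
                                      mean_copies_per_ul = y, is_ntc = FALSE)
  x <- c(100, 400, 1600, 6400)
  fit <- assay_linearity(mk(x, x))
  expect_equal(fit$slope, 1)
  expect_equal(fit$efficiency_pct, 100)
  expect_equal(fit$r_squared, 1)
  # proportional offset moves the intercept, not the slope
  fit2 <- assay_linearity(mk(2 * x, x))
  expect_equal(fit2$slope, 1)
  expect_equal(fit2$intercept, log10(2))
  expect_error(assay_linearity(mk(x[1:2], x[1:2])), "at least 3")
  # closed-form OLS oracle on a non-trivial series, linear axes
  set.seed(7)
  y <- 1.07 * x + rnorm(4, sd = 20)
  fit3 <- assay_linearity(mk(y, x), log_scale = FALSE)
  lx <- x - mean(x); expect_equal(fit3$slope, sum(lx * y) / sum(lx^2))
})

test_that("NCFM dilution series is linear with near-unit efficiency", {
  groups <- summarize_groups(quantify_chips(ncfm_chips))
  fit <- assay_linearity(groups)
  expect_gt(fit$slope, 0.95)
  expect_lt(fit$slope, 1.05)
  expect_gt(fit$r_squared, 0.98)
})

test_that("validate_series assembles the full published report", {
  rep_bl <- validate_series(bl04_chips)
  expect_equal(round(rep_bl$false_positive_rate_pct, 2), 1.14)
  expect_equal(rep_bl$lod_copies_per_ul, 303, tolerance = 0.01)
  expect_equal(rep_bl$loq_copies_per_ul, 1974, tolerance = 0.005)
  expect_equal(rep_bl$empirical_range$copies_per_ul_template[1], 391,
               tolerance = 0.005)
  expect_equal(rep_bl$empirical_range$copies_per_ul_template[2], 42512,
               tolerance = 0.02)

  rep_nc <- validate_series(ncfm_chips)
  expect_equal(round(rep_nc$false_positive_rate_pct, 2), 0.52)
  expect_equal(rep_nc$lod_copies_per_ul, 141, tolerance = 0.01)

  g <- glance(rep_bl)
  expect_identical(nrow(g), 1L)
  expect_equal(g$lod_copies_per_ul, rep_bl$lod_copies_per_ul)
  td <- tidy(rep_bl)
  expect_identical(nrow(td), nrow(rep_bl$groups))
  expect_true(all(c("passes", "rsd_pct") %in% names(td)))
})

test_that("validation report is invariant to input row order", {
  set.seed(11)
  shuffled <- bl04_chips[sample(nrow(bl04_chips)), ]
  a <- validate_series(bl04_chips)
  b <- validate_series(shuffled)
  for (field in c("false_positive_rate_pct", "lod_copies_per_ul",
                  "loq_copies_per_ul")) {
    expect_identical(a[[field]], b[[field]])
  }
  expect_identical(a$groups, b$groups)
  expect_identical(a$empirical_range, b$empirical_range)
})

test_that("validate_series guards its preconditions", {
  expect_error(validate_series(bl04_chips[0, ]), "no rows")
  mixed <- rbind(bl04_chips, ncfm_chips)
  expect_error(validate_series(mixed), "single target")
  no_ntc <- dplyr::filter(bl04_chips, !is_ntc)
  expect_warning(rep_nn <- validate_series(no_ntc), "No NTC")
  expect_true(is.na(rep_nn$lod_copies_per_ul))
  expect_true(is.na(rep_nn$false_positive_rate_pct))
  one_group <- dplyr::filter(bl04_chips, theoretical_copies_per_ul %in% 2657)
  expect_error(validate_series(one_group), "2 dilution groups")
})

test_that("simulated series round-trips through the validator", {
  params <- sim_params(24000, false_positive_rate_per_well = 0.0114)
  series <- simulate_dilution_series(params, dilution_factors = 2^(0:5),
                                     replicates = 3, n_ntc = 3, seed = 303)
  rep_sim <- validate_series(series)
  # linearity close to ideal, FP floor close to the generating rate
  expect_gt(rep_sim$linearity$r_squared, 0.99)
  expect_equal(rep_sim$linearity$slope, 1, tolerance = 0.1)
  fp_implied <- -log(1 - 0.0114) / 7.55e-4 * 20
  expect_equal(rep_sim$lod_copies_per_ul, fp_implied, tolerance = 0.25)
  # with no false positives at all: FP rate 0 and LoD 0
  clean <- simulate_dilution_series(
    sim_params(24000, false_positive_rate_per_well = 0),
    dilution_factors = 2^(0:3), seed = 404)
  rep_clean <- validate_series(clean)
  expect_identical(rep_clean$false_positive_rate_pct, 0)
  expect_identical(rep_clean$lod_copies_per_ul, 0)
})
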