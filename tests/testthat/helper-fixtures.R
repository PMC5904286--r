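# Shared fixtures: the packaged dilution-series tables and the published
# per-chip values they were transcribed with (copies/ul and chip precision,
# in fixture row order).

bl04_path <- system.file("extdata", "bl04_dilution_series.csv", package = "cdpcr")
ncfm_path <- system.file("extdata", "ncfm_dilution_series.csv", package = "cdpcr")

bl04_chips <- read_chip_table(bl04_path)
ncfm_chips <- read_chip_table(ncfm_path)

bl04_published <- tibble::tibble(
  chip_id = bl04_chips$chip_id,
  copies_per_ul = c(41546, 40684, 45307, 20558, 21637, 9747, 10086, 9776,
                    2024, 2047, 1852, 594, 623, 587, 425, 423, 489,
                    388, 393, 392, 312, 276, 322),
  precision_pct = c(1.97, 1.84, 1.93, 2.08, 2.15, 2.72, 2.65, 2.75,
                    5.82, 5.95, 6.00, 10.62, 10.63, 11.40, 12.45, 12.27,
                    11.80, 12.82, 13.49, 13.43, 14.83, 16.07, 14.99)
)

ncfm_published <- tibble::tibble(
  chip_id = ncfm_chips$chip_id,
  copies_per_ul = c(30201, 16083, 17390, 15989, 7704, 7057, 7268,
                    1620, 1823, 1634, 909, 891, 794, 503, 441, 610,
                    287, 289, 306, 182, 237, 3),
  precision_pct = c(1.98, 2.30, 2.34, 2.27, 3.09, 3.21, 3.13,
                    6.32, 6.08, 6.22, 8.58, 8.66, 8.97, 11.64, 12.07,
                    10.21, 16.17, 15.32, 15.32, 19.59, 18.09, 299.85)
)

# Chips whose published copies/ul is consistent with its own row's well
# counts (some low-dilution rows were printed shuffled within their group).
row_consistent <- function(chips, published, assay = assay_config(),
                           tol = 0.005) {
  est <- quantify_chips(chips, assay)
  abs(est$copies_per_ul_template / published$copies_per_ul - 1) < tol
}

# Exact expected positive fraction of a toy chip by brute-force enumeration
# of all wells^molecules equally likely molecule-to-well assignments.
# Returns the total occupied-well count over all assignments and the number
# of (assignment, well) pairs, an exact rational for the expected fraction.
enumerate_occupancy <- function(wells, molecules) {
  assignments <- as.matrix(expand.grid(rep(list(seq_len(wells)), molecules)))
  occupied <- apply(assignments, 1, function(a) length(unique(a)))
  list(total_occupied = sum(occupied), total_wells = nrow(assignments) * wells)
}

make_chips <- function(P, N, theoretical = NA_real_, is_ntc = FALSE,
                       target_id = "T") {
  tibble::tibble(
    chip_id = paste0("c", seq_along(P)),
    target_id = target_id,
    theoretical_copies_per_ul = theoretical,
    qualified_wells = N,
    positive_wells = P,
    is_ntc = is_ntc
  )
}
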