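chip_table_cols <- c("chip_id", "target_id", "theoretical_copies_per_ul",
                     "qualified_wells", "positive_wells", "is_ntc")

#' Read a chip-record CSV
#'
#' Reads per-chip digital PCR records from CSV with header columns
#' `chip_id, target_id, theoretical_copies_per_ul, qualified_wells,
#' positive_wells, is_ntc` (the last two of which
#' may be omitted; `theoretical_copies_per_ul` may be empty for NTC chips).
#' Every row is validated — non-negative integer well counts, positives not
#' exceeding qualified wells — and offending rows are reported by line
#' number.
#'
#' @param path Path to a CSV file.
#' @return A tibble of validated chip records.
#' @examples
#' read_chip_table(
#'   system.file("extdata", "ncfm_dilution_series.csv", package = "cdpcr")
#' )
#' @export
read_chip_table <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  chips <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(paste0("Cannot parse ", path, ": ",
                                     conditionMessage(e)))
  )
  if (nrow(chips) == 0) abort(paste0(path, " contains no chip records."))
  required <- c("chip_id", "target_id", "qualified_wells", "positive_wells")
  missing_cols <- setdiff(required, names(chips))
  if (length(missing_cols)) {
    abort(paste0(path, " is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  if (!"theoretical_copies_per_ul" %in% names(chips)) {
    chips$theoretical_copies_per_ul <- NA_real_
  }
  if (!"is_ntc" %in% names(chips)) chips$is_ntc <- FALSE
  chips$is_ntc <- as.logical(chips$is_ntc)

  bad <- function(cond, why) {
    rows <- which(cond)
    if (length(rows)) {
      # +1 for the header line
      abort(paste0(path, ": ", why, " at line(s) ",
                   paste(rows + 1, collapse = ", "), "."))
    }
  }
  for (col in c("qualified_wells", "positive_wells")) {
    v <- chips[[col]]
    bad(!is.finite(v) | v < 0 | v != round(v),
        paste0("non-integer or negative ", col))
  }
  bad(chips$positive_wells > chips$qualified_wells,
      "positive_wells exceeds qualified_wells")
  bad(is.na(chips$is_ntc), "is_ntc is not TRUE/FALSE")
  chips[union(intersect(chip_table_cols, names(chips)),
              setdiff(names(chips), chip_table_cols))]
}

#' Write chip records to CSV
#'
#' Writes the documented chip-record format; ground-truth columns from the
#' simulator are preserved if present. Round-trips with [read_chip_table()].
#'
#' @param chips A chip-record data frame.
#' @param path Output CSV path.
#' @return `chips`, invisibly.
#' @export
write_chip_table <- function(chips, path) {
  readr::write_csv(as_tibble(chips), path, progress = FALSE)
  invisible(chips)
}

#' Read an assay configuration from YAML or JSON
#'
#' The file holds any subset of [assay_config()]'s arguments by name;
#' unspecified fields keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `cdpcr_assay` object.
#' @export
read_assay_config <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  fields <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort("Assay config must be a .yaml/.yml or .json file.")
  }
  unknown <- setdiff(names(fields), names(formals(assay_config)))
  if (length(unknown)) {
    abort(paste0("Unknown assay config field(s): ",
                 paste(unknown, collapse = ", "), "."))
  }
  do.call(assay_config, fields)
}

#' Write a validation report to JSON (and optionally a text table)
#'
#' The JSON carries full-precision machine-readable values; the text rendering
#' follows the usual display conventions (integer copies/µl, integer %RSD,
#' two-decimal false-positive percentage, two-significant-figure theoretical
#' range).
#'
#' @param report A `cdpcr_validation` object from [validate_series()].
#' @param path Output JSON path.
#' @param text_path Optional path for the human-readable rendering.
#' @return `report`, invisibly.
#' @export
write_validation_report <- function(report, path, text_path = NULL) {
  stopifnot(inherits(report, "cdpcr_validation"))
  payload <- list(
    target_id = report$target_id,
    n_chips = report$n_chips,
    false_positive_rate_pct = report$false_positive_rate_pct,
    lod_copies_per_ul = report$lod_copies_per_ul,
    loq_copies_per_ul = report$loq_copies_per_ul,
    theoretical_range = report$theoretical_range,
    empirical_range = report$empirical_range,
    linearity = report$linearity,
    groups = report$groups,
    loq_diagnostics = report$loq_diagnostics,
    estimates = report$estimates
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(text_path)) {
    writeLines(utils::capture.output(print(report)), text_path)
  }
  invisible(report)
}

# --- command-line surface ---------------------------------------------------

cli_usage <- paste(
  "usage: cdpcr <command> [--flag value ...]",
  "",
  "commands:",
  "  quantify  --input chips.csv --out estimates.csv [--assay cfg.yaml]",
  "  validate  --input chips.csv --out report.json [--txt report.txt] [--assay cfg.yaml]",
  "  simulate  --scenario scenario.yaml --out chips.csv [--seed 1]",
  "  power     --spec spec.csv --out table.csv [--alpha 0.05] [--power 0.8]",
  "  compare   --input measurements.csv --out comparison.json [--alpha 0.05]",
  sep = "\n"
)

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    if (!grepl("^--", args[i]) || i == length(args)) {
      abort(paste0("Cannot parse argument '", args[i], "'.\n", cli_usage))
    }
    flags[[sub("^--", "", args[i])]] <- args[i + 1]
    i <- i + 2
  }
  flags
}

cli_assay <- function(flags) {
  if (is.null(flags$assay)) assay_config() else read_assay_config(flags$assay)
}

cli_need <- function(flags, nm, cmd) {
  if (is.null(flags[[nm]])) {
    abort(paste0("`", cmd, "` requires --", nm, ".\n", cli_usage))
  }
  flags[[nm]]
}

#' Command-line entry point
#'
#' Dispatches the `quantify`, `validate`, `simulate`, `power` and `compare`
#' subcommands over the package's functions; the installed script
#' `system.file("cli", "cdpcr", package = "cdpcr")` wraps this for shell
#' use. A `simulate` scenario file is YAML with [sim_params()] fields plus
#' optional `dilution_factors`, `replicates`, `n_ntc` and `target_id`; a
#' `power` spec CSV has columns `method,rsd_pct,n_replicates,`
#' `detectable_difference_pct`; a `compare` input CSV has columns
#' `group,value` with exactly two groups.
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   process's trailing arguments).
#' @return Exit status, invisibly: 0 on success, 1 on error, 2 on usage
#'   error.
#' @export
cdpcr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 ||
      !args[1] %in% c("quantify", "validate", "simulate", "power", "compare")) {
    message(cli_usage)
    return(invisible(2L))
  }
  cmd <- args[1]
  status <- tryCatch({
    flags <- parse_cli_flags(args[-1])
    switch(cmd,
      quantify = {
        chips <- read_chip_table(cli_need(flags, "input", cmd))
        est <- quantify_chips(chips, cli_assay(flags))
        readr::write_csv(est, cli_need(flags, "out", cmd), progress = FALSE)
      },
      validate = {
        chips <- read_chip_table(cli_need(flags, "input", cmd))
        report <- validate_series(chips, cli_assay(flags))
        write_validation_report(report, cli_need(flags, "out", cmd),
                                text_path = flags$txt)
      },
      simulate = {
        scenario <- yaml::read_yaml(cli_need(flags, "scenario", cmd))
        seed <- if (!is.null(flags$seed)) as.integer(flags$seed)
        message("simulate: seed = ", ifelse(is.null(seed), "none", seed))
        series_fields <- c("dilution_factors", "replicates", "n_ntc",
                           "target_id")
        params <- do.call(sim_params,
                          scenario[setdiff(names(scenario), series_fields)])
        extra <- scenario[intersect(names(scenario), series_fields)]
        chips <- do.call(simulate_dilution_series,
                         c(list(params = params, seed = seed), extra))
        write_chip_table(chips, cli_need(flags, "out", cmd))
      },
      power = {
        specs <- readr::read_csv(cli_need(flags, "spec", cmd),
                                 show_col_types = FALSE, progress = FALSE)
        alpha <- if (is.null(flags$alpha)) 0.05 else as.numeric(flags$alpha)
        pw <- if (is.null(flags$power)) 0.80 else as.numeric(flags$power)
        readr::write_csv(power_table(specs, alpha = alpha, power = pw),
                         cli_need(flags, "out", cmd), progress = FALSE)
      },
      compare = {
        df <- readr::read_csv(cli_need(flags, "input", cmd),
                              show_col_types = FALSE, progress = FALSE)
        if (!all(c("group", "value") %in% names(df))) {
          abort("compare input needs `group` and `value` columns.")
        }
        gs <- split(df$value, df$group)
        if (length(gs) != 2) abort("compare input needs exactly two groups.")
        alpha <- if (is.null(flags$alpha)) 0.05 else as.numeric(flags$alpha)
        cmp <- compare_methods(gs[[1]], gs[[2]], alpha = alpha)
        out <- c(list(group_names = names(gs)),
                 lapply(unclass(cmp), as.list))
        jsonlite::write_json(out, cli_need(flags, "out", cmd),
                             auto_unbox = TRUE, digits = NA)
      }
    )
    0L
  }, error = function(e) {
    message("cdpcr ", cmd, ": ", conditionMessage(e))
    1L
  })
  invisible(status)
}
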