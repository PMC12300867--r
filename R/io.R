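read_table_checked <- function(path, required, numeric_cols, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop(what, " table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad) > 0) {
      stop(what, " table ", path, ": non-numeric value in column '", col,
           "' at row ", bad[1])
    }
    tab[[col]] <- v
  }
  tab
}

read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML config requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Read a parameter set from files
#'
#' Loads a stratum table and a cost table from CSV, and the scalar
#' configuration (discount rate, horizon, dose-response) from JSON or YAML,
#' then validates the assembled set. Column names mirror the published table
#' structure: `sex, age_band, population, mean_intake_g, incidence_per100k,
#' incidence_lo, incidence_hi, prevalence_per100k, prevalence_lo,
#' prevalence_hi, t2d_mort_per100k, t2d_mort_lo, t2d_mort_hi,
#' allcause_mort_per100k, allcause_mort_lo, allcause_mort_hi` for strata and
#' `sex, age_band, annual_outpatient_nhe_usd` for costs. Config keys:
#' `discount_rate`, `horizon_years`, `rr_per_increment`, `rr_ci_low`,
#' `rr_ci_high`, `increment_g`.
#'
#' @param strata_path,cost_path Paths to the two CSV tables.
#' @param config_path Path to the JSON (`.json`) or YAML (`.yaml`/`.yml`)
#'   config.
#' @return A validated [parameter_set()].
#' @seealso [write_parameter_set()] for the inverse; the pair round-trips any
#'   valid set field-for-field.
#' @export
read_parameter_set <- function(strata_path, cost_path, config_path) {
  strata <- read_table_checked(
    strata_path, STRATA_COLUMNS,
    setdiff(STRATA_COLUMNS, c("sex", "age_band")), "strata")
  costs <- read_table_checked(
    cost_path, COST_COLUMNS, "annual_outpatient_nhe_usd", "cost")
  cfg <- read_config(config_path)
  needed <- c("discount_rate", "horizon_years", "rr_per_increment",
              "rr_ci_low", "rr_ci_high", "increment_g")
  missing_keys <- setdiff(needed, names(cfg))
  if (length(missing_keys) > 0) {
    stop("config ", config_path, " is missing key(s): ",
         paste(missing_keys, collapse = ", "))
  }
  parameter_set(
    strata, costs,
    dose_response(cfg$rr_per_increment, cfg$increment_g,
                  cfg$rr_ci_low, cfg$rr_ci_high),
    discount_rate = cfg$discount_rate,
    horizon = cfg$horizon_years
  )
}

#' Write a parameter set to files
#'
#' Writes `strata.csv`, `costs.csv` and `config.json` into `dir`, in the
#' formats [read_parameter_set()] reads.
#'
#' @param ps A [parameter_set()].
#' @param dir Output directory, created if absent.
#' @return Invisibly, the named character vector of file paths written.
#' @export
write_parameter_set <- function(ps, dir) {
  stopifnot(inherits(ps, "parameter_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    strata = file.path(dir, "strata.csv"),
    costs = file.path(dir, "costs.csv"),
    config = file.path(dir, "config.json")
  )
  utils::write.csv(ps$strata, paths["strata"], row.names = FALSE)
  utils::write.csv(ps$costs, paths["costs"], row.names = FALSE)
  dr <- ps$dose_response
  jsonlite::write_json(
    list(discount_rate = ps$discount_rate,
         horizon_years = ps$horizon,
         rr_per_increment = dr$rr,
         rr_ci_low = dr$ci_low,
         rr_ci_high = dr$ci_high,
         increment_g = dr$increment),
    paths["config"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
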