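#' Read a long-format indicator panel
#'
#' Loads one observation per (country, year, indicator) row from a delimited
#' text file in the style of UN SDG data-portal exports. Column names vary
#' between exports, so they are resolved through `schema`. Rows with missing
#' values are dropped; rows with value exactly 0 are treated as missing for
#' the log-scale model and counted separately; negative values are dropped as
#' invalid. A load report accounting for every input row is attached as the
#' `"load_report"` attribute.
#'
#' @param path CSV file with one indicator value per row.
#' @param schema Named character vector mapping the fields `country`, `year`,
#'   `indicator`, `value` to the file's column names.
#' @return Tibble with columns `country_id`, `year`, `indicator_id`, `value`
#'   (all values strictly positive), plus a `load_report` attribute with
#'   counts `total`, `kept`, `dropped_missing`, `dropped_zero`,
#'   `dropped_negative`.
#' @export
read_indicator_panel <- function(path,
                                 schema = c(country = "country", year = "year",
                                            indicator = "indicator", value = "value")) {
  raw <- read_mapped(path, schema, c("country", "year", "indicator", "value"))
  raw <- dplyr::rename(raw, country_id = "country", indicator_id = "indicator")
  raw$year <- as_int(raw$year)
  raw$value <- as_num(raw$value)

  n_total <- nrow(raw)
  missing <- is.na(raw$country_id) | is.na(raw$year) | is.na(raw$value)
  zero <- !missing & raw$value == 0
  negative <- !missing & raw$value < 0
  keep <- !missing & !zero & !negative
  out <- tibble::as_tibble(raw[keep, c("country_id", "year", "indicator_id", "value")])
  if (nrow(out) == 0L) {
    stop("no valid rows in indicator panel '", path, "'", call. = FALSE)
  }
  assert_unique_keys(out, c("country_id", "year", "indicator_id"))
  attr(out, "load_report") <- list(
    total = n_total, kept = sum(keep),
    dropped_missing = sum(missing),
    dropped_zero = sum(zero),
    dropped_negative = sum(negative)
  )
  out
}

#' Read a covariate panel (GDP per capita, Gini, health expenditure)
#'
#' @param path CSV file with one row per country-year.
#' @param schema Named character vector mapping `country`, `year`, `gdp_pc`,
#'   `gini`, `health_exp` to the file's column names.
#' @return Tibble with columns `country_id`, `year`, `gdp_pc`, `gini`,
#'   `health_exp_pct_gdp`; rows with any missing or non-positive covariate are
#'   dropped and counted in the `load_report` attribute. Gini must lie in
#'   (0, 100].
#' @export
read_covariates <- function(path,
                            schema = c(country = "country", year = "year",
                                       gdp_pc = "gdp_pc", gini = "gini",
                                       health_exp = "health_exp_pct_gdp")) {
  raw <- read_mapped(path, schema, c("country", "year", "gdp_pc", "gini", "health_exp"))
  raw <- dplyr::rename(raw, country_id = "country", health_exp_pct_gdp = "health_exp")
  raw$year <- as_int(raw$year)
  for (col in c("gdp_pc", "gini", "health_exp_pct_gdp")) {
    raw[[col]] <- as_num(raw[[col]])
  }
  n_total <- nrow(raw)
  bad <- is.na(raw$country_id) | is.na(raw$year) |
    is.na(raw$gdp_pc) | is.na(raw$gini) | is.na(raw$health_exp_pct_gdp) |
    raw$gdp_pc <= 0 | raw$gini <= 0 | raw$gini > 100 | raw$health_exp_pct_gdp <= 0
  out <- tibble::as_tibble(raw[!bad, c("country_id", "year", "gdp_pc", "gini",
                                       "health_exp_pct_gdp")])
  if (nrow(out) == 0L) stop("no valid rows in covariate panel '", path, "'", call. = FALSE)
  assert_unique_keys(out, c("country_id", "year"))
  attr(out, "load_report") <- list(total = n_total, kept = nrow(out),
                                   dropped = sum(bad))
  out
}

#' Read a country table
#'
#' @param path CSV with columns mappable to `country`, `region`,
#'   `income_group` (optional), `gdp_pc_anchor`.
#' @param schema Column-name map.
#' @return Tibble `country_id`, `region`, `income_group`, `gdp_pc_anchor`.
#'   When the file carries no income-group column, groups are assigned from
#'   `gdp_pc_anchor` via [assign_income_group()].
#' @export
read_countries <- function(path,
                           schema = c(country = "country", region = "region",
                                      gdp_pc_anchor = "gdp_pc_anchor")) {
  raw <- read_mapped(path, schema, c("country", "region", "gdp_pc_anchor"),
                     optional = c(income_group = "income_group"))
  raw <- dplyr::rename(raw, country_id = "country")
  raw$gdp_pc_anchor <- as_num(raw$gdp_pc_anchor)
  if (any(is.na(raw$gdp_pc_anchor) | raw$gdp_pc_anchor <= 0)) {
    stop("non-positive or missing anchor GDP per capita in '", path, "'", call. = FALSE)
  }
  bad_region <- setdiff(unique(raw$region), region_codes())
  if (length(bad_region)) {
    stop("unrecognised region code(s): ", paste(bad_region, collapse = ", "),
         call. = FALSE)
  }
  assert_unique_keys(raw, "country_id")
  if (!"income_group" %in% names(raw)) {
    raw$income_group <- assign_income_group(raw$gdp_pc_anchor)
  }
  tibble::as_tibble(raw[, c("country_id", "region", "income_group", "gdp_pc_anchor")])
}

#' Read indicator metadata (theme, direction of progress)
#'
#' With no `path`, the table shipped with the package covering the 43
#' health-related SDG indicators is used. Direction encodes whether an
#' increase in the indicator is an improvement (`higher_is_better`, e.g.
#' service coverage, health personnel) or a deterioration (`lower_is_better`,
#' e.g. mortality and incidence rates).
#'
#' @param path Optional CSV with columns `indicator`, `theme`, `direction`,
#'   `label`.
#' @return Tibble `indicator_id`, `theme`, `direction`, `label`.
#' @export
read_indicator_meta <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "indicator_meta.csv", package = "prestonloss",
                        mustWork = TRUE)
  }
  meta <- read_csv_chr(path)
  needed <- c("indicator", "theme", "direction", "label")
  if (!all(needed %in% names(meta))) {
    stop("indicator metadata must have columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  meta <- dplyr::rename(meta, indicator_id = "indicator")
  bad_dir <- setdiff(unique(meta$direction), c("higher_is_better", "lower_is_better"))
  if (length(bad_dir)) stop("unknown direction value(s): ",
                            paste(bad_dir, collapse = ", "), call. = FALSE)
  bad_theme <- setdiff(unique(meta$theme), health_themes())
  if (length(bad_theme)) stop("unknown theme(s): ",
                              paste(bad_theme, collapse = ", "), call. = FALSE)
  assert_unique_keys(meta, "indicator_id")
  tibble::as_tibble(meta[, c("indicator_id", "theme", "direction", "label")])
}

#' Construct a growth scenario
#'
#' @param rates Tibble with columns `country_id`, `year`, `rate` (decimal
#'   fractions, e.g. 0.052 for 5.2%/yr).
#' @param scenario_id Label, e.g. `"pre_covid"`.
#' @return The rates tibble with class `growth_scenario` and a `scenario_id`
#'   attribute.
#' @export
growth_scenario <- function(rates, scenario_id) {
  stopifnot(all(c("country_id", "year", "rate") %in% names(rates)))
  if (any(!is.finite(rates$rate)) || any(rates$rate <= -1)) {
    stop("growth rates must be finite and > -1", call. = FALSE)
  }
  assert_unique_keys(rates, c("country_id", "year"))
  out <- tibble::as_tibble(rates[, c("country_id", "year", "rate")])
  out$year <- as.integer(out$year)
  attr(out, "scenario_id") <- scenario_id
  class(out) <- c("growth_scenario", class(tibble::tibble()))
  out
}

#' @export
print.growth_scenario <- function(x, ...) {
  cat(sprintf("<growth_scenario '%s'> %d countries, years %d-%d\n",
              attr(x, "scenario_id"), dplyr::n_distinct(x$country_id),
              min(x$year), max(x$year)))
  NextMethod()
}

#' Read a paired pre/post growth-scenario vintage
#'
#' Each file gives one growth forecast (percent per year) per country per
#' year, in the style of IMF World Economic Outlook vintages. Countries
#' present in only one vintage trigger a coverage warning and are dropped so
#' the two scenarios cover the same country set; country-years missing inside
#' a file's year span are flagged in the `"gaps"` attribute but do not block
#' loading.
#'
#' @param path_pre,path_post CSV files for the baseline (pre-shock) and
#'   revised (post-shock) vintages.
#' @param schema Column-name map for `country`, `year`, `growth_pct`.
#' @return List with elements `pre` and `post`, both [growth_scenario()]
#'   objects storing decimal rates.
#' @export
read_growth_scenarios <- function(path_pre, path_post,
                                  schema = c(country = "country", year = "year",
                                             growth_pct = "growth_pct")) {
  load_one <- function(path, id) {
    raw <- read_mapped(path, schema, c("country", "year", "growth_pct"))
    raw <- dplyr::rename(raw, country_id = "country")
    raw$year <- as_int(raw$year)
    raw$rate <- as_num(raw$growth_pct) / 100
    growth_scenario(raw[, c("country_id", "year", "rate")], id)
  }
  pre <- load_one(path_pre, "pre_covid")
  post <- load_one(path_post, "post_covid")

  only_pre <- setdiff(unique(pre$country_id), unique(post$country_id))
  only_post <- setdiff(unique(post$country_id), unique(pre$country_id))
  if (length(only_pre) || length(only_post)) {
    warning("countries present in one vintage only, dropped: ",
            paste(sort(c(only_pre, only_post)), collapse = ", "), call. = FALSE)
    shared <- intersect(unique(pre$country_id), unique(post$country_id))
    pre <- growth_scenario(pre[pre$country_id %in% shared, ], "pre_covid")
    post <- growth_scenario(post[post$country_id %in% shared, ], "post_covid")
  }
  attr(pre, "gaps") <- scenario_gaps(pre)
  attr(post, "gaps") <- scenario_gaps(post)
  list(pre = pre, post = post)
}

scenario_gaps <- function(scn) {
  span <- seq(min(scn$year), max(scn$year))
  full <- tidyr::expand_grid(country_id = unique(scn$country_id), year = span)
  dplyr::anti_join(full, scn, by = c("country_id", "year"))
}

#' Write loss records and aggregate tables to a results directory
#'
#' Numeric columns are formatted with 17 significant digits so that re-reading
#' the files reproduces the inputs bit-exactly.
#'
#' @param losses Tibble of per-(country, indicator) loss records.
#' @param aggregates A tibble, or a named list of tibbles, of aggregate loss
#'   tables (one file per element).
#' @param path Output directory; created if absent.
#' @return Manifest tibble with columns `file`, `rows`, invisibly.
#' @export
write_results <- function(losses, aggregates, path) {
  if (nrow(losses) == 0L) stop("no loss records to write", call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create results directory '", path, "'",
                              call. = FALSE)
  if (is.data.frame(aggregates)) aggregates <- list(aggregate = aggregates)

  files <- character(0)
  rows <- integer(0)
  write_one <- function(tbl, name) {
    fp <- file.path(path, paste0(name, ".csv"))
    write_csv_full(tbl, fp)
    files <<- c(files, fp)
    rows <<- c(rows, nrow(tbl))
  }
  write_one(losses, "loss_records")
  for (nm in names(aggregates)) write_one(aggregates[[nm]], paste0("aggregate_", nm))
  invisible(tibble::tibble(file = files, rows = rows))
}

# full-precision CSV writer: doubles rendered with %.17g round-trip exactly
write_csv_full <- function(tbl, path) {
  out <- tbl
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- formatC(out[[col]], digits = 17, format = "g", flag = "-")
      out[[col]] <- trimws(out[[col]])
    }
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# read every column as character: numeric conversion is done field by field
# through strtod (as.numeric), which is correctly rounded, so full-precision
# files round-trip bit-exactly
read_csv_chr <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

as_num <- function(x) suppressWarnings(as.numeric(x))
as_int <- function(x) suppressWarnings(as.integer(x))

#' Read a results-style CSV at full precision
#'
#' Companion to [write_results()]: columns that are entirely numeric are
#' converted through the C library's correctly rounded parser, so values
#' written at full precision come back bit-identical.
#'
#' @param path CSV file.
#' @return Tibble with numeric/integer columns restored.
#' @export
read_results_csv <- function(path) {
  tbl <- read_csv_chr(path)
  for (col in names(tbl)) {
    v <- tbl[[col]]
    ok <- !is.na(v)
    if (!any(ok)) next
    if (all(grepl("^-?[0-9]+$", v[ok]))) {
      conv <- as_int(v)
      if (!anyNA(conv[ok])) {
        tbl[[col]] <- conv
        next
      }
    }
    conv <- as_num(v)
    if (!anyNA(conv[ok])) tbl[[col]] <- conv
  }
  tbl
}

read_mapped <- function(path, schema, fields, optional = NULL) {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  missing_fields <- setdiff(fields, names(schema))
  if (length(missing_fields)) {
    stop("schema does not map field(s): ", paste(missing_fields, collapse = ", "),
         call. = FALSE)
  }
  raw <- read_csv_chr(path)
  absent <- setdiff(unname(schema[fields]), names(raw))
  if (length(absent)) {
    stop("column(s) ", paste(absent, collapse = ", "), " not found in '", path,
         "' (schema mismatch)", call. = FALSE)
  }
  out <- raw[, unname(schema[fields]), drop = FALSE]
  names(out) <- fields
  if (!is.null(optional)) {
    for (f in names(optional)) {
      if (optional[[f]] %in% names(raw)) out[[f]] <- raw[[optional[[f]]]]
    }
  }
  out
}

assert_unique_keys <- function(tbl, keys) {
  dup <- duplicated(tbl[, keys, drop = FALSE])
  if (any(dup)) {
    first <- tbl[which(dup)[1], keys, drop = FALSE]
    stop("duplicate key (", paste(keys, collapse = ", "), ") = (",
         paste(unlist(first), collapse = ", "), ")", call. = FALSE)
  }
  invisible(tbl)
}
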