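#' Assign World Bank income groups from anchor-year GDP per capita
#'
#' Thresholds follow the printed World Bank brackets: low income up to $1,045,
#' lower-middle up to $4,095, upper-middle up to $12,695, high income above.
#' The one-dollar gaps between the printed bracket edges are closed by using
#' half-open intervals so the classification partitions any positive input.
#'
#' @param gdp_pc_anchor Positive numeric vector, constant-USD GDP per capita
#'   at the anchor year.
#' @return Character vector of group labels (see [income_groups()]).
#' @export
#' @examples
#' assign_income_group(c(1045, 4096, 46449.74))
assign_income_group <- function(gdp_pc_anchor) {
  if (any(!is.finite(gdp_pc_anchor)) || any(gdp_pc_anchor <= 0)) {
    stop("GDP per capita must be strictly positive", call. = FALSE)
  }
  as.character(cut(gdp_pc_anchor,
                   breaks = c(0, 1045, 4095, 12695, Inf),
                   labels = income_groups(), right = TRUE))
}

#' Collapse yearly observations into the log-scale period panel
#'
#' Period windows of `cfg$period_length` years tile forward from
#' `cfg$start_year`; years after `cfg$anchor_year` are excluded from
#' estimation. Within each window the indicator and all three covariates are
#' arithmetically averaged over the years actually available, then
#' log-transformed. Windows with no observed years are absent from the output
#' rather than zero-filled; `n_years_averaged` records how many years entered
#' each period mean (partial trailing windows are kept).
#'
#' @param obs Yearly indicator observations (`country_id`, `year`,
#'   `indicator_id`, `value`), one or several indicators.
#' @param covs Covariate panel (`country_id`, `year`, `gdp_pc`, `gini`,
#'   `health_exp_pct_gdp`).
#' @param cfg A [run_config()].
#' @return Tibble with columns `country_id`, `indicator_id`, `period_index`
#'   (0-based), `ln_sdg`, `ln_gdp_pc`, `ln_gini`, `ln_he`, `n_years_averaged`.
#' @export
build_periods <- function(obs, covs, cfg = run_config()) {
  window_of <- function(y) (y - cfg$start_year) %/% cfg$period_length

  obs <- dplyr::filter(obs, .data$year >= cfg$start_year,
                       .data$year <= cfg$anchor_year)
  covs <- dplyr::filter(covs, .data$year >= cfg$start_year,
                        .data$year <= cfg$anchor_year)
  if (nrow(obs) == 0L) {
    stop("no observations inside the configured estimation window", call. = FALSE)
  }
  if (any(obs$value <= 0)) {
    stop("indicator values must be strictly positive for the log transform",
         call. = FALSE)
  }

  per_obs <- obs |>
    dplyr::mutate(period_index = window_of(.data$year)) |>
    dplyr::group_by(.data$country_id, .data$indicator_id, .data$period_index) |>
    dplyr::summarise(sdg_mean = mean(.data$value),
                     n_years_averaged = dplyr::n(), .groups = "drop")

  per_cov <- covs |>
    dplyr::mutate(period_index = window_of(.data$year)) |>
    dplyr::group_by(.data$country_id, .data$period_index) |>
    dplyr::summarise(gdp_mean = mean(.data$gdp_pc),
                     gini_mean = mean(.data$gini),
                     he_mean = mean(.data$health_exp_pct_gdp),
                     .groups = "drop")

  joined <- dplyr::inner_join(per_obs, per_cov,
                              by = c("country_id", "period_index"))
  lost <- setdiff(unique(per_obs$indicator_id), unique(joined$indicator_id))
  if (length(lost)) {
    stop("indicator(s) with no covariate overlap in any period: ",
         paste(lost, collapse = ", "), call. = FALSE)
  }
  joined |>
    dplyr::transmute(
      country_id = .data$country_id,
      indicator_id = .data$indicator_id,
      period_index = .data$period_index,
      ln_sdg = log(.data$sdg_mean),
      ln_gdp_pc = log(.data$gdp_mean),
      ln_gini = log(.data$gini_mean),
      ln_he = log(.data$he_mean),
      n_years_averaged = .data$n_years_averaged
    )
}

#' Apply the minimum-reporting-coverage filter
#'
#' An (indicator, income group) cell is retained if and only if the fraction
#' of the group's countries with at least one observation of the indicator is
#' at least `cfg$coverage_threshold`. Reports are emitted for every cell,
#' retained or not; empty groups yield `n_in_group = 0` and `retained =
#' FALSE`.
#'
#' @param panel Period panel as returned by [build_periods()].
#' @param groups Tibble `country_id`, `income_group` covering every country in
#'   `panel`.
#' @param cfg A [run_config()].
#' @return List with `panel` (retained rows, gaining an `income_group`
#'   column) and `report` (tibble `indicator_id`, `income_group`,
#'   `n_reporting`, `n_in_group`, `retained`).
#' @export
apply_coverage_filter <- function(panel, groups, cfg = run_config()) {
  unknown <- setdiff(unique(panel$country_id), groups$country_id)
  if (length(unknown)) {
    stop("income group unknown for countries: ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  sizes <- groups |>
    dplyr::count(.data$income_group, name = "n_in_group")
  cells <- tidyr::expand_grid(
    indicator_id = unique(panel$indicator_id),
    income_group = intersect(income_groups(), unique(groups$income_group))
  )
  reporting <- panel |>
    dplyr::distinct(.data$indicator_id, .data$country_id) |>
    dplyr::left_join(groups, by = "country_id") |>
    dplyr::count(.data$indicator_id, .data$income_group, name = "n_reporting")

  report <- cells |>
    dplyr::left_join(sizes, by = "income_group") |>
    dplyr::left_join(reporting, by = c("indicator_id", "income_group")) |>
    dplyr::mutate(
      n_in_group = dplyr::coalesce(.data$n_in_group, 0L),
      n_reporting = dplyr::coalesce(.data$n_reporting, 0L),
      retained = .data$n_in_group > 0L &
        .data$n_reporting / .data$n_in_group >= cfg$coverage_threshold
    )

  kept <- panel |>
    dplyr::left_join(groups, by = "country_id") |>
    dplyr::semi_join(dplyr::filter(report, .data$retained),
                     by = c("indicator_id", "income_group"))
  list(panel = kept, report = report)
}

#' Classify each indicator's panel structure
#'
#' Flags each indicator as `panel` (at least two countries each observed in
#' at least two periods, so unit and time effects are identifiable),
#' `cross_section` (several countries but effectively a single usable
#' period), or `unusable` (fewer than two countries). The flag drives the
#' estimator choice: within estimator for `panel`, single-period OLS for
#' `cross_section`.
#'
#' @param panel Period panel as returned by [build_periods()].
#' @return List with `indicators` (tibble `indicator_id`, `n_countries`,
#'   `n_periods`, `status`) and `countries` (tibble `indicator_id`,
#'   `country_id`, `n_periods`).
#' @export
balance_check <- function(panel) {
  if (nrow(panel) == 0L) stop("empty panel", call. = FALSE)
  per_country <- panel |>
    dplyr::count(.data$indicator_id, .data$country_id, name = "n_periods")
  indicators <- per_country |>
    dplyr::group_by(.data$indicator_id) |>
    dplyr::summarise(
      n_countries = dplyr::n(),
      n_multi = sum(.data$n_periods >= 2L),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      panel |>
        dplyr::group_by(.data$indicator_id) |>
        dplyr::summarise(n_periods = dplyr::n_distinct(.data$period_index),
                         .groups = "drop"),
      by = "indicator_id"
    ) |>
    dplyr::mutate(
      status = dplyr::case_when(
        .data$n_countries < 2L ~ "unusable",
        .data$n_multi >= 2L & .data$n_periods >= 2L ~ "panel",
        TRUE ~ "cross_section"
      )
    ) |>
    dplyr::select("indicator_id", "n_countries", "n_periods", "status")
  list(indicators = indicators, countries = per_country)
}
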