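#' Compound a per-capita GDP path from a growth scenario
#'
#' Starting from the anchor-year GDP level, the path applies every yearly
#' rate the scenario carries from `cfg$anchor_year` through the end of the
#' projection range: `GDP_t = GDP_{t-1} * (1 + g_t)`. The anchor GDP is the
#' start-of-anchor-year level, so the anchor year's own rate is applied —
#' twelve applications for a 2019 anchor and a 2030 horizon, which is the
#' convention that reconciles published decade forecasts with their printed
#' average growth rates.
#'
#' @param anchor_gdp Positive GDP per capita at the anchor year.
#' @param scenario A [growth_scenario()].
#' @param country Country id to look up in the scenario.
#' @param cfg A [run_config()].
#' @return Named numeric vector, one GDP value per year from
#'   `cfg$anchor_year` to `max(cfg$projection_years)`.
#' @export
#' @examples
#' s <- growth_scenario(
#'   tibble::tibble(country_id = "A", year = 2019:2030, rate = 0.052), "pre")
#' build_gdp_path(2060.02, s, "A", run_config())[["2030"]]
build_gdp_path <- function(anchor_gdp, scenario, country, cfg = run_config()) {
  if (!is.finite(anchor_gdp) || anchor_gdp <= 0) {
    stop("anchor GDP must be strictly positive", call. = FALSE)
  }
  years_needed <- seq(cfg$anchor_year, max(cfg$projection_years))
  rates <- scenario[scenario$country_id == country, ]
  missing_years <- setdiff(years_needed, rates$year)
  if (length(missing_years)) {
    stop("growth rates missing for ", country, " in year(s): ",
         paste(missing_years, collapse = ", "), call. = FALSE)
  }
  rates <- rates[match(years_needed, rates$year), ]
  path <- anchor_gdp * cumprod(1 + rates$rate)
  setNames(path, years_needed)
}

#' Extrapolate an indicator along a GDP path
#'
#' Under the log-log model, holding the Gini index, health expenditure,
#' country effects and the last period effect fixed, the projected indicator
#' is the last observed value scaled by the GDP ratio raised to the
#' elasticity: `value_t = last_value * (GDP_t / anchor_gdp)^elasticity`.
#' Every level term cancels in the ratio, so projections depend only on the
#' growth path and the elasticity.
#'
#' @param last_value Last observed indicator value (> 0).
#' @param anchor_gdp GDP per capita at the anchor year (> 0).
#' @param gdp_path Named numeric vector year -> projected GDP per capita.
#' @param elasticity Combined GDP elasticity (see [combined_elasticity()]).
#' @return Named numeric vector year -> projected indicator value.
#' @export
#' @examples
#' project_indicator(100, 100, c(`2030` = 80), elasticity = -0.5)  # 111.80
project_indicator <- function(last_value, anchor_gdp, gdp_path, elasticity) {
  if (!is.finite(last_value) || last_value <= 0) {
    stop("last observed value must be strictly positive", call. = FALSE)
  }
  if (!is.finite(anchor_gdp) || anchor_gdp <= 0) {
    stop("anchor GDP must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(gdp_path)) || any(gdp_path <= 0)) {
    stop("GDP path must be strictly positive", call. = FALSE)
  }
  if (!is.finite(elasticity)) stop("elasticity must be finite", call. = FALSE)
  last_value * (gdp_path / anchor_gdp)^elasticity
}

#' Latest observed value per (country, indicator) at or before the anchor
#'
#' @param obs Yearly observations (`country_id`, `year`, `indicator_id`,
#'   `value`).
#' @param cfg A [run_config()].
#' @return Tibble `country_id`, `indicator_id`, `year`, `value`.
#' @export
latest_values <- function(obs, cfg = run_config()) {
  obs |>
    dplyr::filter(.data$year <= cfg$anchor_year) |>
    dplyr::group_by(.data$country_id, .data$indicator_id) |>
    dplyr::slice_max(.data$year, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("country_id", "indicator_id", "year", "value")
}

#' Project every (country, indicator) under both growth scenarios
#'
#' Each country's elasticity is drawn from its income group's fit (default)
#' or the global fit, combined with its region's interaction term where
#' estimated. Countries lacking a usable fit, a last observed value, or
#' scenario coverage are skipped with a logged reason (attribute
#' `"skipped"`), never silently.
#'
#' @param fits Result of [fit_all()].
#' @param countries Country table (`country_id`, `region`, `income_group`,
#'   `gdp_pc_anchor`).
#' @param scenarios List with [growth_scenario()] elements `pre` and `post`.
#' @param last_values Tibble from [latest_values()].
#' @param cfg A [run_config()].
#' @return Long tibble `country_id`, `indicator_id`, `scenario_id`, `year`,
#'   `gdp_pc`, `value`, restricted to `cfg$projection_years`; the
#'   `"skipped"` attribute lists (country, indicator, reason) rows, and
#'   `"elasticities"` records the elasticity used per (country, indicator).
#' @export
project_all <- function(fits, countries, scenarios, last_values,
                        cfg = run_config()) {
  stopifnot(all(c("pre", "post") %in% names(scenarios)))
  ok_fits <- fits[fits$status == "ok", ]
  fit_key <- paste(ok_fits$indicator_id, ok_fits$subsample, sep = "\r")
  proj_years <- as.character(cfg$projection_years)

  work <- dplyr::inner_join(last_values, countries, by = "country_id")
  out <- vector("list", nrow(work))
  skipped <- list()
  elast_log <- list()

  for (i in seq_len(nrow(work))) {
    row <- work[i, ]
    target <- if (cfg$subsample_mode == "by_income_group") row$income_group else "global"
    idx <- match(paste(row$indicator_id, target, sep = "\r"), fit_key)
    if (is.na(idx)) {
      skipped[[length(skipped) + 1L]] <- tibble::tibble(
        country_id = row$country_id, indicator_id = row$indicator_id,
        reason = paste0("no usable fit for subsample '", target, "'"))
      next
    }
    fit <- ok_fits$fit[[idx]]
    elast <- combined_elasticity(fit, row$region)
    if (!is.finite(elast)) {
      skipped[[length(skipped) + 1L]] <- tibble::tibble(
        country_id = row$country_id, indicator_id = row$indicator_id,
        reason = "GDP elasticity not estimable")
      next
    }
    paths <- tryCatch(
      lapply(scenarios[c("pre", "post")], function(s) {
        build_gdp_path(row$gdp_pc_anchor, s, row$country_id, cfg)
      }),
      error = function(e) conditionMessage(e)
    )
    if (is.character(paths)) {
      skipped[[length(skipped) + 1L]] <- tibble::tibble(
        country_id = row$country_id, indicator_id = row$indicator_id,
        reason = paths)
      next
    }
    elast_log[[length(elast_log) + 1L]] <- tibble::tibble(
      country_id = row$country_id, indicator_id = row$indicator_id,
      subsample = target, elasticity = elast)
    out[[i]] <- dplyr::bind_rows(lapply(names(paths), function(which) {
      gp <- paths[[which]][proj_years]
      vals <- project_indicator(row$value, row$gdp_pc_anchor, gp, elast)
      tibble::tibble(
        country_id = row$country_id,
        indicator_id = row$indicator_id,
        scenario_id = attr(scenarios[[which]], "scenario_id"),
        year = cfg$projection_years,
        gdp_pc = unname(gp),
        value = unname(vals)
      )
    }))
  }

  res <- dplyr::bind_rows(out)
  attr(res, "skipped") <- dplyr::bind_rows(skipped)
  attr(res, "elasticities") <- dplyr::bind_rows(elast_log)
  res
}
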