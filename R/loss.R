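#' Potential-progress loss per (country, indicator)
#'
#' The loss compares the projected indicator at the final projection year
#' under the revised (post-shock) scenario with the baseline (pre-shock)
#' scenario: `raw_diff = post - pre` in indicator-native units, and
#' `relative_loss = 100 * direction_sign * raw_diff / denominator`, where
#' `direction_sign` is +1 for indicators where higher is better and -1 where
#' lower is better, so a negative relative loss always means foregone
#' progress. The denominator is the baseline 2030 forecast
#' (`loss_denominator = "baseline_2030"`, default) or the last observed
#' value (`"anchor_value"`).
#'
#' @param projections Long projection tibble from [project_all()], carrying
#'   both scenarios on a shared year grid.
#' @param meta Indicator metadata from [read_indicator_meta()].
#' @param cfg A [run_config()].
#' @param anchor_values Tibble `country_id`, `indicator_id`, `value`
#'   (required when `cfg$loss_denominator = "anchor_value"`).
#' @param pre_id,post_id Scenario labels in `projections`. Defaults
#'   `"pre_covid"` / `"post_covid"`.
#' @return Tibble `country_id`, `indicator_id`, `raw_diff`, `relative_loss`
#'   (percent), `denominator_used`.
#' @export
compute_loss <- function(projections, meta, cfg = run_config(),
                         anchor_values = NULL,
                         pre_id = "pre_covid", post_id = "post_covid") {
  final_year <- max(cfg$projection_years)
  fin <- projections[projections$year == final_year, ]
  wide <- tidyr::pivot_wider(
    fin[, c("country_id", "indicator_id", "scenario_id", "value")],
    names_from = "scenario_id", values_from = "value"
  )
  if (!all(c(pre_id, post_id) %in% names(wide))) {
    stop("projections must carry scenarios '", pre_id, "' and '", post_id, "'",
         call. = FALSE)
  }
  if (anyNA(wide[[pre_id]]) || anyNA(wide[[post_id]])) {
    stop("pre and post projections do not share the same (country, indicator)",
         " pairs", call. = FALSE)
  }
  unknown <- setdiff(unique(wide$indicator_id), meta$indicator_id)
  if (length(unknown)) {
    stop("no metadata for indicator(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  wide <- dplyr::left_join(wide, meta[, c("indicator_id", "direction")],
                           by = "indicator_id")
  wide$raw_diff <- wide[[post_id]] - wide[[pre_id]]
  sign_dir <- ifelse(wide$direction == "higher_is_better", 1, -1)

  if (cfg$loss_denominator == "baseline_2030") {
    denom <- wide[[pre_id]]
  } else {
    if (is.null(anchor_values)) {
      stop("anchor_values required for loss_denominator = 'anchor_value'",
           call. = FALSE)
    }
    wide <- dplyr::left_join(
      wide, dplyr::rename(anchor_values[, c("country_id", "indicator_id", "value")],
                          anchor_value = "value"),
      by = c("country_id", "indicator_id"))
    if (anyNA(wide$anchor_value)) {
      stop("anchor values missing for some (country, indicator) pairs",
           call. = FALSE)
    }
    denom <- wide$anchor_value
  }
  tibble::tibble(
    country_id = wide$country_id,
    indicator_id = wide$indicator_id,
    raw_diff = wide$raw_diff,
    relative_loss = 100 * sign_dir * wide$raw_diff / denom,
    denominator_used = cfg$loss_denominator
  )
}

#' GDP loss as a proportion of initial GDP per capita
#'
#' `100 * (post_2030 - pre_2030) / anchor_gdp`: how much of the anchor-year
#' income level the downward forecast revision amounts to by the horizon.
#'
#' @param anchor_gdp GDP per capita at the anchor year (> 0).
#' @param pre_2030 Baseline-scenario GDP forecast at the horizon (> 0).
#' @param post_2030 Revised-scenario GDP forecast at the horizon (> 0).
#' @return Percent change (negative = loss). Vectorised.
#' @export
#' @examples
#' gdp_loss_proportion(2060.02, 3800.46, 2931.23)  # about -42%
gdp_loss_proportion <- function(anchor_gdp, pre_2030, post_2030) {
  if (any(!is.finite(anchor_gdp)) || any(anchor_gdp <= 0) ||
      any(!is.finite(pre_2030)) || any(pre_2030 <= 0) ||
      any(!is.finite(post_2030)) || any(post_2030 <= 0)) {
    stop("all GDP inputs must be strictly positive", call. = FALSE)
  }
  100 * (post_2030 - pre_2030) / anchor_gdp
}

#' Aggregate loss records to themes, groups, indicators or countries
#'
#' Every cell is the single-stage unweighted arithmetic mean of all
#' (country, indicator) loss records falling in it; `n_contributing` counts
#' them, so counts across an axis always sum to the number of input records.
#'
#' @param losses Loss records from [compute_loss()].
#' @param meta Indicator metadata (for themes).
#' @param groups Tibble `country_id`, `income_group`.
#' @param axis One of `"theme_income_group"`, `"indicator_income_group"`,
#'   `"country"`, `"income_group"`.
#' @return Tibble with the axis key columns, `mean_loss` (percent) and
#'   `n_contributing`.
#' @export
aggregate_losses <- function(losses, meta, groups,
                             axis = c("theme_income_group",
                                      "indicator_income_group",
                                      "country", "income_group")) {
  axis <- match.arg(axis)
  unknown <- setdiff(unique(losses$indicator_id), meta$indicator_id)
  if (length(unknown)) {
    stop("no metadata for indicator(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  d <- losses |>
    dplyr::left_join(meta[, c("indicator_id", "theme")], by = "indicator_id") |>
    dplyr::left_join(groups, by = "country_id")
  if (axis != "country" && anyNA(d$income_group)) {
    stop("income group unknown for some loss records", call. = FALSE)
  }
  keys <- switch(axis,
    theme_income_group = c("theme", "income_group"),
    indicator_income_group = c("indicator_id", "income_group"),
    country = "country_id",
    income_group = "income_group"
  )
  d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(mean_loss = mean(.data$relative_loss),
                     n_contributing = dplyr::n(), .groups = "drop")
}

#' Ratio of mean losses between two income groups
#'
#' Magnitude ratio `|mean_a| / |mean_b|` over the all-indicator average of
#' each group — the headline disparity statistic (e.g. how many times larger
#' the average loss of low-income countries is than that of high-income
#' countries).
#'
#' @param table Aggregate table from
#'   `aggregate_losses(..., axis = "income_group")` (columns `income_group`,
#'   `mean_loss`).
#' @param group_a,group_b Income-group labels; `group_b` is the denominator.
#' @return A single non-negative number.
#' @export
disparity_ratio <- function(table, group_a, group_b) {
  pick <- function(g) {
    v <- table$mean_loss[table$income_group == g]
    if (length(v) != 1L) stop("group '", g, "' not present exactly once",
                              call. = FALSE)
    v
  }
  a <- pick(group_a)
  b <- pick(group_b)
  if (b == 0) stop("undefined ratio: mean loss of '", group_b, "' is zero",
                   call. = FALSE)
  abs(a) / abs(b)
}
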