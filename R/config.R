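#' Recognised region codes
#'
#' The six WHO regions plus China and India, which are carried as separate
#' levels because of their population size. `AFR` is the baseline level for
#' the region-by-GDP interaction terms.
#'
#' @return Character vector of the eight region codes.
#' @export
region_codes <- function() {
  c("AFR", "AMR", "SEAR", "EUR", "EMR", "WPR", "CHN", "IND")
}

#' Baseline region for GDP-elasticity interactions
#' @return `"AFR"`.
#' @export
baseline_region <- function() "AFR"

#' World Bank income-group labels, poorest first
#' @return Character vector of the four group labels.
#' @export
income_groups <- function() {
  c("low", "lower_middle", "upper_middle", "high")
}

#' The seven health themes
#'
#' Theme labels used to aggregate indicator-level losses.
#'
#' @return Character vector of length 7.
#' @export
health_themes <- function() {
  c(
    "Maternal and reproductive health",
    "Infant and neonatal health",
    "Infectious diseases",
    "Non-communicable diseases",
    "Violence and injuries",
    "Environmental risks",
    "Health systems and coverage"
  )
}

#' Pipeline run configuration
#'
#' Bundles every tunable the pipeline consumes: the period-averaging window,
#' the anchor (last pre-pandemic) year, the projection horizon, the
#' reporting-coverage threshold, how elasticities are looked up when
#' projecting, and which denominator the relative loss uses.
#'
#' @param period_length Years averaged into one panel period. Default 5.
#' @param start_year First year of the historical estimation window; period
#'   windows tile forward from here in fixed blocks.
#' @param anchor_year Last observed (pre-shock) year; income classification
#'   and projection baselines are taken here. Default 2019.
#' @param projection_years Inclusive range of years to project. Default
#'   2021:2030.
#' @param coverage_threshold Minimum fraction of an income group's countries
#'   that must report an indicator for the (indicator, group) cell to be
#'   retained. Default 0.40.
#' @param subsample_mode `"by_income_group"` (default) draws each country's
#'   elasticity from its income-group fit; `"global"` uses the pooled fit.
#' @param loss_denominator `"baseline_2030"` (default) expresses the loss
#'   relative to the pre-shock 2030 forecast; `"anchor_value"` relative to the
#'   last observed value.
#' @param cluster_se Use country-clustered standard errors instead of the
#'   conventional homoskedastic within-estimator ones. Default `FALSE`.
#' @param seed Integer seed recorded with the run.
#'
#' @return A list of class `preston_config`.
#' @export
run_config <- function(period_length = 5L,
                       start_year = 2000L,
                       anchor_year = 2019L,
                       projection_years = 2021:2030,
                       coverage_threshold = 0.40,
                       subsample_mode = c("by_income_group", "global"),
                       loss_denominator = c("baseline_2030", "anchor_value"),
                       cluster_se = FALSE,
                       seed = 1L) {
  subsample_mode <- match.arg(subsample_mode)
  loss_denominator <- match.arg(loss_denominator)
  if (length(projection_years) < 1L) {
    stop("`projection_years` must be a non-empty range", call. = FALSE)
  }
  if (period_length < 1L) stop("`period_length` must be >= 1", call. = FALSE)
  if (coverage_threshold < 0 || coverage_threshold > 1) {
    stop("`coverage_threshold` must lie in [0, 1]", call. = FALSE)
  }
  if (anchor_year < start_year) {
    stop("`anchor_year` must not precede `start_year`", call. = FALSE)
  }
  structure(
    list(
      period_length = as.integer(period_length),
      start_year = as.integer(start_year),
      anchor_year = as.integer(anchor_year),
      projection_years = as.integer(projection_years),
      coverage_threshold = coverage_threshold,
      subsample_mode = subsample_mode,
      loss_denominator = loss_denominator,
      cluster_se = isTRUE(cluster_se),
      seed = as.integer(seed)
    ),
    class = "preston_config"
  )
}

#' @export
print.preston_config <- function(x, ...) {
  cat("<preston_config>\n")
  cat(sprintf("  periods: %d-year windows from %d, anchor %d\n",
              x$period_length, x$start_year, x$anchor_year))
  cat(sprintf("  projection: %d-%d\n",
              min(x$projection_years), max(x$projection_years)))
  cat(sprintf("  coverage threshold: %.2f | subsample: %s | denominator: %s\n",
              x$coverage_threshold, x$subsample_mode, x$loss_denominator))
  invisible(x)
}
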