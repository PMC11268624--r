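# shared fixtures and the LSDV oracle used against the within estimator

small_world <- function(seed = 1, n = 40, ...) {
  gen_world(generator_spec(n_countries = n, seed = seed, ...))
}

# a world where every country sits in the baseline region: no interaction
# columns, so single-elasticity designs are isolated
afr_only_weights <- function() {
  stats::setNames(c(1, rep(0, 7)), region_codes())
}

# explicit-dummy least squares: the independent oracle for fit_panel_fe
lsdv_fit <- function(dm) {
  df <- data.frame(y = dm$response, dm$X, check.names = FALSE)
  df$country <- factor(dm$row_keys$country_id)
  fml <- stats::reformulate(c("0", "country", colnames(dm$X)), response = "y")
  stats::lm(fml, data = df)
}

# random unbalanced panel with random region assignment, guaranteed to keep
# enough multi-period countries for fixed-effects estimation
random_fe_panel <- function(seed) {
  set.seed(seed)
  n_c <- sample(5:20, 1)
  n_p <- sample(3:5, 1)
  countries <- sprintf("U%02d", seq_len(n_c))
  regions <- tibble::tibble(
    country_id = countries,
    region = sample(region_codes(), n_c, replace = TRUE)
  )
  grid <- expand.grid(country_id = countries, period_index = 0:(n_p - 1L),
                      stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(grid)) > 0.15
  keep[grid$country_id %in% countries[1:3]] <- TRUE
  g <- grid[keep, ]
  panel <- tibble::tibble(
    country_id = g$country_id,
    indicator_id = "x",
    period_index = g$period_index,
    ln_sdg = stats::rnorm(nrow(g)),
    ln_gdp_pc = stats::rnorm(nrow(g)),
    ln_gini = stats::rnorm(nrow(g)),
    ln_he = stats::rnorm(nrow(g)),
    n_years_averaged = 1L
  )
  list(panel = panel, regions = regions)
}

# constant covariates over a year span, for hand-computed period means
flat_covariates <- function(countries, years, gdp = 1000, gini = 40, he = 6) {
  tidyr::expand_grid(country_id = countries, year = years) |>
    dplyr::mutate(gdp_pc = gdp, gini = gini, health_exp_pct_gdp = he)
}

run_pipeline <- function(world, cfg) {
  pp <- build_periods(world$panel, world$covariates, cfg)
  flt <- apply_coverage_filter(pp, world$countries[, c("country_id", "income_group")],
                               cfg)
  fits <- fit_all(flt$panel, world$countries, cfg)
  lv <- latest_values(world$panel, cfg)
  proj <- project_all(fits, world$countries, world$scenarios, lv, cfg)
  losses <- compute_loss(proj, world$meta, cfg)
  list(periods = pp, filtered = flt, fits = fits, projections = proj,
       losses = losses)
}
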