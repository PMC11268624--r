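test_that("design matrix follows the baseline-region and dummy-coding rules", {
  base <- tibble::tibble(ln_sdg = rnorm(12), ln_gdp_pc = rnorm(12),
                         ln_gini = rnorm(12), ln_he = rnorm(12),
                         n_years_averaged = 1L)
  panel <- tidyr::expand_grid(country_id = c("A", "B", "C"),
                              indicator_id = "x", period_index = 0:3) |>
    dplyr::bind_cols(base)

  # two regions with AFR baseline: exactly one interaction column
  regions2 <- tibble::tibble(country_id = c("A", "B", "C"),
                             region = c("AFR", "AMR", "AFR"))
  dm <- build_design(panel, regions2, time_fe = FALSE)
  expect_setequal(colnames(dm$X), c("ln_gdp_pc", "ln_gini", "ln_he", "gdp_x_AMR"))
  amr_rows <- dm$row_keys$country_id == "B"
  expect_equal(dm$X[amr_rows, "gdp_x_AMR"], dm$X[amr_rows, "ln_gdp_pc"])
  expect_true(all(dm$X[!amr_rows, "gdp_x_AMR"] == 0))

  # 4 periods with time FE: 3 period dummies, first period absorbed
  dm_t <- build_design(panel, regions2, time_fe = TRUE)
  expect_equal(sum(grepl("^period_", colnames(dm_t$X))), 3L)
  expect_false("period_0" %in% colnames(dm_t$X))

  expect_error(build_design(panel[panel$country_id == "A", ], regions2),
               "at least 2")
})

test_that("a single-region subsample drops its interaction, keeping ln GDPpc", {
  set.seed(3)
  base <- tibble::tibble(ln_sdg = rnorm(12), ln_gdp_pc = rnorm(12),
                         ln_gini = rnorm(12), ln_he = rnorm(12),
                         n_years_averaged = 1L)
  panel <- tidyr::expand_grid(country_id = c("A", "B", "C"),
                              indicator_id = "x", period_index = 0:3) |>
    dplyr::bind_cols(base)
  regions <- tibble::tibble(country_id = c("A", "B", "C"), region = "EUR")
  dm <- build_design(panel, regions, time_fe = TRUE)
  fit <- fit_panel_fe(dm)
  expect_true("gdp_x_EUR" %in% fit$dropped_terms)
  expect_true(is.finite(fit$beta_gdp))
  # elasticity composition treats the dropped interaction as zero
  expect_equal(combined_elasticity(fit, "EUR"), fit$beta_gdp)
})

test_that("noiseless synthetic panels are recovered to machine precision", {
  cfg <- run_config(subsample_mode = "global")
  world <- small_world(seed = 3, n = 60, sigma_country = 0,
                       sigma_period = 0, sigma_eps = 0)
  pp <- build_periods(world$panel, world$covariates, cfg)
  regions <- world$countries[, c("country_id", "region")]
  truth <- world$truth$params
  for (ind in names(truth)) {
    dm <- build_design(pp[pp$indicator_id == ind, ], regions)
    fit <- fit_panel_fe(dm)
    expect_equal(fit$beta_gdp, truth[[ind]]$beta_gdp, tolerance = 1e-10)
    expect_equal(fit$beta_gini, truth[[ind]]$beta_gini, tolerance = 1e-10)
    expect_equal(fit$beta_he, truth[[ind]]$beta_he, tolerance = 1e-10)
    expect_equal(fit$beta_region[names(fit$beta_region)],
                 truth[[ind]]$beta_region[names(fit$beta_region)],
                 tolerance = 1e-10)
  }
})

test_that("the within estimator equals explicit-dummy least squares", {
  for (seed in 1:12) {
    rp <- random_fe_panel(seed)
    dm <- build_design(rp$panel, rp$regions, time_fe = TRUE)
    fit <- fit_panel_fe(dm)
    oracle <- lsdv_fit(dm)
    terms <- names(fit$coefficients)
    expect_equal(unname(fit$coefficients[terms]), unname(coef(oracle)[terms]),
                 tolerance = 1e-8)
    # country intercepts of LSDV = alpha + f_i
    dum <- coef(oracle)[paste0("country", names(fit$country_effects))]
    expect_equal(unname(fit$alpha + fit$country_effects), unname(dum),
                 tolerance = 1e-8)
    # residuals carry no mean by construction
    expect_lt(abs(mean(fit$residuals)), 1e-10)
  }
})

test_that("FE slopes are invariant to translating ln GDPpc", {
  world <- small_world(seed = 8, n = 30)
  cfg <- run_config()
  pp <- build_periods(world$panel, world$covariates, cfg)
  pp <- pp[pp$indicator_id == "synthA", ]
  regions <- world$countries[, c("country_id", "region")]
  f0 <- fit_panel_fe(build_design(pp, regions))
  pp_shift <- dplyr::mutate(pp, ln_gdp_pc = ln_gdp_pc + 3)
  f1 <- fit_panel_fe(build_design(pp_shift, regions))
  expect_equal(f1$beta_gdp, f0$beta_gdp, tolerance = 1e-10)
  expect_equal(f1$beta_gini, f0$beta_gini, tolerance = 1e-10)
  expect_equal(f1$beta_region, f0$beta_region, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(f1$alpha, f0$alpha)))
})

test_that("r-squared trio lies in [0, 1] across random panels", {
  for (seed in 21:26) {
    rp <- random_fe_panel(seed)
    fit <- fit_panel_fe(build_design(rp$panel, rp$regions))
    expect_true(all(c(fit$r2_within, fit$r2_between, fit$r2_overall) >= 0))
    expect_true(all(c(fit$r2_within, fit$r2_between, fit$r2_overall) <= 1))
  }
})

test_that("cross-section OLS fits single-period data and reports r2_overall only", {
  # a response exactly linear in ln GDPpc is fit perfectly
  set.seed(11)
  panel <- tibble::tibble(
    country_id = sprintf("C%02d", 1:20), indicator_id = "x",
    period_index = 3L, ln_gdp_pc = rnorm(20), ln_gini = rnorm(20),
    ln_he = rnorm(20), n_years_averaged = 1L) |>
    dplyr::mutate(ln_sdg = 2 - 0.7 * ln_gdp_pc)
  regions <- tibble::tibble(country_id = sprintf("C%02d", 1:20), region = "AFR")
  fit <- fit_cross_section_ols(build_design(panel, regions, time_fe = FALSE))
  expect_equal(fit$estimator_kind, "cross_section_ols")
  expect_equal(fit$beta_gdp, -0.7, tolerance = 1e-10)
  expect_equal(fit$alpha, 2, tolerance = 1e-10)
  expect_equal(fit$r2_overall, 1, tolerance = 1e-10)
  expect_true(is.na(fit$r2_within) && is.na(fit$r2_between))
  expect_length(fit$country_effects, 0)

  # multiple periods are refused; too few countries are an estimability error
  panel2 <- dplyr::mutate(panel, period_index = rep(0:1, 10))
  expect_error(fit_cross_section_ols(build_design(panel2, regions, FALSE)),
               "single period")
  expect_error(fit_cross_section_ols(build_design(panel[1:4, ], regions, FALSE)),
               "[Uu]nderdetermined")
})

test_that("cross-section estimates sit within two standard errors of truth", {
  cfg <- run_config(subsample_mode = "global")
  hits <- vapply(1:100, function(s) {
    world <- gen_world(generator_spec(
      n_countries = 60, region_weights = afr_only_weights(),
      true_params = default_true_params()["synthA"], seed = 300 + s))
    pp <- build_periods(world$panel, world$covariates, cfg)
    last_p <- max(pp$period_index)
    dm <- build_design(pp[pp$period_index == last_p, ],
                       world$countries[, c("country_id", "region")],
                       time_fe = FALSE)
    fit <- fit_cross_section_ols(dm)
    abs(fit$beta_gdp - (-0.5)) <= 2 * fit$se[["ln_gdp_pc"]]
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("a single-round indicator is routed to cross-section by fit_all", {
  world <- small_world(seed = 13, n = 50)
  cfg <- run_config()
  pp <- build_periods(world$panel, world$covariates, cfg)
  # keep only the final period for synthA: a one-round survey
  pp_one <- dplyr::bind_rows(
    pp[pp$indicator_id != "synthA", ],
    pp[pp$indicator_id == "synthA" & pp$period_index == 3L, ]
  )
  fits <- fit_all(pp_one, world$countries, cfg)
  got <- fits[fits$indicator_id == "synthA" & fits$subsample == "global", ]
  expect_equal(got$estimator, "cross_section_ols")
  expect_equal(got$status, "ok")
})

test_that("combined elasticity adds the regional interaction to the GDP term", {
  fit <- fit_result(beta_gdp = -0.4910,
                    beta_region = c(AMR = -0.1205, EUR = -0.2587))
  expect_equal(combined_elasticity(fit, "EUR"), -0.7497)
  expect_equal(combined_elasticity(fit, "AMR"), -0.6115)
  # baseline and absent regions pass the main elasticity through
  expect_equal(combined_elasticity(fit, "AFR"), -0.4910)
  expect_equal(combined_elasticity(fit, "SEAR"), -0.4910)
  expect_error(combined_elasticity(fit, "XYZ"), "unknown region")
})

test_that("fit_all produces one fit per retained cell plus the global fit", {
  world <- gen_world(generator_spec(
    n_countries = 80, true_params = default_true_params()[1:3], seed = 17))
  cfg <- run_config()
  pp <- build_periods(world$panel, world$covariates, cfg)
  groups <- world$countries[, c("country_id", "income_group")]
  flt <- apply_coverage_filter(pp, groups, cfg)
  fits <- fit_all(flt$panel, world$countries, cfg)
  expect_equal(nrow(fits), 15L)  # 3 global + 3 x 4 groups
  expect_true(all(fits$status == "ok"))

  # empty one (indicator, group) cell: it is dismissed by the coverage filter
  # and fit_all sees one cell fewer
  low_ids <- groups$country_id[groups$income_group == "low"]
  pp_holed <- pp[!(pp$indicator_id == "synthA" & pp$country_id %in% low_ids), ]
  flt2 <- apply_coverage_filter(pp_holed, groups, cfg)
  dismissed <- flt2$report[!flt2$report$retained, ]
  expect_equal(nrow(dismissed), 1L)
  expect_equal(dismissed$indicator_id, "synthA")
  expect_equal(dismissed$income_group, "low")
  fits2 <- fit_all(flt2$panel, world$countries, cfg)
  expect_equal(nrow(fits2), 14L)
})

test_that("income groups simulated with different elasticities are ranked correctly", {
  truth <- c(low = -0.8, lower_middle = -0.6, upper_middle = -0.4, high = -0.2)
  world <- gen_world(generator_spec(
    n_countries = 160,
    income_mix = c(low = 0.25, lower_middle = 0.25, upper_middle = 0.25,
                   high = 0.25),
    region_weights = afr_only_weights(),
    true_params = default_true_params()["synthA"],
    group_elasticity = list(synthA = truth),
    sigma_eps = 0.05, seed = 29))
  cfg <- run_config()
  pp <- build_periods(world$panel, world$covariates, cfg)
  flt <- apply_coverage_filter(pp, world$countries[, c("country_id", "income_group")],
                               cfg)
  fits <- fit_all(flt$panel, world$countries, cfg)
  est <- vapply(names(truth), function(g) {
    fits$fit[[which(fits$subsample == g)]]$beta_gdp
  }, 0)
  expect_equal(names(sort(est)), names(sort(truth)))
  expect_equal(unname(est), unname(truth), tolerance = 0.3)
})

test_that("tidy coefficient tables carry estimates, SEs and dropped terms", {
  world <- small_world(seed = 31, n = 30)
  cfg <- run_config(subsample_mode = "global")
  pp <- build_periods(world$panel, world$covariates, cfg)
  fits <- fit_all(pp, world$countries, cfg)
  tt <- tidy_fits(fits)
  expect_true(all(c("indicator_id", "subsample", "term", "estimate", "se")
                  %in% names(tt)))
  expect_true("(Constant)" %in% tt$term)
  expect_true(all(is.finite(tt$se[!is.na(tt$se)])))
})
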