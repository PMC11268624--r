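proj_pair <- function(pre_2030, post_2030, country = "A", indicator = "x",
                      year = 2030L) {
  tibble::tibble(
    country_id = country, indicator_id = indicator,
    scenario_id = rep(c("pre_covid", "post_covid"), each = length(pre_2030)),
    year = year, gdp_pc = NA_real_,
    value = c(pre_2030, post_2030)
  )
}

meta_for <- function(indicator = "x", direction = "lower_is_better",
                     theme = health_themes()[1]) {
  tibble::tibble(indicator_id = indicator, theme = theme,
                 direction = direction, label = "t")
}

test_that("loss is the direction-signed relative forecast difference at 2030", {
  cfg <- run_config()
  # identical paths: exactly zero
  z <- compute_loss(proj_pair(10, 10), meta_for(), cfg)
  expect_identical(z$relative_loss, 0)
  expect_identical(z$raw_diff, 0)

  # lower-is-better indicator under the published GDP revision: the
  # post/pre GDP ratio at 2030 is 2931.23/3800.46 and elasticity -0.5
  # inflates the indicator by that ratio^-0.5
  ratio <- 2931.23 / 3800.46
  pre <- 50
  post <- pre * ratio^-0.5
  ls <- compute_loss(proj_pair(pre, post), meta_for(), cfg)
  expect_equal(ls$relative_loss, -100 * (ratio^-0.5 - 1))
  expect_equal(ls$relative_loss, -13.87, tolerance = 0.001)

  # higher-is-better indicator whose post path exceeds pre: a gain
  g <- compute_loss(proj_pair(40, 41.412), meta_for(direction = "higher_is_better"),
                    cfg)
  expect_equal(g$relative_loss, 100 * 1.412 / 40)
  expect_gt(g$relative_loss, 0)
})

test_that("anchor-value denominator mode divides by the last observed value", {
  cfg <- run_config(loss_denominator = "anchor_value")
  anchors <- tibble::tibble(country_id = "A", indicator_id = "x", value = 25)
  ls <- compute_loss(proj_pair(50, 55), meta_for(), cfg, anchor_values = anchors)
  expect_equal(ls$relative_loss, -100 * 5 / 25)
  expect_error(compute_loss(proj_pair(50, 55), meta_for(), cfg), "anchor_values")
})

test_that("mismatched scenario pairs and unknown indicators are refused", {
  cfg <- run_config()
  p <- proj_pair(10, 12)
  expect_error(compute_loss(p, meta_for(indicator = "other"), cfg),
               "no metadata")
  p_half <- p[p$scenario_id == "pre_covid", ]
  expect_error(compute_loss(p_half, meta_for(), cfg), "scenario")
})

test_that("GDP-loss proportion reproduces the published income-group row", {
  expect_equal(round(gdp_loss_proportion(2060.02, 3800.46, 2931.23)), -42)
  expect_equal(round(gdp_loss_proportion(6952.56, 11519.97, 9579.79)), -28)
  expect_equal(round(gdp_loss_proportion(16489.29, 23844.50, 21315.85)), -15)
  expect_equal(round(gdp_loss_proportion(46449.74, 58733.41, 55512.59)), -7)
  expect_equal(gdp_loss_proportion(100, 120, 120), 0)
  expect_error(gdp_loss_proportion(0, 1, 1), "positive")
})

test_that("aggregation takes unweighted cell means and conserves record counts", {
  losses <- tibble::tibble(
    country_id = c("A", "B", "A", "B"),
    indicator_id = c("x", "x", "y", "y"),
    raw_diff = 0,
    relative_loss = c(-10, -20, -30, -50),
    denominator_used = "baseline_2030"
  )
  meta <- dplyr::bind_rows(meta_for("x"), meta_for("y", theme = health_themes()[2]))
  groups <- tibble::tibble(country_id = c("A", "B"),
                           income_group = c("low", "high"))

  by_cell <- aggregate_losses(losses, meta, groups, axis = "theme_income_group")
  expect_equal(
    by_cell$mean_loss[by_cell$theme == health_themes()[1] &
                        by_cell$income_group == "low"], -10)
  expect_equal(sum(by_cell$n_contributing), nrow(losses))

  by_country <- aggregate_losses(losses, meta, groups, axis = "country")
  expect_equal(by_country$mean_loss[by_country$country_id == "A"], -20)
  expect_equal(by_country$mean_loss[by_country$country_id == "B"], -35)

  by_group <- aggregate_losses(losses, meta, groups, axis = "income_group")
  expect_equal(by_group$mean_loss[by_group$income_group == "low"], -20)

  # permutation invariance
  perm <- losses[sample(nrow(losses)), ]
  expect_equal(aggregate_losses(perm, meta, groups, axis = "theme_income_group") |>
                 dplyr::arrange(theme, income_group),
               by_cell |> dplyr::arrange(theme, income_group))
})

test_that("a fully populated world yields the 4 x 7 theme-by-group table shape", {
  losses <- tidyr::expand_grid(country_id = sprintf("C%02d", 1:8),
                               indicator_id = as.character(1:7)) |>
    dplyr::mutate(raw_diff = 0, relative_loss = -5,
                  denominator_used = "baseline_2030")
  meta <- tibble::tibble(indicator_id = as.character(1:7),
                         theme = health_themes(),
                         direction = "lower_is_better", label = "t")
  groups <- tibble::tibble(country_id = sprintf("C%02d", 1:8),
                           income_group = rep(income_groups(), each = 2))
  tab <- aggregate_losses(losses, meta, groups, axis = "theme_income_group")
  expect_equal(nrow(tab), 28L)
  expect_true(all(tab$n_contributing == 2L))
})

test_that("disparity ratio is the magnitude ratio of group means", {
  tab <- tibble::tibble(income_group = c("low", "high"),
                        mean_loss = c(-16.48, -2.9))
  expect_equal(disparity_ratio(tab, "low", "high"), 16.48 / 2.9)
  expect_gte(disparity_ratio(tab, "low", "high"), 5.5)
  expect_equal(disparity_ratio(tab, "high", "high"), 1)
  zero <- tibble::tibble(income_group = c("low", "high"), mean_loss = c(-1, 0))
  expect_error(disparity_ratio(zero, "low", "high"), "undefined ratio")
  expect_error(disparity_ratio(tab, "low", "upper_middle"), "not present")
})

test_that("flipping direction metadata flips loss signs, preserving magnitudes", {
  world <- small_world(seed = 37, n = 30)
  cfg <- run_config(subsample_mode = "global")
  pipe <- run_pipeline(world, cfg)
  flipped_meta <- dplyr::mutate(world$meta, direction = ifelse(
    direction == "lower_is_better", "higher_is_better", "lower_is_better"))
  flipped <- compute_loss(pipe$projections, flipped_meta, cfg)
  merged <- dplyr::inner_join(pipe$losses, flipped,
                              by = c("country_id", "indicator_id"),
                              suffix = c("", "_flip"))
  expect_equal(merged$relative_loss_flip, -merged$relative_loss)
  expect_equal(abs(merged$relative_loss_flip), abs(merged$relative_loss))
})

test_that("the richer simulated growth shock hits poorer groups harder", {
  ratios <- vapply(1:10, function(s) {
    world <- gen_world(generator_spec(
      n_countries = 80, region_weights = afr_only_weights(),
      true_params = default_true_params()["synthA"],
      group_elasticity = list(synthA = c(low = -0.8, lower_middle = -0.6,
                                         upper_middle = -0.4, high = -0.2)),
      seed = 500 + s))
    cfg <- run_config(subsample_mode = "global")
    pipe <- run_pipeline(world, cfg)
    agg <- aggregate_losses(pipe$losses, world$meta,
                            world$countries[, c("country_id", "income_group")],
                            axis = "income_group")
    disparity_ratio(agg, "low", "high")
  }, 0)
  expect_true(all(ratios > 1))
})
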