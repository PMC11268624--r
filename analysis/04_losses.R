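#!/usr/bin/env Rscript
# Stage 4: potential-progress losses and their aggregation.
#
# The loss per (country, indicator) is the direction-signed relative gap at
# 2030 between the post- and pre-pandemic projections. Aggregates are
# unweighted means by theme x income group, indicator x income group, and
# country; the headline statistic is the low- vs high-income disparity
# ratio.

suppressPackageStartupMessages(library(prestonloss))
suppressPackageStartupMessages(library(dplyr))

world_dir <- "scratch/world"
cfg <- run_config(seed = 20260)

panel <- read_indicator_panel(file.path(world_dir, "synthetic_indicator_panel.csv"))
covs <- read_covariates(file.path(world_dir, "synthetic_covariates.csv"))
countries <- read_countries(file.path(world_dir, "synthetic_countries.csv"))
scenarios <- read_growth_scenarios(file.path(world_dir, "synthetic_growth_pre.csv"),
                                   file.path(world_dir, "synthetic_growth_post.csv"))
meta <- read_indicator_meta(file.path(world_dir, "synthetic_indicator_meta.csv"))

periods <- build_periods(panel, covs, cfg)
groups <- countries[, c("country_id", "income_group")]
flt <- apply_coverage_filter(periods, groups, cfg)
fits <- fit_all(flt$panel, countries, cfg)
proj <- project_all(fits, countries, scenarios, latest_values(panel, cfg), cfg)

losses <- compute_loss(proj, meta, cfg)
aggs <- list(
  theme_group = aggregate_losses(losses, meta, groups, "theme_income_group"),
  indicator_group = aggregate_losses(losses, meta, groups, "indicator_income_group"),
  country = aggregate_losses(losses, meta, groups, "country"),
  income_group = aggregate_losses(losses, meta, groups, "income_group")
)
manifest <- write_results(losses, aggs, "results/losses")
message(paste(capture.output(print(manifest)), collapse = "\n"))

by_group <- aggs$income_group
message(paste(capture.output(print(by_group)), collapse = "\n"))
message(sprintf("low vs high disparity ratio: %.2f",
                disparity_ratio(by_group, "low", "high")))
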