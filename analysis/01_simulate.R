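#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study world.
#
# There is no redistributable copy of the UN SDG / IMF inputs, so the study
# runs on a synthetic world drawn from the generative model the estimator
# assumes: 150 countries, years 2000-2019, four indicators with known
# elasticities, and paired pre/post-pandemic growth vintages whose group
# means mirror the published forecast revisions. Raw fixture files go to
# scratch/ (they are bulky and reproducible); a small summary is kept under
# results/.

suppressPackageStartupMessages(library(prestonloss))
suppressPackageStartupMessages(library(dplyr))

world_dir <- "scratch/world"
dir.create("results", showWarnings = FALSE)

spec <- generator_spec(seed = 20260)
world <- gen_world(spec)
manifest <- gen_fixture_files(world, world_dir)

message(sprintf("world: %d countries, %d panel rows, %d indicators",
                nrow(world$countries), nrow(world$panel),
                length(unique(world$panel$indicator_id))))
message(paste(capture.output(print(manifest)), collapse = "\n"))

summary_tbl <- world$countries |>
  count(income_group, region, name = "n_countries")
readr::write_csv(summary_tbl, "results/world_composition.csv")
message("wrote results/world_composition.csv")
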