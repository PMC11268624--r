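#' Default ground-truth parameters for synthetic indicators
#'
#' Four synthetic indicators whose GDP elasticities span the range typical of
#' fitted health-indicator curves (roughly -1.7 to +0.9), two with negative
#' and two with positive elasticity so both directions of progress are
#' exercised, each with its own regional interaction profile.
#'
#' @return Named list: per indicator, `alpha`, `beta_gdp`, `beta_gini`,
#'   `beta_he` and a named `beta_region` vector (baseline region absent).
#' @export
default_true_params <- function() {
  list(
    synthA = list(
      alpha = 8.0, beta_gdp = -0.5, beta_gini = 0.2, beta_he = -0.1,
      beta_region = c(AMR = -0.12, SEAR = -0.08, EUR = -0.26, EMR = -0.13,
                      WPR = -0.17, CHN = -0.15, IND = -0.07)
    ),
    synthB = list(
      alpha = 10.5, beta_gdp = -1.4, beta_gini = 0.6, beta_he = -0.3,
      beta_region = c(AMR = 0.20, SEAR = -0.10, EUR = -0.30, EMR = 0.10,
                      WPR = -0.20, CHN = -0.25, IND = 0.05)
    ),
    synthC = list(
      alpha = 1.2, beta_gdp = 0.45, beta_gini = -0.2, beta_he = 0.2,
      beta_region = c(AMR = 0.05, SEAR = 0.03, EUR = 0.06, EMR = 0.02,
                      WPR = 0.04, CHN = 0.05, IND = 0.03)
    ),
    synthD = list(
      alpha = -3.0, beta_gdp = 0.9, beta_gini = -0.4, beta_he = 0.35,
      beta_region = c(AMR = 0.15, SEAR = 0.10, EUR = 0.19, EMR = 0.14,
                      WPR = 0.13, CHN = 0.17, IND = 0.10)
    )
  )
}

#' Specification of a synthetic world
#'
#' Encodes the statistical structure the estimation model assumes: a
#' multi-country yearly panel whose period-averaged log values follow the
#' log-log model exactly, with Gaussian country effects, period effects and
#' residual noise; geometric GDP paths with income-group drift, persistent
#' country-level growth offsets and transitory jitter; paired divergent
#' growth forecasts whose group means mirror the published pre/post
#' pandemic vintages (5.20/4.27/3.07/2.12 vs 4.36/3.45/2.71/2.02 percent per
#' year, poorest to richest); and group-structured country-level
#' missingness.
#'
#' @param n_countries Number of countries. Default 150.
#' @param years Historical years. Default 2000:2019.
#' @param horizon Last projection year. Default 2030.
#' @param period_length Period window used to lay down the ground-truth
#'   model. Default 5.
#' @param region_weights Named sampling probabilities over [region_codes()].
#' @param income_mix Named fractions over [income_groups()].
#' @param true_params Per-indicator ground truth; see
#'   [default_true_params()].
#' @param directions Named directions per indicator. By default aligned with
#'   the sign of each true elasticity (negative elasticity: lower is better),
#'   which is half/half under [default_true_params()] so sign handling is
#'   exercised both ways.
#' @param sigma_country,sigma_period,sigma_eps Standard deviations of the
#'   country effects, period effects and residual on the log scale.
#' @param growth_pre,growth_post Named mean yearly growth per income group
#'   (decimal fractions) for the baseline and revised scenario vintages.
#' @param growth_hist Named historical mean yearly growth per group, used to
#'   back-cast GDP paths (2010s decade averages by default).
#' @param growth_noise_sd Country-level spread around the scenario group
#'   means. Default 0.004 (0.4 pp/yr).
#' @param growth_persist_sd Persistent country growth offset in the
#'   historical back-cast. Default 0.015 (1.5 pp/yr).
#' @param growth_jitter_sd Transitory yearly growth noise in the historical
#'   back-cast. Default 0.03 (3 pp/yr).
#' @param group_elasticity Optional per-indicator named list of income-group
#'   overrides of `beta_gdp`, for worlds where the true elasticity differs
#'   by development level.
#' @param missing_rate Named fraction per income group of countries that do
#'   not report an indicator at all (country-level MCAR).
#' @param seed Integer seed; identical seeds give bit-identical worlds.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(n_countries = 150L,
                           years = 2000:2019,
                           horizon = 2030L,
                           period_length = 5L,
                           region_weights = c(AFR = 0.22, AMR = 0.18,
                                              SEAR = 0.05, EUR = 0.22,
                                              EMR = 0.10, WPR = 0.13,
                                              CHN = 0.05, IND = 0.05),
                           income_mix = c(low = 0.15, lower_middle = 0.28,
                                          upper_middle = 0.28, high = 0.29),
                           true_params = default_true_params(),
                           directions = NULL,
                           sigma_country = 0.25,
                           sigma_period = 0.05,
                           sigma_eps = 0.10,
                           growth_pre = c(low = 0.0520, lower_middle = 0.0427,
                                          upper_middle = 0.0307, high = 0.0212),
                           growth_post = c(low = 0.0436, lower_middle = 0.0345,
                                           upper_middle = 0.0271, high = 0.0202),
                           growth_hist = c(low = 0.0432, lower_middle = 0.0416,
                                           upper_middle = 0.0316, high = 0.0231),
                           growth_noise_sd = 0.004,
                           growth_persist_sd = 0.015,
                           growth_jitter_sd = 0.03,
                           group_elasticity = NULL,
                           missing_rate = c(low = 0, lower_middle = 0,
                                            upper_middle = 0, high = 0),
                           seed = 1L) {
  if (n_countries < 1L || length(years) < 1L) {
    stop("degenerate spec: need countries and years", call. = FALSE)
  }
  stopifnot(
    abs(sum(region_weights) - 1) < 1e-9,
    abs(sum(income_mix) - 1) < 1e-9,
    setequal(names(region_weights), region_codes()),
    setequal(names(income_mix), income_groups()),
    sigma_country >= 0, sigma_period >= 0, sigma_eps >= 0,
    all(growth_pre > -1), all(growth_post > -1), all(growth_hist > -1),
    all(income_groups() %in% names(growth_pre)),
    all(income_groups() %in% names(growth_post)),
    all(income_groups() %in% names(missing_rate))
  )
  if (is.null(directions)) {
    # sign-coherent default: economic growth improves the indicator, so
    # negative elasticities are "lower is better" (mortality-like) and
    # positive ones "higher is better" (coverage-like); half/half under
    # default_true_params()
    b1 <- vapply(true_params, function(p) p$beta_gdp, 0)
    directions <- setNames(
      ifelse(b1 <= 0, "lower_is_better", "higher_is_better"),
      names(true_params))
  }
  stopifnot(setequal(names(directions), names(true_params)))
  structure(
    list(
      n_countries = as.integer(n_countries), years = as.integer(years),
      horizon = as.integer(horizon), period_length = as.integer(period_length),
      region_weights = region_weights, income_mix = income_mix,
      true_params = true_params, directions = directions,
      sigma_country = sigma_country, sigma_period = sigma_period,
      sigma_eps = sigma_eps,
      growth_pre = growth_pre, growth_post = growth_post,
      growth_hist = growth_hist,
      growth_noise_sd = growth_noise_sd,
      growth_persist_sd = growth_persist_sd,
      growth_jitter_sd = growth_jitter_sd,
      group_elasticity = group_elasticity,
      missing_rate = missing_rate, seed = as.integer(seed)
    ),
    class = "generator_spec"
  )
}

with_fixed_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Generate a complete synthetic world
#'
#' Draws countries (region, income group, anchor GDP log-uniform inside its
#' group's bracket), back-casts yearly GDP paths, draws Gini (per-country
#' base uniform in [25, 55] with small yearly lognormal wiggle) and health
#' expenditure (group-level means rising with income, echoing published
#' group averages), and lays down indicator values that satisfy the log-log
#' period model exactly: the log period value is
#' `alpha + beta' x + f_i + tau_t + eps`, with `f_i ~ N(0, sigma_country)`,
#' `tau_t ~ N(0, sigma_period)`, `eps ~ N(0, sigma_eps)`, and yearly values
#' held constant within each period window so that period-averaging then
#' logging recovers the model without aggregation bias. Paired growth
#' scenarios come from [gen_scenarios()] under the same seed, and
#' missingness removes whole (country, indicator) series at the group's
#' configured rate.
#'
#' @param spec A [generator_spec()].
#' @return List with `countries`, `covariates`, `panel`, `scenarios`
#'   (elements `pre`, `post`), `meta`, and `truth` (ground-truth parameters
#'   and effect draws).
#' @export
gen_world <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  with_fixed_rng(spec$seed, {
    n <- spec$n_countries
    years <- spec$years
    n_years <- length(years)
    anchor_year <- max(years)

    countries <- tibble::tibble(
      country_id = sprintf("C%03d", seq_len(n)),
      region = sample(names(spec$region_weights), n, replace = TRUE,
                      prob = spec$region_weights),
      income_group = sample(names(spec$income_mix), n, replace = TRUE,
                            prob = spec$income_mix)
    )
    bounds <- list(low = c(300, 1045), lower_middle = c(1046, 4095),
                   upper_middle = c(4096, 12695), high = c(12696, 80000))
    lb <- vapply(countries$income_group, function(g) bounds[[g]][1], 0)
    ub <- vapply(countries$income_group, function(g) bounds[[g]][2], 0)
    gdp_anchor <- exp(runif(n, log(lb), log(ub)))
    countries$gdp_pc_anchor <- gdp_anchor

    # back-cast yearly GDP: group drift + persistent country offset +
    # transitory jitter, compounded backwards from the anchor level
    persist <- rnorm(n, 0, spec$growth_persist_sd)
    drift <- spec$growth_hist[countries$income_group] + persist
    gdp <- matrix(NA_real_, n, n_years, dimnames = list(NULL, years))
    gdp[, n_years] <- gdp_anchor
    for (j in rev(seq_len(n_years - 1L))) {
      g <- drift + rnorm(n, 0, spec$growth_jitter_sd)
      g <- pmax(g, -0.5)
      gdp[, j] <- gdp[, j + 1L] / (1 + g)
    }

    gini_base <- runif(n, 25, 55)
    gini <- gini_base * exp(matrix(rnorm(n * n_years, 0, 0.02), n, n_years))
    gini <- pmin(gini, 100)

    he_means <- c(low = 5.85, lower_middle = 5.75, upper_middle = 7.14,
                  high = 9.00)
    he_base <- he_means[countries$income_group] * exp(rnorm(n, 0, 0.12))
    he <- he_base * exp(matrix(rnorm(n * n_years, 0, 0.03), n, n_years))

    covariates <- tibble::tibble(
      country_id = rep(countries$country_id, each = n_years),
      year = rep(years, times = n),
      gdp_pc = as.vector(t(gdp)),
      gini = as.vector(t(gini)),
      health_exp_pct_gdp = as.vector(t(he))
    )

    # period-window means of the covariates, mirroring the estimation windows
    period_of <- (years - min(years)) %/% spec$period_length
    periods <- sort(unique(period_of))
    pmean <- function(M) {
      vapply(periods, function(p) rowMeans(M[, period_of == p, drop = FALSE]),
             numeric(n))
    }
    lgdp_p <- log(pmean(gdp))
    lgini_p <- log(pmean(gini))
    lhe_p <- log(pmean(he))

    inds <- names(spec$true_params)
    panel_parts <- vector("list", length(inds))
    f_parts <- vector("list", length(inds))
    tau_parts <- vector("list", length(inds))
    for (m in seq_along(inds)) {
      ind <- inds[m]
      pr <- spec$true_params[[ind]]
      b1 <- rep(pr$beta_gdp, n)
      if (!is.null(spec$group_elasticity[[ind]])) {
        ov <- spec$group_elasticity[[ind]]
        hit <- countries$income_group %in% names(ov)
        b1[hit] <- ov[countries$income_group[hit]]
      }
      breg <- rep(0, n)
      in_reg <- countries$region %in% names(pr$beta_region)
      breg[in_reg] <- pr$beta_region[countries$region[in_reg]]

      f_i <- rnorm(n, 0, spec$sigma_country)
      tau_p <- rnorm(length(periods), 0, spec$sigma_period)
      eps <- matrix(rnorm(n * length(periods), 0, spec$sigma_eps),
                    n, length(periods))

      ln_sdg_p <- pr$alpha + (b1 + breg) * lgdp_p +
        pr$beta_gini * lgini_p + pr$beta_he * lhe_p +
        f_i + matrix(tau_p, n, length(periods), byrow = TRUE) + eps
      # yearly values constant within each period window
      value_year <- exp(ln_sdg_p[, period_of + 1L, drop = FALSE])

      report <- runif(n) >= spec$missing_rate[countries$income_group]
      keep <- which(report)
      panel_parts[[m]] <- tibble::tibble(
        country_id = rep(countries$country_id[keep], each = n_years),
        year = rep(years, times = length(keep)),
        indicator_id = ind,
        value = as.vector(t(value_year[keep, , drop = FALSE]))
      )
      f_parts[[m]] <- tibble::tibble(indicator_id = ind,
                                     country_id = countries$country_id,
                                     effect = f_i)
      tau_parts[[m]] <- tibble::tibble(indicator_id = ind,
                                       period_index = periods, effect = tau_p)
    }
    panel <- dplyr::bind_rows(panel_parts)
    if (nrow(panel) == 0L) stop("missingness removed every country", call. = FALSE)

    themes <- health_themes()
    meta <- tibble::tibble(
      indicator_id = inds,
      theme = themes[(seq_along(inds) - 1L) %% length(themes) + 1L],
      direction = unname(spec$directions[inds]),
      label = paste0("synthetic indicator ", inds)
    )

    truth <- list(
      params = spec$true_params,
      group_elasticity = spec$group_elasticity,
      country_effects = dplyr::bind_rows(f_parts),
      period_effects = dplyr::bind_rows(tau_parts),
      spec = spec
    )

    scenarios <- gen_scenarios(spec, countries)

    list(countries = countries, covariates = covariates, panel = panel,
         scenarios = scenarios, meta = meta, truth = truth)
  })
}

#' Generate a paired pre/post growth-scenario vintage
#'
#' Each country's yearly rate is its income group's scenario mean plus a
#' persistent country-level offset (shared between the two vintages, so the
#' revision is a clean group-level shock). Rates cover the anchor year
#' through the horizon. With the default group means, every post-vintage
#' group mean sits strictly below its pre-vintage counterpart.
#'
#' @param spec A [generator_spec()].
#' @param countries Country table from [gen_world()].
#' @return List with [growth_scenario()] elements `pre` and `post`.
#' @export
gen_scenarios <- function(spec, countries) {
  stopifnot(inherits(spec, "generator_spec"))
  missing_grp <- setdiff(unique(countries$income_group), names(spec$growth_pre))
  if (length(missing_grp)) {
    stop("growth means absent for group(s): ",
         paste(missing_grp, collapse = ", "), call. = FALSE)
  }
  with_fixed_rng(spec$seed + 1L, {
    n <- nrow(countries)
    scn_years <- seq(max(spec$years), spec$horizon)
    noise <- rnorm(n, 0, spec$growth_noise_sd)
    make <- function(means, id) {
      rate_i <- unname(means[countries$income_group]) + noise
      growth_scenario(
        tibble::tibble(
          country_id = rep(countries$country_id, each = length(scn_years)),
          year = rep(scn_years, times = n),
          rate = rep(rate_i, each = length(scn_years))
        ), id)
    }
    list(pre = make(spec$growth_pre, "pre_covid"),
         post = make(spec$growth_post, "post_covid"))
  })
}

#' Ground-truth terminal values implied by a synthetic world
#'
#' The generator's own forward simulation: for every reported (country,
#' indicator) it carries the anchor-year value to the horizon with the true
#' combined elasticity and the scenario's compounded GDP ratio, bypassing
#' the estimation pipeline entirely. Used as the oracle for end-to-end
#' closure checks.
#'
#' @param world Output of [gen_world()].
#' @param cfg A [run_config()]; its projection range sets the horizon.
#' @return Tibble `country_id`, `indicator_id`, `scenario_id`,
#'   `value_final`.
#' @export
true_forward_values <- function(world, cfg = run_config()) {
  spec <- world$truth$spec
  anchor_year <- max(spec$years)
  horizon <- max(cfg$projection_years)
  last <- world$panel[world$panel$year == anchor_year, ]

  out <- list()
  for (which in c("pre", "post")) {
    scn <- world$scenarios[[which]]
    ratio <- scn |>
      dplyr::filter(.data$year >= anchor_year, .data$year <= horizon) |>
      dplyr::group_by(.data$country_id) |>
      dplyr::summarise(gdp_ratio = prod(1 + .data$rate), .groups = "drop")
    d <- last |>
      dplyr::inner_join(world$countries[, c("country_id", "region",
                                            "income_group")],
                        by = "country_id") |>
      dplyr::inner_join(ratio, by = "country_id")
    elast <- vapply(seq_len(nrow(d)), function(i) {
      pr <- spec$true_params[[d$indicator_id[i]]]
      b1 <- pr$beta_gdp
      ov <- spec$group_elasticity[[d$indicator_id[i]]]
      if (!is.null(ov) && d$income_group[i] %in% names(ov)) {
        b1 <- ov[[d$income_group[i]]]
      }
      b4 <- if (d$region[i] %in% names(pr$beta_region)) {
        pr$beta_region[[d$region[i]]]
      } else 0
      b1 + b4
    }, 0)
    out[[which]] <- tibble::tibble(
      country_id = d$country_id,
      indicator_id = d$indicator_id,
      scenario_id = attr(scn, "scenario_id"),
      value_final = d$value * d$gdp_ratio^elast
    )
  }
  dplyr::bind_rows(out)
}

#' Write a synthetic world to fixture files
#'
#' Emits exactly the delimited dialects the readers consume (growth rates in
#' percent at the file boundary), plus the ground-truth parameter table for
#' test assertions. All files carry a `synthetic_` prefix.
#'
#' @param world Output of [gen_world()].
#' @param path Output directory; created if absent.
#' @return Manifest tibble `file`, `rows`, invisibly.
#' @export
gen_fixture_files <- function(world, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create '", path, "'", call. = FALSE)

  files <- list(
    synthetic_countries = tibble::tibble(
      country = world$countries$country_id,
      region = world$countries$region,
      income_group = world$countries$income_group,
      gdp_pc_anchor = world$countries$gdp_pc_anchor
    ),
    synthetic_indicator_panel = tibble::tibble(
      country = world$panel$country_id, year = world$panel$year,
      indicator = world$panel$indicator_id, value = world$panel$value
    ),
    synthetic_covariates = tibble::tibble(
      country = world$covariates$country_id, year = world$covariates$year,
      gdp_pc = world$covariates$gdp_pc, gini = world$covariates$gini,
      health_exp_pct_gdp = world$covariates$health_exp_pct_gdp
    ),
    synthetic_growth_pre = scenario_to_pct(world$scenarios$pre),
    synthetic_growth_post = scenario_to_pct(world$scenarios$post),
    synthetic_indicator_meta = tibble::tibble(
      indicator = world$meta$indicator_id, theme = world$meta$theme,
      direction = world$meta$direction, label = world$meta$label
    ),
    synthetic_ground_truth = truth_table(world$truth)
  )
  manifest <- tibble::tibble(
    file = file.path(path, paste0(names(files), ".csv")),
    rows = vapply(files, nrow, 0L)
  )
  for (i in seq_along(files)) write_csv_full(files[[i]], manifest$file[i])
  invisible(manifest)
}

scenario_to_pct <- function(scn) {
  tibble::tibble(country = scn$country_id, year = scn$year,
                 growth_pct = scn$rate * 100)
}

truth_table <- function(truth) {
  rows <- lapply(names(truth$params), function(ind) {
    pr <- truth$params[[ind]]
    tibble::tibble(
      indicator = ind,
      term = c("alpha", "beta_gdp", "beta_gini", "beta_he",
               paste0("beta_region_", names(pr$beta_region))),
      value = c(pr$alpha, pr$beta_gdp, pr$beta_gini, pr$beta_he,
                unname(pr$beta_region))
    )
  })
  dplyr::bind_rows(rows)
}
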