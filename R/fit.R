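#' Build the design matrix for one indicator's Preston-curve fit
#'
#' Columns are, in keep-priority order: `ln_gdp_pc`, `ln_gini`, `ln_he`, one
#' GDP interaction column per non-baseline region present in the data
#' (`gdp_x_<REG>`, equal to `ln_gdp_pc` for that region's countries and 0
#' elsewhere; the baseline region AFR has no column), and — when `time_fe` is
#' on and several periods are present — one dummy per period after the first.
#' All-zero columns are dropped at construction; collinearity that only
#' appears after the within-transformation is detected at fit time, with
#' later columns (interactions, dummies) ceding to earlier ones.
#'
#' @param panel Period panel rows for a single indicator.
#' @param regions Tibble `country_id`, `region` covering every country.
#' @param time_fe Include period fixed effects. Default `TRUE`.
#' @return List of class `preston_design`: `response`, `X` (numeric matrix),
#'   `row_keys` (tibble `country_id`, `period_index`), `indicator_id`,
#'   `time_fe`, `dropped_terms`.
#' @export
build_design <- function(panel, regions, time_fe = TRUE) {
  ind <- unique(panel$indicator_id)
  if (length(ind) != 1L) {
    stop("build_design expects a single indicator, got: ",
         paste(ind, collapse = ", "), call. = FALSE)
  }
  d <- dplyr::inner_join(panel, regions, by = "country_id")
  if (nrow(d) < nrow(panel)) {
    stop("region unknown for some countries in the panel", call. = FALSE)
  }
  if (dplyr::n_distinct(d$country_id) < 2L) {
    stop("design needs at least 2 distinct countries", call. = FALSE)
  }
  d <- dplyr::arrange(d, .data$country_id, .data$period_index)

  cols <- list(
    ln_gdp_pc = d$ln_gdp_pc,
    ln_gini = d$ln_gini,
    ln_he = d$ln_he
  )
  for (reg in intersect(region_codes(), unique(d$region))) {
    if (reg == baseline_region()) next
    cols[[paste0("gdp_x_", reg)]] <- ifelse(d$region == reg, d$ln_gdp_pc, 0)
  }
  periods <- sort(unique(d$period_index))
  if (time_fe && length(periods) >= 2L) {
    for (p in periods[-1]) {
      cols[[paste0("period_", p)]] <- as.numeric(d$period_index == p)
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL

  zero <- apply(X, 2, function(v) all(v == 0))
  dropped <- colnames(X)[zero]
  X <- X[, !zero, drop = FALSE]

  structure(
    list(
      response = d$ln_sdg,
      X = X,
      row_keys = tibble::tibble(country_id = d$country_id,
                                period_index = d$period_index),
      indicator_id = ind,
      time_fe = time_fe,
      dropped_terms = dropped
    ),
    class = "preston_design"
  )
}

# greedy rank-revealing column selection: walk columns in order, keep a
# column only if it increases the numerical rank at relative tolerance `tol`.
# Column order therefore encodes keep-priority (main effects before
# interactions before dummies).
select_independent_columns <- function(X, tol = 1e-10) {
  keep <- integer(0)
  for (j in seq_len(ncol(X))) {
    if (all(abs(X[, j]) < tol * max(1, max(abs(X))))) next
    cand <- X[, c(keep, j), drop = FALSE]
    if (qr(cand, tol = tol)$rank == length(keep) + 1L) keep <- c(keep, j)
  }
  keep
}

new_preston_fit <- function(...) {
  structure(list(...), class = "preston_fit")
}

#' Minimal fit-result constructor
#'
#' Builds a lightweight fit object from known coefficients — useful for
#' worked examples and for composing elasticities from published coefficient
#' tables without re-estimating.
#'
#' @param beta_gdp GDP elasticity (the main log-log coefficient).
#' @param beta_region Named numeric vector of region-interaction add-ons
#'   (baseline region absent).
#' @param alpha Constant. Default `NA`.
#' @param ... Further fields stored verbatim.
#' @return A `preston_fit` object.
#' @export
#' @examples
#' f <- fit_result(beta_gdp = -0.4910, beta_region = c(EUR = -0.2587))
#' combined_elasticity(f, "EUR")
fit_result <- function(beta_gdp, beta_region = c(), alpha = NA_real_, ...) {
  new_preston_fit(beta_gdp = beta_gdp, beta_region = beta_region,
                  alpha = alpha, ...)
}

#' @export
print.preston_fit <- function(x, ...) {
  cat(sprintf("<preston_fit%s%s>\n",
              if (!is.null(x$indicator_id)) paste0(" ", x$indicator_id) else "",
              if (!is.null(x$subsample)) paste0(" [", x$subsample, "]") else ""))
  if (!is.null(x$estimator_kind)) cat("  estimator:", x$estimator_kind, "\n")
  cat(sprintf("  ln GDPpc: %s  ln Gini: %s  ln HE: %s\n",
              format(x$beta_gdp), format(x$beta_gini), format(x$beta_he)))
  if (length(x$beta_region)) {
    cat("  region x ln GDPpc:",
        paste(names(x$beta_region), format(x$beta_region, digits = 4),
              sep = "=", collapse = " "), "\n")
  }
  if (length(x$dropped_terms)) {
    cat("  dropped (collinear):", paste(x$dropped_terms, collapse = ", "), "\n")
  }
  if (!is.null(x$n_obs)) {
    cat(sprintf("  n = %d | r2 within/between/overall = %s/%s/%s\n", x$n_obs,
                format(x$r2_within, digits = 4), format(x$r2_between, digits = 4),
                format(x$r2_overall, digits = 4)))
  }
  invisible(x)
}

#' Fit the extended Preston curve by the within (fixed-effects) estimator
#'
#' Country effects are absorbed by demeaning every variable within country;
#' period effects enter as dummy columns of the design. The slope estimates
#' are numerically identical to least squares with explicit country dummies
#' (LSDV) on the same data. The constant is the grand mean of the
#' composite residual `y - Xb`, and country effects are the per-country
#' means of that composite centred on the constant.
#'
#' Fit statistics follow the panel-software convention: `r2_within`,
#' `r2_between` and `r2_overall` are the squared correlations between the
#' linear predictor `Xb` and the response on the within-demeaned scale, the
#' country-mean scale, and the raw scale respectively. `joint_stat` is the
#' F statistic for all retained slope coefficients jointly zero
#' (homoskedastic, or cluster-robust when `cluster_se`).
#'
#' @param dm A `preston_design` from [build_design()].
#' @param cluster_se Country-clustered (CR1) standard errors instead of the
#'   conventional homoskedastic ones. Default `FALSE`.
#' @return A `preston_fit` with coefficients, `country_effects`,
#'   `time_effects`, `residuals`, standard errors (`se`), `vcov`,
#'   `dropped_terms`, the r-squared trio and `joint_stat`;
#'   `estimator_kind = "panel_fe"`.
#' @export
fit_panel_fe <- function(dm, cluster_se = FALSE) {
  stopifnot(inherits(dm, "preston_design"))
  y <- dm$response
  X <- dm$X
  cid <- dm$row_keys$country_id
  n <- length(y)

  multi <- table(cid)
  if (sum(multi >= 2L) < 2L || length(unique(dm$row_keys$period_index)) < 2L) {
    stop("fewer than 2 periods for 2 countries: use fit_cross_section_ols",
         call. = FALSE)
  }

  demean <- function(v) v - stats::ave(v, cid)
  yd <- demean(y)
  Xd <- apply(X, 2, demean)

  sel <- select_independent_columns(Xd)
  if (length(sel) == 0L) {
    stop("all regressors collinear after the within-transformation",
         call. = FALSE)
  }
  dropped <- union(dm$dropped_terms, setdiff(colnames(X), colnames(X)[sel]))
  Xs <- Xd[, sel, drop = FALSE]

  ls <- stats::lm.fit(Xs, yd)
  b <- coef(ls)
  e <- ls$residuals

  G <- length(unique(cid))
  k <- length(sel)
  df <- n - G - k
  if (df <= 0) stop("not enough observations for the free parameters", call. = FALSE)

  XtXinv <- chol2inv(chol(crossprod(Xs)))
  if (cluster_se) {
    Xe <- Xs * e
    meat <- matrix(0, k, k)
    for (g in unique(cid)) {
      sg <- colSums(Xe[cid == g, , drop = FALSE])
      meat <- meat + tcrossprod(sg)
    }
    adj <- G / (G - 1) * (n - 1) / df
    V <- adj * XtXinv %*% meat %*% XtXinv
  } else {
    sigma2 <- sum(e^2) / df
    V <- sigma2 * XtXinv
  }
  dimnames(V) <- list(colnames(Xs), colnames(Xs))
  se <- sqrt(diag(V))

  xb_raw <- drop(X[, sel, drop = FALSE] %*% b)
  comp <- y - xb_raw
  alpha <- mean(comp)
  fe_tab <- tapply(comp, cid, mean) - alpha
  country_effects <- setNames(as.numeric(fe_tab), names(fe_tab))

  period_cols <- grep("^period_", colnames(Xs), value = TRUE)
  time_effects <- setNames(b[period_cols], sub("^period_", "", period_cols))
  slope_cols <- setdiff(colnames(Xs), period_cols)

  r2_within <- safe_cor2(drop(Xs %*% b), yd)
  ybar <- tapply(y, cid, mean)
  xbbar <- tapply(xb_raw, cid, mean)
  r2_between <- safe_cor2(as.numeric(xbbar), as.numeric(ybar))
  r2_overall <- safe_cor2(xb_raw, y)

  joint <- wald_f(b, V, names(b), df)

  new_preston_fit(
    indicator_id = dm$indicator_id,
    subsample = NULL,
    estimator_kind = "panel_fe",
    alpha = alpha,
    beta_gdp = coef_or_na(b, "ln_gdp_pc"),
    beta_gini = coef_or_na(b, "ln_gini"),
    beta_he = coef_or_na(b, "ln_he"),
    beta_region = region_betas(b),
    dropped_terms = dropped,
    country_effects = country_effects,
    time_effects = time_effects,
    residuals = e,
    n_obs = n,
    n_countries = G,
    r2_within = r2_within,
    r2_between = r2_between,
    r2_overall = r2_overall,
    joint_stat = joint$stat,
    joint_df = joint$df,
    joint_assumption = if (cluster_se) "cluster_robust" else "homoskedastic",
    se = se,
    vcov = V,
    df_resid = df,
    slope_terms = slope_cols,
    coefficients = b
  )
}

#' Fit the Preston curve by single-period cross-sectional OLS
#'
#' Fallback estimator for indicators whose series are too short for panel
#' estimation (e.g. a single survey round). Requires one period and at least
#' two more countries than free parameters. `r2_overall` is reported;
#' within/between r-squared are undefined and returned as `NA`.
#'
#' @param dm A `preston_design` built with `time_fe = FALSE` on a
#'   single-period subset.
#' @return A `preston_fit` with `estimator_kind = "cross_section_ols"` and
#'   empty country/time effects.
#' @export
fit_cross_section_ols <- function(dm) {
  stopifnot(inherits(dm, "preston_design"))
  periods <- unique(dm$row_keys$period_index)
  if (length(periods) != 1L) {
    stop("cross-section OLS expects a single period, got ", length(periods),
         call. = FALSE)
  }
  y <- dm$response
  X <- cbind(`(Intercept)` = 1, dm$X)
  n <- length(y)

  sel <- select_independent_columns(X)
  Xs <- X[, sel, drop = FALSE]
  k <- ncol(Xs)
  if (n < k + 2L) {
    stop("underdetermined cross-section: ", n, " countries for ", k,
         " parameters", call. = FALSE)
  }
  dropped <- union(dm$dropped_terms, setdiff(colnames(X), colnames(Xs)))
  dropped <- setdiff(dropped, "(Intercept)")

  ls <- stats::lm.fit(Xs, y)
  b <- coef(ls)
  e <- ls$residuals
  df <- n - k
  sigma2 <- sum(e^2) / df
  V <- sigma2 * chol2inv(chol(crossprod(Xs)))
  dimnames(V) <- list(colnames(Xs), colnames(Xs))
  se <- sqrt(diag(V))

  fitted <- drop(Xs %*% b)
  r2 <- safe_cor2(fitted, y)
  slope_terms <- setdiff(colnames(Xs), "(Intercept)")
  joint <- wald_f(b, V, slope_terms, df)

  new_preston_fit(
    indicator_id = dm$indicator_id,
    subsample = NULL,
    estimator_kind = "cross_section_ols",
    alpha = unname(b["(Intercept)"]),
    beta_gdp = coef_or_na(b, "ln_gdp_pc"),
    beta_gini = coef_or_na(b, "ln_gini"),
    beta_he = coef_or_na(b, "ln_he"),
    beta_region = region_betas(b),
    dropped_terms = dropped,
    country_effects = setNames(numeric(0), character(0)),
    time_effects = setNames(numeric(0), character(0)),
    residuals = e,
    n_obs = n,
    n_countries = n,
    r2_within = NA_real_,
    r2_between = NA_real_,
    r2_overall = r2,
    joint_stat = joint$stat,
    joint_df = joint$df,
    joint_assumption = "homoskedastic",
    se = se,
    vcov = V,
    df_resid = df,
    slope_terms = slope_terms,
    coefficients = b
  )
}

#' GDP elasticity for a country in a given region
#'
#' Returns the main log-log GDP coefficient plus the region's interaction
#' add-on. The baseline region, regions absent from the fit, and
#' interactions dropped for collinearity all contribute 0, so the main
#' elasticity carries through unchanged.
#'
#' @param fit A `preston_fit` (or any list with `beta_gdp` and
#'   `beta_region`).
#' @param region One of [region_codes()].
#' @return The combined elasticity, a single number.
#' @export
#' @examples
#' f <- fit_result(beta_gdp = -0.4910, beta_region = c(EUR = -0.2587))
#' combined_elasticity(f, "EUR")  # -0.7497
#' combined_elasticity(f, "AFR")  # -0.4910
combined_elasticity <- function(fit, region) {
  if (!is.character(region) || length(region) != 1L ||
      !region %in% region_codes()) {
    stop("unknown region code: ", paste(region, collapse = ", "), call. = FALSE)
  }
  b4 <- 0
  if (region != baseline_region() && region %in% names(fit$beta_region)) {
    v <- fit$beta_region[[region]]
    if (is.finite(v)) b4 <- v
  }
  unname(fit$beta_gdp + b4)
}

#' Fit every retained (indicator, subsample) cell
#'
#' Runs the global fit plus one fit per income group for each indicator in
#' the (coverage-filtered) panel. The estimator is chosen per cell from
#' [balance_check()]: within estimator where unit and time variation allow,
#' single-period OLS otherwise (on the period covering the most countries),
#' and an explicit failure record where neither is estimable — cells are
#' never silently skipped.
#'
#' @param panel Coverage-filtered period panel (see
#'   [apply_coverage_filter()]).
#' @param countries Country table (`country_id`, `region`, `income_group`).
#' @param cfg A [run_config()].
#' @param time_fe Include period fixed effects in panel fits. Default `TRUE`.
#' @return Tibble with columns `indicator_id`, `subsample`, `estimator`,
#'   `status` (`"ok"`/`"failed"`), `reason`, and a `fit` list-column of
#'   `preston_fit` objects (NULL on failure).
#' @export
fit_all <- function(panel, countries, cfg = run_config(), time_fe = TRUE) {
  regions <- countries[, c("country_id", "region")]
  groups <- countries[, c("country_id", "income_group")]
  if (!"income_group" %in% names(panel)) {
    panel <- dplyr::left_join(panel, groups, by = "country_id")
  }

  cells <- dplyr::bind_rows(
    tibble::tibble(indicator_id = unique(panel$indicator_id),
                   subsample = "global"),
    panel |>
      dplyr::distinct(.data$indicator_id, .data$income_group) |>
      dplyr::rename(subsample = "income_group")
  )

  fit_cell <- function(indicator_id, subsample) {
    rows <- panel[panel$indicator_id == indicator_id, ]
    if (subsample != "global") rows <- rows[rows$income_group == subsample, ]
    res <- list(estimator = NA_character_, status = "failed",
                reason = NA_character_, fit = NULL)
    bc <- tryCatch(balance_check(rows)$indicators$status,
                   error = function(e) "unusable")
    if (bc == "unusable") {
      res$reason <- "fewer than 2 countries"
      return(res)
    }
    out <- tryCatch({
      if (bc == "panel") {
        dm <- build_design(rows, regions, time_fe = time_fe)
        f <- fit_panel_fe(dm, cluster_se = cfg$cluster_se)
      } else {
        counts <- table(rows$period_index)
        best_p <- as.integer(names(counts)[which.max(counts)])
        dm <- build_design(rows[rows$period_index == best_p, ], regions,
                           time_fe = FALSE)
        f <- fit_cross_section_ols(dm)
      }
      f$subsample <- subsample
      f
    }, error = function(e) conditionMessage(e))
    if (is.character(out)) {
      res$reason <- out
    } else {
      res <- list(estimator = out$estimator_kind, status = "ok",
                  reason = NA_character_, fit = out)
    }
    res
  }

  results <- purrr::pmap(cells, function(indicator_id, subsample) {
    r <- fit_cell(indicator_id, subsample)
    tibble::tibble(indicator_id = indicator_id, subsample = subsample,
                   estimator = r$estimator, status = r$status,
                   reason = r$reason, fit = list(r$fit))
  })
  dplyr::bind_rows(results)
}

#' Tidy coefficient table from a set of fits
#'
#' Long format: one row per (indicator, subsample, term), with estimate and
#' standard error; terms dropped for collinearity appear with `NA` estimate,
#' mirroring the em-dash convention of published coefficient tables.
#'
#' @param fits Result of [fit_all()].
#' @return Tibble `indicator_id`, `subsample`, `term`, `estimate`, `se`.
#' @export
tidy_fits <- function(fits) {
  ok <- fits[fits$status == "ok", ]
  purrr::pmap(ok[, c("indicator_id", "subsample", "fit")],
              function(indicator_id, subsample, fit) {
    terms <- fit$slope_terms
    est <- fit$coefficients[terms]
    se <- fit$se[terms]
    dropped <- setdiff(fit$dropped_terms, grep("^period_", fit$dropped_terms,
                                               value = TRUE))
    tibble::tibble(
      indicator_id = indicator_id, subsample = subsample,
      term = c(terms, dropped, "(Constant)"),
      estimate = c(unname(est), rep(NA_real_, length(dropped)), fit$alpha),
      se = c(unname(se), rep(NA_real_, length(dropped)), NA_real_)
    )
  }) |> dplyr::bind_rows()
}

coef_or_na <- function(b, nm) if (nm %in% names(b)) unname(b[nm]) else NA_real_

region_betas <- function(b) {
  rb <- b[grep("^gdp_x_", names(b))]
  setNames(unname(rb), sub("^gdp_x_", "", names(rb)))
}

safe_cor2 <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  min(max(cor(a, b)^2, 0), 1)
}

wald_f <- function(b, V, terms, df_resid) {
  terms <- intersect(terms, names(b))
  terms <- setdiff(terms, "(Intercept)")
  if (length(terms) == 0L) return(list(stat = NA_real_, df = c(0, df_resid)))
  bb <- b[terms]
  VV <- V[terms, terms, drop = FALSE]
  stat <- tryCatch(
    drop(t(bb) %*% solve(VV, bb)) / length(terms),
    error = function(e) NA_real_
  )
  list(stat = stat, df = c(length(terms), df_resid))
}
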