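# Synthetic country-table generator.
#
# Dependence between each covariate and dietary LCn-3 is induced through a
# one-factor Gaussian copula on ranks: a shared latent normal drives LCn-3,
# and each covariate's latent is correlated with it. Marginals are then free
# choices (only rank structure matters to the median-quadrant method):
# GDP log-normal, ranked price a permutation, total fish gamma, percent
# marine scaled beta, LCn-3 and serving size zero-truncated normal.

.country_covariates <- c("recommended_g_day", "gdp_percap", "price_rank",
                         "total_fish", "pct_marine")
.maskable_columns <- c("lcn3_mg_day", .country_covariates)

#' Configure a synthetic country-table scenario
#'
#' Builds a validated configuration for [generate_countries()]. The defaults
#' describe the study conditions the package's analyses assume: 166 countries,
#' FBDG category frequencies matching a compiled global table (65 countries
#' with a seafood serving size, 92 with any seafood recommendation), a
#' serving-size distribution of roughly 32.9 +/- 17.4 g/day, and null
#' (zero) covariate effects.
#'
#' @param n_countries Number of countries to generate (>= 8).
#' @param seed Integer seed; the generator is fully deterministic given
#'   `seed` and the remaining configuration.
#' @param effect Rank-correlation strength in `[-1, 1]` between each covariate
#'   and dietary LCn-3. Either a single number recycled to all covariates or a
#'   named vector over any of `recommended_g_day`, `gdp_percap`, `price_rank`,
#'   `total_fish`, `pct_marine` (unnamed covariates default to 0). The value
#'   is the population Spearman correlation of the generated pair: internally
#'   the Gaussian-copula latent correlation is `2*sin(pi*effect/6)`.
#' @param fbdg_probs Probabilities of the four FBDG categories (see
#'   [fbdg_levels()]); must sum to 1 within `1e-9`.
#' @param missingness Probability in `[0, 1)` of masking each cell, applied
#'   independently per cell (MCAR), never to `country_id`. A single number or
#'   a named vector over the maskable columns (`lcn3_mg_day` and the five
#'   covariates). Default 0.
#' @param gdp_log_mean,gdp_log_sd Log-scale mean and sd of per-capita GDP
#'   (log-normal marginal), in log-USD.
#' @param lcn3_mean_mgday,lcn3_sd Mean and sd (mg EPA+DHA per capita per day)
#'   of the zero-truncated normal LCn-3 marginal.
#' @param serving_mean_g_day,serving_sd_g_day Mean and sd (g/day) of the
#'   zero-truncated normal recommended-serving marginal, present only for
#'   countries in the `rec_with_serving` category.
#' @param total_fish_shape,total_fish_mean Shape and mean (kg per capita per
#'   year) of the gamma marginal for total fish supply.
#' @param pct_marine_shape1,pct_marine_shape2 Beta shape parameters for the
#'   percent-of-marine-origin marginal (scaled to 0-100).
#'
#' @return A list of class `country_scenario`.
#' @seealso [generate_countries()], [consumption_scenario()]
#' @export
#' @examples
#' cfg <- country_scenario(n_countries = 50, seed = 7,
#'                         effect = c(gdp_percap = 0.4))
#' head(generate_countries(cfg))
country_scenario <- function(n_countries = 166L,
                             seed = 1L,
                             effect = 0,
                             fbdg_probs = c(none = 41, no_recommendation = 33,
                                            rec_with_serving = 65,
                                            rec_without_serving = 27) / 166,
                             missingness = 0,
                             gdp_log_mean = log(12000),
                             gdp_log_sd = 1.3,
                             lcn3_mean_mgday = 150,
                             lcn3_sd = 120,
                             serving_mean_g_day = 32.9,
                             serving_sd_g_day = 17.4,
                             total_fish_shape = 2,
                             total_fish_mean = 20,
                             pct_marine_shape1 = 2,
                             pct_marine_shape2 = 1.2) {
  if (!is.numeric(n_countries) || length(n_countries) != 1 ||
      is.na(n_countries) || n_countries < 8 || n_countries != floor(n_countries)) {
    stop_config("n_countries", "must be a single integer >= 8")
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop_config("seed", "must be a single integer")
  }
  effect <- .expand_named(effect, .country_covariates, "effect")
  if (any(is.na(effect)) || any(abs(effect) > 1)) {
    stop_config("effect", "entries must be in [-1, 1]")
  }
  if (length(fbdg_probs) != 4 || any(is.na(fbdg_probs)) || any(fbdg_probs < 0)) {
    stop_config("fbdg_probs", "must be 4 nonnegative probabilities")
  }
  if (is.null(names(fbdg_probs))) {
    names(fbdg_probs) <- fbdg_levels()
  }
  if (!setequal(names(fbdg_probs), fbdg_levels())) {
    stop_config("fbdg_probs", sprintf("names must be {%s}",
                                      paste(fbdg_levels(), collapse = ", ")))
  }
  fbdg_probs <- fbdg_probs[fbdg_levels()]
  if (abs(sum(fbdg_probs) - 1) > 1e-9) {
    stop_config("fbdg_probs", "must sum to 1 within 1e-9")
  }
  missingness <- .expand_named(missingness, .maskable_columns, "missingness")
  if (any(is.na(missingness)) || any(missingness < 0) || any(missingness >= 1)) {
    stop_config("missingness", "entries must be in [0, 1)")
  }
  for (nm in c("gdp_log_sd", "lcn3_sd", "serving_sd_g_day")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0) {
      stop_config(nm, "must be a positive number")
    }
  }
  for (nm in c("lcn3_mean_mgday", "serving_mean_g_day", "total_fish_shape",
               "total_fish_mean", "pct_marine_shape1", "pct_marine_shape2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0) {
      stop_config(nm, "must be a positive number")
    }
  }
  structure(list(
    n_countries = as.integer(n_countries),
    seed = as.integer(seed),
    effect = effect,
    fbdg_probs = fbdg_probs,
    missingness = missingness,
    gdp_log_mean = gdp_log_mean,
    gdp_log_sd = gdp_log_sd,
    lcn3_mean_mgday = lcn3_mean_mgday,
    lcn3_sd = lcn3_sd,
    serving_mean_g_day = serving_mean_g_day,
    serving_sd_g_day = serving_sd_g_day,
    total_fish_shape = total_fish_shape,
    total_fish_mean = total_fish_mean,
    pct_marine_shape1 = pct_marine_shape1,
    pct_marine_shape2 = pct_marine_shape2
  ), class = "country_scenario")
}

# Recycle a scalar over `names`, or align a named vector to them (absent
# names default to `default`).
.expand_named <- function(x, names, field, default = 0) {
  if (!is.numeric(x)) stop_config(field, "must be numeric")
  if (length(x) == 1 && is.null(names(x))) {
    out <- rep(as.numeric(x), length(names))
    names(out) <- names
    return(out)
  }
  if (is.null(names(x)) || !all(names(x) %in% names)) {
    stop_config(field, sprintf("must be a scalar or named over {%s}",
                               paste(names, collapse = ", ")))
  }
  out <- rep(default, length(names))
  names(out) <- names
  out[names(x)] <- as.numeric(x)
  out
}

# Quantile of a normal truncated below at zero, evaluated at u in (0, 1).
# Rank-preserving, so copula effects survive the marginal transform.
.qtnorm0 <- function(u, mean, sd) {
  p0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(p0 + u * (1 - p0), mean, sd)
}

#' Generate a synthetic country table
#'
#' Draws `n_countries` country records under a one-factor Gaussian copula:
#' a shared standard-normal latent drives dietary LCn-3, each covariate's
#' latent correlates with it at `2*sin(pi*effect/6)` so that the population
#' Spearman correlation equals the configured `effect`, and marginals are
#' applied by quantile transform. FBDG categories are drawn independently
#' from `fbdg_probs`; the recommended serving size is present only for
#' `rec_with_serving` countries. Missing values, if configured, are injected
#' independently per cell (MCAR) and never in `country_id`.
#'
#' The call is fully deterministic given the configuration (the RNG state is
#' seeded from `config$seed` and restored afterwards).
#'
#' @param config A [country_scenario()] configuration.
#' @return A `data.frame` with one row per country and columns `country_id`,
#'   `lcn3_mg_day`, `fbdg_status` (factor over [fbdg_levels()]),
#'   `recommended_g_day`, `gdp_percap`, `price_rank`, `total_fish`,
#'   `pct_marine`.
#' @export
#' @examples
#' tab <- generate_countries(country_scenario(n_countries = 20, seed = 1))
#' summary(tab$lcn3_mg_day)
generate_countries <- function(config) {
  if (!inherits(config, "country_scenario")) {
    config <- do.call(country_scenario, as.list(config))
  }
  n <- config$n_countries
  withr::local_seed(config$seed)

  z0 <- stats::rnorm(n)                       # latent driving LCn-3
  rho <- 2 * sin(pi * config$effect / 6)      # latent corr giving Spearman = effect
  z_cov <- sapply(.country_covariates, function(v) {
    rho[v] * z0 + sqrt(1 - rho[v]^2) * stats::rnorm(n)
  })

  lcn3 <- .qtnorm0(stats::pnorm(z0), config$lcn3_mean_mgday, config$lcn3_sd)
  serving <- .qtnorm0(stats::pnorm(z_cov[, "recommended_g_day"]),
                      config$serving_mean_g_day, config$serving_sd_g_day)
  gdp <- stats::qlnorm(stats::pnorm(z_cov[, "gdp_percap"]),
                       config$gdp_log_mean, config$gdp_log_sd)
  price_rank <- rank(z_cov[, "price_rank"], ties.method = "first")
  total_fish <- stats::qgamma(stats::pnorm(z_cov[, "total_fish"]),
                              shape = config$total_fish_shape,
                              rate = config$total_fish_shape / config$total_fish_mean)
  pct_marine <- 100 * stats::qbeta(stats::pnorm(z_cov[, "pct_marine"]),
                                   config$pct_marine_shape1, config$pct_marine_shape2)

  fbdg <- factor(sample(fbdg_levels(), n, replace = TRUE, prob = config$fbdg_probs),
                 levels = fbdg_levels())
  serving[fbdg != "rec_with_serving"] <- NA_real_

  out <- data.frame(
    country_id = sprintf("C%04d", seq_len(n)),
    lcn3_mg_day = lcn3,
    fbdg_status = fbdg,
    recommended_g_day = serving,
    gdp_percap = gdp,
    price_rank = as.integer(price_rank),
    total_fish = total_fish,
    pct_marine = pct_marine,
    stringsAsFactors = FALSE
  )

  for (col in .maskable_columns) {
    p <- config$missingness[col]
    if (p > 0) {
      out[[col]][stats::runif(n) < p] <- NA
    }
  }
  out
}
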