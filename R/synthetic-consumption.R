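# Synthetic species-consumption generator: a skewed (Zipf-like) consumption
# profile in which the dominant species is low in EPA+DHA while at least one
# minority species is rich in it — the shrimp/salmon pattern of national
# consumption tables.

#' Configure a synthetic species-consumption scenario
#'
#' @param n_species Number of listed species (>= 2).
#' @param seed Integer seed.
#' @param top_coverage Fraction in `(0, 1]` of total national consumption
#'   covered by the listed species (default 0.748, the coverage of a top-ten
#'   list in published US consumption data).
#' @param dominance Positive skew exponent of the Zipf-like consumption-share
#'   profile (`share_i` proportional to `i^-dominance`); larger values
#'   concentrate consumption on the leading species.
#' @param density_range_mg_per_100g Length-2 positive `(low, high)` range of
#'   EPA+DHA densities, mg per 100 g edible portion.
#' @param total_g_week Implied total national seafood consumption in grams
#'   per capita per week (listed species cover `top_coverage` of it);
#'   default 138.9, a published US 2019 weekly average.
#'
#' @return A list of class `consumption_scenario`.
#' @seealso [generate_consumption()]
#' @export
consumption_scenario <- function(n_species = 10L,
                                 seed = 1L,
                                 top_coverage = 0.748,
                                 dominance = 1.0,
                                 density_range_mg_per_100g = c(20, 2000),
                                 total_g_week = 138.9) {
  if (!is.numeric(n_species) || length(n_species) != 1 || is.na(n_species) ||
      n_species < 2 || n_species != floor(n_species)) {
    stop_config("n_species", "must be a single integer >= 2")
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop_config("seed", "must be a single integer")
  }
  if (!is.numeric(top_coverage) || length(top_coverage) != 1 ||
      is.na(top_coverage) || top_coverage <= 0 || top_coverage > 1) {
    stop_config("top_coverage", "must be in (0, 1]")
  }
  if (!is.numeric(dominance) || length(dominance) != 1 || is.na(dominance) ||
      dominance <= 0) {
    stop_config("dominance", "must be > 0")
  }
  dr <- density_range_mg_per_100g
  if (!is.numeric(dr) || length(dr) != 2 || any(is.na(dr)) || any(dr <= 0) ||
      dr[1] >= dr[2]) {
    stop_config("density_range_mg_per_100g", "must be positive (low, high) with low < high")
  }
  if (!is.numeric(total_g_week) || length(total_g_week) != 1 ||
      is.na(total_g_week) || total_g_week <= 0) {
    stop_config("total_g_week", "must be a positive number")
  }
  structure(list(
    n_species = as.integer(n_species),
    seed = as.integer(seed),
    top_coverage = top_coverage,
    dominance = dominance,
    density_range_mg_per_100g = as.numeric(dr),
    total_g_week = total_g_week
  ), class = "consumption_scenario")
}

#' Generate a synthetic species-consumption table
#'
#' Consumption shares follow a Zipf-like profile `i^-dominance`, normalized
#' so the listed species jointly cover `top_coverage` of the implied national
#' total. EPA+DHA densities are drawn uniformly over the configured range,
#' except that the dominant (highest-consumption) species is forced into the
#' lower third of the range and at least one other species into the upper
#' third — emulating national profiles where the most-eaten item (shrimp) is
#' omega-3-poor while a minority item (salmon) is omega-3-rich.
#'
#' @param config A [consumption_scenario()] configuration.
#' @return A `data.frame` with columns `species`, `grams_per_week`,
#'   `epa_dha_mg_per_100g`, ordered by decreasing consumption.
#' @export
#' @examples
#' sp <- generate_consumption(consumption_scenario(n_species = 10, seed = 3))
#' sum(sp$grams_per_week) / 138.9  # listed coverage, 0.748
generate_consumption <- function(config) {
  if (!inherits(config, "consumption_scenario")) {
    config <- do.call(consumption_scenario, as.list(config))
  }
  n <- config$n_species
  withr::local_seed(config$seed)

  w <- seq_len(n)^(-config$dominance)
  w <- w / sum(w)
  grams <- config$total_g_week * config$top_coverage * w

  lo <- config$density_range_mg_per_100g[1]
  hi <- config$density_range_mg_per_100g[2]
  third <- (hi - lo) / 3
  dens <- stats::runif(n, lo, hi)
  dens[1] <- stats::runif(1, lo, lo + third)        # dominant species is LCn-3 poor
  if (!any(dens[-1] >= hi - third)) {               # keep one LCn-3-rich species
    dens[n] <- stats::runif(1, hi - third, hi)
  }

  data.frame(
    species = sprintf("species_%02d", seq_len(n)),
    grams_per_week = grams,
    epa_dha_mg_per_100g = dens,
    stringsAsFactors = FALSE
  )
}
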