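# Dietary EPA+DHA allocation from a species-consumption profile: per-species
# contributions, weighted-mean imputation of unlisted consumption, and
# proportional extension of the whole profile to a recommended seafood total.

#' Consumption-weighted mean EPA+DHA density
#'
#' `sum(grams_i * density_i) / sum(grams_i)` over the listed species — the
#' density imputed to the unlisted residual share of consumption.
#'
#' @param items Species `data.frame` with `grams_per_week` and
#'   `epa_dha_mg_per_100g` (see [generate_consumption()] or
#'   [read_species_table()]).
#' @return Weighted mean density in mg per 100 g.
#' @export
#' @examples
#' toy <- data.frame(species = c("a", "b"), grams_per_week = c(150, 50),
#'                   epa_dha_mg_per_100g = c(100, 1000))
#' weighted_mean_density(toy)  # 325
weighted_mean_density <- function(items) {
  .check_species(items)
  g <- items$grams_per_week
  if (sum(g) <= 0) stop_insufficient("total listed consumption is zero")
  sum(g * items$epa_dha_mg_per_100g) / sum(g)
}

.check_species <- function(items) {
  for (v in c("species", "grams_per_week", "epa_dha_mg_per_100g")) {
    if (!v %in% names(items)) stop_schema(sprintf("missing column '%s'", v))
  }
  if (anyDuplicated(items$species)) stop_schema("species names must be unique")
  if (any(is.na(items$grams_per_week)) || any(items$grams_per_week < 0) ||
      any(is.na(items$epa_dha_mg_per_100g)) || any(items$epa_dha_mg_per_100g < 0)) {
    stop_schema("grams_per_week and epa_dha_mg_per_100g must be nonnegative")
  }
  invisible(items)
}

#' Allocate dietary EPA+DHA across a consumption profile
#'
#' The listed species are assumed to cover `coverage` of total national
#' seafood consumption, so the implied total is `sum(grams)/coverage` and the
#' residual (unlisted) category weighs `total * (1 - coverage)` grams at the
#' consumption-weighted mean density of the listed species. Each category's
#' EPA+DHA contribution is `(grams_per_week / 7) * (density / 100)` mg/day.
#'
#' @param items Species `data.frame` (columns `species`, `grams_per_week`,
#'   `epa_dha_mg_per_100g`).
#' @param coverage Fraction in `(0, 1]` of total consumption covered by the
#'   listed species; with `coverage = 1` the residual is empty.
#' @param target_g_week Optional recommended total (g/week); when given, the
#'   returned summary carries the rescaled scenario in its `$scaled` field
#'   (see [scale_to_recommendation()]).
#' @param scale_listed_only When rescaling, scale only the listed species to
#'   make up the target (the residual kept fixed) instead of the whole mix.
#'   Default `FALSE`: proportional scaling of listed + residual, which keeps
#'   every share unchanged.
#' @return An object of class `diet_summary`: list with `per_species`
#'   (data.frame of grams, density, `lcn3_mg_day`, `share_consumption`,
#'   `share_lcn3`), `residual` (one-row data.frame, zero grams when
#'   `coverage = 1`), `total_grams_per_week`, `total_lcn3_mg_day`, `coverage`
#'   and optionally `scaled`.
#' @export
#' @examples
#' toy <- data.frame(species = c("a", "b"), grams_per_week = c(150, 50),
#'                   epa_dha_mg_per_100g = c(100, 1000))
#' allocate_diet(toy, coverage = 1)
allocate_diet <- function(items, coverage = 1, target_g_week = NULL,
                          scale_listed_only = FALSE) {
  .check_species(items)
  if (!is.numeric(coverage) || length(coverage) != 1 || is.na(coverage) ||
      coverage <= 0 || coverage > 1) {
    stop_config("coverage", "must be in (0, 1]")
  }
  listed_total <- sum(items$grams_per_week)
  if (listed_total <= 0) stop_insufficient("total listed consumption is zero")
  total <- listed_total / coverage
  residual_g <- total - listed_total
  residual_density <- weighted_mean_density(items)

  lcn3 <- (items$grams_per_week / 7) * (items$epa_dha_mg_per_100g / 100)
  residual_lcn3 <- (residual_g / 7) * (residual_density / 100)
  total_lcn3 <- sum(lcn3) + residual_lcn3

  per_species <- data.frame(
    species = items$species,
    grams_per_week = items$grams_per_week,
    epa_dha_mg_per_100g = items$epa_dha_mg_per_100g,
    lcn3_mg_day = lcn3,
    share_consumption = items$grams_per_week / total,
    share_lcn3 = lcn3 / total_lcn3,
    stringsAsFactors = FALSE
  )
  residual <- data.frame(
    species = "(unlisted)",
    grams_per_week = residual_g,
    epa_dha_mg_per_100g = residual_density,
    lcn3_mg_day = residual_lcn3,
    share_consumption = residual_g / total,
    share_lcn3 = residual_lcn3 / total_lcn3,
    stringsAsFactors = FALSE
  )
  out <- structure(list(
    per_species = per_species,
    residual = residual,
    total_grams_per_week = total,
    total_lcn3_mg_day = total_lcn3,
    coverage = coverage
  ), class = "diet_summary")
  if (!is.null(target_g_week)) {
    out$scaled <- scale_to_recommendation(out, target_g_week,
                                          scale_listed_only = scale_listed_only)
  }
  out
}

#' Rescale a diet summary to a recommended seafood total
#'
#' Default behaviour multiplies every category's grams (listed species and
#' residual alike) by `target / total`, holding densities fixed — so total
#' EPA+DHA scales by exactly the same factor and every consumption and
#' EPA+DHA share is unchanged. With `scale_listed_only = TRUE` the residual's
#' grams are held fixed and only the listed species are scaled to close the
#' gap to the target.
#'
#' @param summary A [allocate_diet()] result.
#' @param target_g_week Positive recommended total, g/week (e.g. 226.7 for
#'   the 8 oz/week guideline).
#' @param scale_listed_only See [allocate_diet()].
#' @return A new `diet_summary` at the target total.
#' @export
scale_to_recommendation <- function(summary, target_g_week,
                                    scale_listed_only = FALSE) {
  stopifnot(inherits(summary, "diet_summary"))
  if (!is.numeric(target_g_week) || length(target_g_week) != 1 ||
      is.na(target_g_week) || target_g_week <= 0) {
    stop_config("target_g_week", "must be a positive number")
  }
  if (summary$total_grams_per_week <= 0) {
    stop_insufficient("summary total consumption is zero")
  }
  items <- summary$per_species[c("species", "grams_per_week", "epa_dha_mg_per_100g")]
  if (scale_listed_only) {
    listed_target <- target_g_week - summary$residual$grams_per_week
    if (listed_target <= 0) {
      stop_config("target_g_week", "must exceed the fixed residual consumption")
    }
    k <- listed_target / sum(items$grams_per_week)
    items$grams_per_week <- items$grams_per_week * k
    # residual grams fixed: reconstruct with the implied coverage
    allocate_diet(items, coverage = listed_target / target_g_week)
  } else {
    k <- target_g_week / summary$total_grams_per_week
    items$grams_per_week <- items$grams_per_week * k
    allocate_diet(items, coverage = summary$coverage)
  }
}

#' @export
print.diet_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Dietary EPA+DHA summary: %.1f g/week total seafood, %.1f mg/day EPA+DHA\n",
              x$total_grams_per_week, x$total_lcn3_mg_day))
  df <- rbind(x$per_species, x$residual)
  df$share_consumption <- round(100 * df$share_consumption, 1)
  df$share_lcn3 <- round(100 * df$share_lcn3, 1)
  names(df)[names(df) == "share_consumption"] <- "consumption_pct"
  names(df)[names(df) == "share_lcn3"] <- "lcn3_pct"
  print(df, digits = digits, row.names = FALSE)
  if (!is.null(x$scaled)) {
    cat("\nAt recommended intake:\n")
    print(x$scaled, digits = digits)
  }
  invisible(x)
}

#' Convert seafood-intake quantities between units
#'
#' Supported units: `"oz/week"`, `"g/week"`, `"g/day"`. One ounce is
#' 28.3495 g in `"standard"` mode; `"rounded_8oz"` mode uses the rounded
#' guideline constant 8 oz = 226.7 g (i.e. 28.3375 g/oz), the convention of
#' published serving-size tables. A week has 7 days. Values are returned at
#' full precision; round only at presentation (226.7 g/week is 32.3857...
#' g/day, presented as 32.4).
#'
#' @param x Numeric quantity (vectorized).
#' @param from,to Units among `"oz/week"`, `"g/week"`, `"g/day"`.
#' @param constants `"standard"` or `"rounded_8oz"`.
#' @return Converted numeric quantity.
#' @export
#' @examples
#' convert_intake(8, "oz/week", "g/week")                       # 226.796
#' round(convert_intake(226.7, "g/week", "g/day"), 1)           # 32.4
convert_intake <- function(x, from, to, constants = c("standard", "rounded_8oz")) {
  constants <- match.arg(constants)
  oz_g <- if (constants == "standard") 28.3495 else 226.7 / 8
  units <- c("oz/week", "g/week", "g/day")
  if (!from %in% units) stop_config("from", sprintf("unknown unit '%s'", from))
  if (!to %in% units) stop_config("to", sprintf("unknown unit '%s'", to))
  g_week <- switch(from,
    "oz/week" = x * oz_g,
    "g/week"  = x,
    "g/day"   = x * 7
  )
  switch(to,
    "oz/week" = g_week / oz_g,
    "g/week"  = g_week,
    "g/day"   = g_week / 7
  )
}
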