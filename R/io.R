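# CSV readers/writers for the two tabular inputs, and the combined report
# renderer. CSV is the sole interchange format: UTF-8, comma-separated,
# header row mandatory, empty cells = missing.

.country_columns <- c("country_id", "lcn3_mg_day", "fbdg_status",
                      "recommended_g_day", "gdp_percap", "price_rank",
                      "total_fish", "pct_marine")
.species_columns <- c("species", "grams_per_week", "epa_dha_mg_per_100g")

#' Read a country-level table from CSV
#'
#' Expects the documented header (`country_id`, `lcn3_mg_day`,
#' `fbdg_status`, `recommended_g_day`, `gdp_percap`, `price_rank`,
#' `total_fish`, `pct_marine`); empty cells are missing. Malformed numeric
#' cells, invalid FBDG categories, out-of-range `pct_marine` and duplicate
#' country ids are rejected with the offending row numbers.
#'
#' @param path CSV file path.
#' @return Typed country `data.frame`; `fbdg_status` is a factor over
#'   [fbdg_levels()].
#' @export
read_country_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), check.names = FALSE)
  missing_cols <- setdiff(.country_columns, names(df))
  if (length(missing_cols) > 0) {
    stop_schema(sprintf("missing column(s) %s; expected headers: %s",
                        paste(sQuote(missing_cols), collapse = ", "),
                        paste(.country_columns, collapse = ", ")))
  }
  df$country_id <- as.character(df$country_id)
  if (any(is.na(df$country_id))) {
    stop_schema(sprintf("country_id missing in row(s) %s",
                        paste(which(is.na(df$country_id)), collapse = ", ")))
  }
  if (anyDuplicated(df$country_id)) {
    stop_schema(sprintf("duplicate country_id in row(s) %s",
                        paste(which(duplicated(df$country_id)), collapse = ", ")))
  }
  num_cols <- c("lcn3_mg_day", "recommended_g_day", "gdp_percap",
                "price_rank", "total_fish", "pct_marine")
  for (v in num_cols) {
    df[[v]] <- .coerce_numeric(df[[v]], v)
  }
  bad_status <- !is.na(df$fbdg_status) & !(df$fbdg_status %in% fbdg_levels())
  if (any(bad_status)) {
    stop_schema(sprintf("invalid fbdg_status in row(s) %s; allowed: %s",
                        paste(which(bad_status), collapse = ", "),
                        paste(fbdg_levels(), collapse = ", ")))
  }
  df$fbdg_status <- factor(df$fbdg_status, levels = fbdg_levels())
  bad_pct <- !is.na(df$pct_marine) & (df$pct_marine < 0 | df$pct_marine > 100)
  if (any(bad_pct)) {
    stop_schema(sprintf("pct_marine outside [0, 100] in row(s) %s",
                        paste(which(bad_pct), collapse = ", ")))
  }
  neg <- !is.na(df$lcn3_mg_day) & df$lcn3_mg_day < 0
  if (any(neg)) {
    stop_schema(sprintf("negative lcn3_mg_day in row(s) %s",
                        paste(which(neg), collapse = ", ")))
  }
  df$price_rank <- ifelse(is.na(df$price_rank), NA_integer_,
                          as.integer(df$price_rank))
  df[.country_columns]
}

.coerce_numeric <- function(col, name) {
  if (is.numeric(col)) return(as.numeric(col))
  raw <- as.character(col)
  num <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & is.na(num))
  if (length(bad) > 0) {
    stop_schema(sprintf("malformed numeric value for '%s' in row(s) %s",
                        name, paste(bad, collapse = ", ")))
  }
  num
}

#' Write a country-level table to CSV
#'
#' @param records Country `data.frame`.
#' @param path Output path.
#' @export
write_country_table <- function(records, path) {
  out <- records[.country_columns]
  out$fbdg_status <- as.character(out$fbdg_status)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a species-consumption table from CSV
#'
#' Columns: `species`, `grams_per_week`, `epa_dha_mg_per_100g`. Quantities
#' must be nonnegative and species names unique.
#'
#' @param path CSV file path.
#' @return Species `data.frame`.
#' @export
read_species_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), check.names = FALSE)
  missing_cols <- setdiff(.species_columns, names(df))
  if (length(missing_cols) > 0) {
    stop_schema(sprintf("missing column(s) %s; expected headers: %s",
                        paste(sQuote(missing_cols), collapse = ", "),
                        paste(.species_columns, collapse = ", ")))
  }
  df$species <- as.character(df$species)
  for (v in c("grams_per_week", "epa_dha_mg_per_100g")) {
    df[[v]] <- .coerce_numeric(df[[v]], v)
    bad <- which(is.na(df[[v]]) | df[[v]] < 0)
    if (length(bad) > 0) {
      stop_schema(sprintf("'%s' must be nonnegative and present; bad row(s) %s",
                          v, paste(bad, collapse = ", ")))
    }
  }
  if (anyDuplicated(df$species)) {
    stop_schema(sprintf("duplicate species in row(s) %s",
                        paste(which(duplicated(df$species)), collapse = ", ")))
  }
  df[.species_columns]
}

#' Write a species-consumption table to CSV
#'
#' @param items Species `data.frame`.
#' @param path Output path.
#' @export
write_species_table <- function(items, path) {
  utils::write.csv(items[.species_columns], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Render a combined analysis report
#'
#' Assembles whichever results are supplied — a [run_family()] comparison
#' family, [attribute_index()] scores with their [anova_by_group()] summary,
#' and an [allocate_diet()] summary — into a deterministic machine-readable
#' structure (written as JSON when `path_json` is given) and a human-readable
#' text rendering with the quadrant count matrices laid out in the
#' conventional above/below grid (written when `path_text` is given).
#'
#' @param associations Optional `quadrant_family`.
#' @param index_scores Optional `index_scores` data frame.
#' @param anova Optional `index_anova`.
#' @param diet Optional `diet_summary`.
#' @param path_json,path_text Optional output paths.
#' @return Invisibly, a list with `report` (the structure serialized to
#'   JSON), `json` (the JSON string) and `text` (character vector of lines).
#' @export
render_report <- function(associations = NULL, index_scores = NULL,
                          anova = NULL, diet = NULL,
                          path_json = NULL, path_text = NULL) {
  if (is.null(associations) && is.null(index_scores) && is.null(anova) &&
      is.null(diet)) {
    stop_config("results", "at least one result must be supplied")
  }
  report <- list()
  text <- character(0)

  if (!is.null(associations)) {
    stopifnot(inherits(associations, "quadrant_family"))
    report$associations <- list(
      family_alpha = attr(associations, "family_alpha"),
      m = attr(associations, "m"),
      alpha_protected = attr(associations, "alpha_protected"),
      comparisons = lapply(unname(associations), function(r) {
        list(x = r$table$x_name, y = r$table$y_name, n = r$table$n,
             counts = list(bb = r$table$bb, ba = r$table$ba,
                           ab = r$table$ab, aa = r$table$aa),
             chi2 = r$chi2, p_value = r$p_value, direction = r$direction,
             significant = r$significant)
      })
    )
    text <- c(text,
              sprintf("Median-quadrant associations (%d comparisons, protected alpha %.4g [%.3f])",
                      attr(associations, "m"),
                      attr(associations, "alpha_protected"),
                      round(attr(associations, "alpha_protected"), 3)),
              "")
    for (r in associations) {
      text <- c(text, .text_quadrant(r), "")
    }
  }

  if (!is.null(index_scores)) {
    tab <- table(factor(index_scores$score, levels = 0:4),
                 index_scores$fbdg_group)
    report$index <- list(
      n_scored = nrow(index_scores),
      excluded = as.character(attr(index_scores, "excluded")),
      histogram = lapply(stats::setNames(colnames(tab), colnames(tab)),
                         function(g) as.integer(tab[, g]))
    )
    text <- c(text, "Positive-attributes index (rows: score 0-4, columns: FBDG group)",
              utils::capture.output(print(tab)), "")
  }

  if (!is.null(anova)) {
    stopifnot(inherits(anova, "index_anova"))
    report$anova <- list(
      f_stat = anova$f_stat, df_between = anova$df_between,
      df_within = anova$df_within, p_value = anova$p_value,
      group_means = anova$group_means, group_ns = anova$group_ns
    )
    text <- c(text,
              sprintf("One-way ANOVA of index score by FBDG group: F(%d, %d) = %.4g, p = %.4g",
                      anova$df_between, anova$df_within, anova$f_stat,
                      anova$p_value), "")
  }

  if (!is.null(diet)) {
    stopifnot(inherits(diet, "diet_summary"))
    report$diet <- .diet_report(diet)
    text <- c(text, "Dietary EPA+DHA allocation (observed consumption):",
              utils::capture.output(print(diet)))
  }

  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = 10, na = "null",
                           pretty = TRUE)
  if (!is.null(path_json)) writeLines(json, path_json)
  if (!is.null(path_text)) writeLines(text, path_text)
  invisible(list(report = report, json = json, text = text))
}

.diet_report <- function(diet) {
  out <- list(
    total_grams_per_week = diet$total_grams_per_week,
    total_lcn3_mg_day = diet$total_lcn3_mg_day,
    coverage = diet$coverage,
    per_species = diet$per_species,
    residual = diet$residual
  )
  if (!is.null(diet$scaled)) out$scaled <- .diet_report(diet$scaled)
  out
}

.text_quadrant <- function(r) {
  t <- r$table
  c(sprintf("%s vs %s (n = %d)", t$x_name, t$y_name, t$n),
    sprintf("              %s Below  %s Above", t$y_name, t$y_name),
    sprintf("  %s Above  %6d  %6d", t$x_name, t$ab, t$aa),
    sprintf("  %s Below  %6d  %6d", t$x_name, t$bb, t$ba),
    sprintf("  chi2 = %.4f, p = %.4g, direction = %s, %s",
            r$chi2, r$p_value, r$direction,
            if (r$significant) "significant" else "not significant"))
}
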