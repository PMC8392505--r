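# Four-point "positive attributes" country index and its comparison across
# FBDG categories. Each attribute marks a condition associated with higher
# dietary LCn-3: GDP above the median, ranked fish price below the median
# (price associates negatively, so it is inverted), total fish supply above
# the median, and percent marine fish above the median.

.index_vars <- c("gdp_percap", "price_rank", "total_fish", "pct_marine")

#' Compute the four-point positive-attributes index
#'
#' Scores each country 0-4 by counting strict median comparisons over the
#' complete-case set (countries with all four variables present): GDP above
#' its median, price rank below its median, total fish above its median,
#' percent marine above its median. Medians are computed on the complete-case
#' set itself (switchable to per-variable medians over all non-missing
#' countries with `medians = "per_variable"`). Countries at a median earn no
#' point for that attribute; countries missing any variable are excluded and
#' listed in the `excluded` attribute.
#'
#' @param records Country `data.frame` with the four index variables and
#'   `country_id`, `fbdg_status`.
#' @param medians `"complete_case"` (default) or `"per_variable"` — the set
#'   over which each attribute's median is taken.
#' @return A `data.frame` of class `index_scores` with columns `country_id`,
#'   the four logical components (`gdp_above`, `price_below`,
#'   `total_fish_above`, `pct_marine_above`), `score` (integer 0-4) and
#'   `fbdg_group`; attribute `excluded` holds the ids of countries dropped
#'   for missing data.
#' @export
#' @examples
#' tab <- generate_countries(country_scenario(n_countries = 30, seed = 2))
#' table(attribute_index(tab)$score)
attribute_index <- function(records, medians = c("complete_case", "per_variable")) {
  medians <- match.arg(medians)
  for (v in c("country_id", .index_vars)) {
    if (!v %in% names(records)) stop_schema(sprintf("missing column '%s'", v))
  }
  cc <- stats::complete.cases(records[.index_vars])
  if (sum(cc) < 2) {
    stop_insufficient("fewer than 2 countries with all four index variables")
  }
  med_set <- if (medians == "complete_case") {
    lapply(records[.index_vars], function(col) col[cc])
  } else {
    lapply(records[.index_vars], function(col) col[!is.na(col)])
  }
  med <- vapply(med_set, stats::median, na.rm = TRUE, FUN.VALUE = 0)

  sub <- records[cc, , drop = FALSE]
  comp <- data.frame(
    gdp_above        = sub$gdp_percap > med[["gdp_percap"]],
    price_below      = sub$price_rank < med[["price_rank"]],   # inverted attribute
    total_fish_above = sub$total_fish > med[["total_fish"]],
    pct_marine_above = sub$pct_marine > med[["pct_marine"]]
  )
  out <- data.frame(
    country_id = sub$country_id,
    comp,
    score = as.integer(rowSums(comp)),
    stringsAsFactors = FALSE
  )
  out$fbdg_group <- if ("fbdg_status" %in% names(sub)) {
    factor(as.character(sub$fbdg_status), levels = fbdg_levels())
  } else {
    factor(rep(NA_character_, nrow(sub)), levels = fbdg_levels())
  }
  structure(out, class = c("index_scores", "data.frame"),
            excluded = records$country_id[!cc], medians = med)
}

#' One-way ANOVA of index scores across FBDG groups
#'
#' Fixed-effects one-way ANOVA of the integer score on the FBDG category
#' (via [stats::oneway.test()] with equal variances, the classical F-test).
#' Groups with zero members are dropped with a warning. A design with all
#' scores in a single group is degenerate and rejected; a design with zero
#' between-group variance returns F = 0, p = 1.
#'
#' @param scores An `index_scores` data frame (or any data frame with
#'   numeric `score` and factor `fbdg_group`).
#' @return A list of class `index_anova` with `f_stat`, `df_between`,
#'   `df_within`, `p_value`, `group_means`, `group_ns`.
#' @export
anova_by_group <- function(scores) {
  if (!all(c("score", "fbdg_group") %in% names(scores))) {
    stop_schema("scores must have columns 'score' and 'fbdg_group'")
  }
  keep <- !is.na(scores$score) & !is.na(scores$fbdg_group)
  score <- as.numeric(scores$score[keep])
  grp <- scores$fbdg_group[keep]
  if (!is.factor(grp)) grp <- factor(grp)
  empty <- levels(grp)[tabulate(grp, nlevels(grp)) == 0]
  if (length(empty) > 0) {
    warning(sprintf("dropping empty group(s): %s", paste(empty, collapse = ", ")))
    grp <- droplevels(grp)
  }
  k <- nlevels(grp)
  if (k < 2) stop_degenerate("all scores fall in a single group")
  ns <- table(grp)
  if (!any(ns >= 2)) stop_degenerate("no group has at least 2 members")

  n <- length(score)
  group_means <- tapply(score, grp, mean)
  grand <- mean(score)
  ssb <- sum(as.numeric(ns) * (group_means - grand)^2)
  sst <- sum((score - grand)^2)
  if (ssb <= 1e-12 * max(sst, 1)) {
    f <- 0
    p <- 1
  } else {
    fit <- stats::oneway.test(score ~ grp, var.equal = TRUE)
    f <- unname(fit$statistic)
    p <- unname(fit$p.value)
  }
  structure(list(
    f_stat = f,
    df_between = k - 1L,
    df_within = n - k,
    p_value = p,
    group_means = as.list(group_means),
    group_ns = as.list(as.integer(ns)) |> stats::setNames(names(ns))
  ), class = "index_anova")
}

#' @export
print.index_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_stat, x$p_value))
  for (g in names(x$group_means)) {
    cat(sprintf("  %-22s n = %3d, mean score = %.3f\n",
                g, x$group_ns[[g]], x$group_means[[g]]))
  }
  invisible(x)
}

#' Histogram of index scores by FBDG group
#'
#' Optional ggplot2 panel plot of the score distribution (0-4) within each
#' FBDG category, mirroring the index-distribution figure style of
#' country-level FBDG analyses.
#'
#' @param scores An `index_scores` data frame.
#' @return A ggplot object.
#' @export
plot_index_by_group <- function(scores) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_index_by_group requires the ggplot2 package")
  }
  df <- as.data.frame(scores)
  df$score_level <- factor(df$score, levels = 0:4)
  ggplot2::ggplot(df, ggplot2::aes(x = score_level)) +
    ggplot2::geom_bar() +
    ggplot2::facet_wrap(~fbdg_group, ncol = 2) +
    ggplot2::labs(x = "positive-attributes score", y = "countries")
}
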