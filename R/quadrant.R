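# Median-quadrant (quadrate) association analysis: dichotomize two
# country-level variables at their medians, tabulate the 2x2 quadrant
# counts, test independence with the uncorrected Pearson chi-square, and
# read the association direction off quadrant concordance.

#' Dichotomize values at their median
#'
#' Labels each value `"Above"` or `"Below"` relative to the median of the
#' non-missing values. Under the default `strict_above` policy a value is
#' `"Above"` iff it is strictly greater than the median (values equal to the
#' median are `"Below"`). Under `exclude_ties`, values equal to the median
#' are dropped (labelled `NA`) and their positions reported in the
#' `ties_dropped` attribute. Missing values are never labelled.
#'
#' @param values Numeric vector; may contain `NA`.
#' @param policy `"strict_above"` (default) or `"exclude_ties"`.
#' @return Character vector of `"Above"`/`"Below"`/`NA` with attributes
#'   `median` (the split point) and `ties_dropped` (integer positions
#'   dropped under `exclude_ties`).
#' @export
#' @examples
#' dichotomize(c(1, 2, 3, 4, 5))       # B B B A A
#' dichotomize(c(2, 4, 6, 8))          # median 5: B B A A
dichotomize <- function(values, policy = c("strict_above", "exclude_ties")) {
  policy <- match.arg(policy)
  if (!is.numeric(values)) stop_config("values", "must be numeric")
  ok <- !is.na(values)
  if (sum(ok) < 2) {
    stop_insufficient("dichotomize needs at least 2 non-missing values")
  }
  med <- stats::median(values[ok])
  lab <- ifelse(values > med, "Above", "Below")
  lab[!ok] <- NA_character_
  ties <- integer(0)
  if (policy == "exclude_ties") {
    ties <- which(ok & values == med)
    lab[ties] <- NA_character_
  }
  structure(lab, median = med, ties_dropped = ties)
}

#' Construct a 2x2 quadrant table from counts
#'
#' Counts are named by quadrant: the first letter is the x-variable's side of
#' its median (`b`elow / `a`bove), the second the y-variable's. So `ba` is
#' the count of observations below the x median and above the y median.
#'
#' @param bb,ba,ab,aa Nonnegative integer quadrant counts.
#' @param x_name,y_name Variable names, for reporting.
#' @return An object of class `quadrant_table`.
#' @seealso [tabulate_quadrants()] to build one from labels.
#' @export
#' @examples
#' quadrant_table(19, 15, 5, 26, "recommended_g_day", "lcn3_mg_day")
quadrant_table <- function(bb, ba, ab, aa, x_name = "x", y_name = "y") {
  counts <- c(bb = bb, ba = ba, ab = ab, aa = aa)
  if (!is.numeric(counts) || any(is.na(counts)) || any(counts < 0) ||
      any(counts != floor(counts))) {
    stop_config("counts", "must be nonnegative integers")
  }
  structure(list(
    bb = as.integer(bb), ba = as.integer(ba),
    ab = as.integer(ab), aa = as.integer(aa),
    x_name = x_name, y_name = y_name,
    n = as.integer(bb + ba + ab + aa)
  ), class = "quadrant_table")
}

#' Tabulate quadrant counts from Above/Below labels
#'
#' Pairs with a missing label on either side are dropped (pairwise-complete);
#' `n` is the number of complete pairs.
#'
#' @param x_labels,y_labels Aligned character vectors of `"Above"`/`"Below"`/
#'   `NA`, e.g. from [dichotomize()].
#' @param x_name,y_name Variable names, for reporting.
#' @return A [quadrant_table()].
#' @export
tabulate_quadrants <- function(x_labels, y_labels, x_name = "x", y_name = "y") {
  if (length(x_labels) != length(y_labels)) {
    stop_config("labels", "must have equal length (aligned by country)")
  }
  keep <- !is.na(x_labels) & !is.na(y_labels)
  if (!any(keep)) stop_insufficient("no complete (x, y) label pairs")
  x <- x_labels[keep]
  y <- y_labels[keep]
  quadrant_table(
    bb = sum(x == "Below" & y == "Below"),
    ba = sum(x == "Below" & y == "Above"),
    ab = sum(x == "Above" & y == "Below"),
    aa = sum(x == "Above" & y == "Above"),
    x_name = x_name, y_name = y_name
  )
}

#' @export
print.quadrant_table <- function(x, ...) {
  cat(sprintf("Quadrant table: %s (x) vs %s (y), n = %d\n",
              x$x_name, x$y_name, x$n))
  m <- matrix(c(x$ab, x$aa, x$bb, x$ba), nrow = 2, byrow = TRUE,
              dimnames = list(c("x Above", "x Below"),
                              c("y Below", "y Above")))
  print(m)
  invisible(x)
}

#' Uncorrected Pearson chi-square for a quadrant table
#'
#' Computes the closed-form Pearson statistic for a 2x2 table,
#' `n (bb*aa - ba*ab)^2 / ((bb+ba)(ab+aa)(bb+ab)(ba+aa))`, with 1 degree of
#' freedom and no continuity correction (the uncorrected statistic is the
#' one that reproduces published median-quadrant values). The p-value is the
#' chi-square(1) upper tail. A table with any zero row or column margin is
#' degenerate: the statistic is defined as 0 with p = 1 and a warning.
#'
#' @param table A [quadrant_table()].
#' @return A list with elements `chi2` and `p_value`.
#' @export
#' @examples
#' pearson_chi2(quadrant_table(19, 15, 5, 26))  # chi2 ~ 11.0029
pearson_chi2 <- function(table) {
  stopifnot(inherits(table, "quadrant_table"))
  if (table$n < 1) stop_insufficient("empty quadrant table")
  r1 <- table$bb + table$ba   # x Below margin
  r2 <- table$ab + table$aa   # x Above margin
  c1 <- table$bb + table$ab   # y Below margin
  c2 <- table$ba + table$aa   # y Above margin
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    warn_degenerate(sprintf(
      "quadrant table %s vs %s has a zero margin; chi-square undefined, reported as 0",
      table$x_name, table$y_name))
    return(list(chi2 = 0, p_value = 1))
  }
  det <- as.numeric(table$bb) * table$aa - as.numeric(table$ba) * table$ab
  chi2 <- table$n * det^2 / (as.numeric(r1) * r2 * c1 * c2)
  list(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Association direction from quadrant concordance
#'
#' `"positive"` when the concordant quadrants (below-below plus above-above)
#' hold a majority of observations, `"negative"` when the discordant
#' quadrants do, `"none"` on a tie.
#'
#' @param table A [quadrant_table()].
#' @return One of `"positive"`, `"negative"`, `"none"`.
#' @export
#' @examples
#' association_direction(quadrant_table(28, 45, 44, 29))  # "negative"
association_direction <- function(table) {
  stopifnot(inherits(table, "quadrant_table"))
  if (table$n < 1) stop_insufficient("empty quadrant table")
  conc <- table$bb + table$aa
  disc <- table$ba + table$ab
  if (conc > disc) "positive" else if (conc < disc) "negative" else "none"
}

#' Full quadrant association test for one variable pair
#'
#' Convenience wrapper: restrict to pairwise-complete observations, compute
#' each variable's median on that subset, dichotomize, tabulate, run the
#' uncorrected chi-square and report direction and a protected-alpha verdict.
#'
#' @param x,y Aligned numeric vectors.
#' @param x_name,y_name Variable names.
#' @param tie_policy Passed to [dichotomize()].
#' @param family_alpha Family-wise alpha.
#' @param m Number of comparisons in the family; the per-comparison
#'   protected threshold is `family_alpha / m`.
#' @return An object of class `association_result`: a list with `table`
#'   ([quadrant_table()]), `chi2`, `p_value`, `direction`, `alpha_protected`,
#'   `significant`.
#' @export
quadrant_association <- function(x, y, x_name = "x", y_name = "y",
                                 tie_policy = "strict_above",
                                 family_alpha = 0.05, m = 1L) {
  if (length(x) != length(y)) stop_config("x, y", "must have equal length")
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < 2) stop_insufficient("fewer than 2 pairwise-complete observations")
  xl <- dichotomize(x[keep], policy = tie_policy)
  yl <- dichotomize(y[keep], policy = tie_policy)
  .association_from_labels(xl, yl, x_name, y_name, family_alpha, m)
}

.association_from_labels <- function(x_labels, y_labels, x_name, y_name,
                                     family_alpha, m) {
  tab <- tabulate_quadrants(x_labels, y_labels, x_name, y_name)
  test <- pearson_chi2(tab)
  alpha_protected <- family_alpha / m
  structure(list(
    table = tab,
    chi2 = test$chi2,
    p_value = test$p_value,
    direction = association_direction(tab),
    alpha_protected = alpha_protected,
    significant = test$p_value < alpha_protected
  ), class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("chi2 = %.4f, p = %.4g, direction = %s; %s at protected alpha %.4g\n",
              x$chi2, x$p_value, x$direction,
              if (x$significant) "significant" else "not significant",
              x$alpha_protected))
  invisible(x)
}

#' Default family of quadrant comparisons
#'
#' The six comparisons of dietary LCn-3 against its candidate country-level
#' drivers: recommended seafood serving size, FBDG seafood-recommendation
#' presence, per-capita GDP, ranked fish price, total fish supply, and
#' percent of fish supply of marine origin.
#'
#' @return List of length-2 character vectors `(x_name, y_name)`.
#' @export
default_pairs <- function() {
  lapply(c("recommended_g_day", "fbdg_status", "gdp_percap",
           "price_rank", "total_fish", "pct_marine"),
         function(v) c(v, "lcn3_mg_day"))
}

#' Run a Bonferroni-protected family of quadrant comparisons
#'
#' For each `(x, y)` pair: restrict to the pair's pairwise-complete subset,
#' compute medians there, dichotomize both variables, tabulate the quadrant
#' counts and run the uncorrected chi-square. The per-comparison protected
#' threshold is `family_alpha` divided by the number of pairs (0.05/6 =
#' 0.00833 for the default six-comparison family, conventionally rounded to
#' 0.008 in reports).
#'
#' `fbdg_status` used as an x-variable is dichotomized by presence of any
#' seafood recommendation: `Above` for the categories in `fbdg_above`,
#' `Below` otherwise (by default both "no FBDG" and "FBDG without a seafood
#' recommendation" count as Below).
#'
#' @param records Country `data.frame` (see [generate_countries()] or
#'   [read_country_table()]).
#' @param pairs List of length-2 character vectors `(x_name, y_name)`;
#'   default [default_pairs()].
#' @param family_alpha Family-wise alpha, default 0.05.
#' @param tie_policy Passed to [dichotomize()].
#' @param fbdg_above FBDG categories labelled `Above`.
#' @return An object of class `quadrant_family`: a list of
#'   `association_result`s (named `x_name~y_name`) with attributes
#'   `family_alpha`, `m`, `alpha_protected`. `as.data.frame()` gives a
#'   one-row-per-comparison summary.
#' @export
#' @examples
#' tab <- generate_countries(country_scenario(seed = 1))
#' fam <- run_family(tab)
#' as.data.frame(fam)
run_family <- function(records, pairs = default_pairs(), family_alpha = 0.05,
                       tie_policy = "strict_above",
                       fbdg_above = fbdg_recommendation_levels()) {
  if (is.data.frame(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)), function(i) {
      c(as.character(pairs$x[i]), as.character(pairs$y[i]))
    })
  }
  if (!is.list(pairs) || length(pairs) == 0) {
    stop_config("pairs", "must be a nonempty list of (x_name, y_name) pairs")
  }
  if (!is.numeric(family_alpha) || length(family_alpha) != 1 ||
      is.na(family_alpha) || family_alpha <= 0 || family_alpha >= 1) {
    stop_config("family_alpha", "must be in (0, 1)")
  }
  m <- length(pairs)
  results <- lapply(pairs, function(pr) {
    if (length(pr) != 2) stop_config("pairs", "each pair must name two variables")
    for (v in pr) {
      if (!v %in% names(records)) {
        stop_config("pairs", sprintf("unknown variable '%s'", v))
      }
    }
    xv <- .pair_values(records, pr[1], fbdg_above)
    yv <- .pair_values(records, pr[2], fbdg_above)
    keep <- !is.na(xv$values) & !is.na(yv$values)
    if (sum(keep) < 2) {
      stop_insufficient(sprintf("pair %s vs %s has fewer than 2 complete observations",
                                pr[1], pr[2]))
    }
    xl <- if (xv$categorical) xv$labels[keep] else dichotomize(xv$values[keep], tie_policy)
    yl <- if (yv$categorical) yv$labels[keep] else dichotomize(yv$values[keep], tie_policy)
    .association_from_labels(xl, yl, pr[1], pr[2], family_alpha, m)
  })
  names(results) <- vapply(pairs, function(pr) paste(pr, collapse = "~"), "")
  structure(results, class = "quadrant_family",
            family_alpha = family_alpha, m = m,
            alpha_protected = family_alpha / m)
}

# A variable entering a quadrant comparison: numeric covariates are
# dichotomized at the median downstream; fbdg_status is already binary
# (recommendation present / absent).
.pair_values <- function(records, name, fbdg_above) {
  col <- records[[name]]
  if (name == "fbdg_status" || is.factor(col) || is.character(col)) {
    status <- as.character(col)
    labels <- ifelse(is.na(status), NA_character_,
                     ifelse(status %in% fbdg_above, "Above", "Below"))
    list(values = labels, labels = labels, categorical = TRUE)
  } else {
    list(values = as.numeric(col), labels = NULL, categorical = FALSE)
  }
}

#' @export
as.data.frame.quadrant_family <- function(x, ...) {
  do.call(rbind, lapply(unname(x), function(r) {
    data.frame(
      x = r$table$x_name, y = r$table$y_name, n = r$table$n,
      bb = r$table$bb, ba = r$table$ba, ab = r$table$ab, aa = r$table$aa,
      chi2 = r$chi2, p_value = r$p_value, direction = r$direction,
      alpha_protected = r$alpha_protected, significant = r$significant,
      stringsAsFactors = FALSE
    )
  }))
}

#' @export
print.quadrant_family <- function(x, ...) {
  cat(sprintf("Quadrant association family: %d comparisons, family alpha %.3g, protected alpha %.4g\n",
              attr(x, "m"), attr(x, "family_alpha"), attr(x, "alpha_protected")))
  print(as.data.frame(x))
  invisible(x)
}

#' Published quadrant counts for the six country-level comparisons
#'
#' The 2x2 quadrant count matrices for dietary LCn-3 against each candidate
#' driver, as compiled from published global country-level datasets (up to
#' 166 countries; sample sizes differ per comparison because not every
#' variable is available for every country). Useful as a reference input for
#' the chi-square machinery.
#'
#' @return Named list of [quadrant_table()]s, keyed by the x-variable.
#' @export
#' @examples
#' pearson_chi2(fbdg_quadrant_counts()$recommended_g_day)$chi2  # 11.0029
fbdg_quadrant_counts <- function() {
  list(
    recommended_g_day = quadrant_table(19, 15, 5, 26, "recommended_g_day", "lcn3_mg_day"),
    fbdg_status       = quadrant_table(47, 27, 36, 56, "fbdg_status", "lcn3_mg_day"),
    gdp_percap        = quadrant_table(49, 31, 29, 51, "gdp_percap", "lcn3_mg_day"),
    price_rank        = quadrant_table(28, 45, 44, 29, "price_rank", "lcn3_mg_day"),
    total_fish        = quadrant_table(67, 16, 16, 67, "total_fish", "lcn3_mg_day"),
    pct_marine        = quadrant_table(52, 31, 31, 52, "pct_marine", "lcn3_mg_day")
  )
}
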