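# Median dichotomization, quadrant tabulation, chi-square and the
# Bonferroni-protected comparison family.

test_that("dichotomize labels values against the median", {
  expect_equal(as.character(dichotomize(c(1, 2, 3, 4, 5))),
               c("Below", "Below", "Below", "Above", "Above"))
  expect_equal(as.character(dichotomize(c(1, 1, 1, 1))), rep("Below", 4))
  # even length: median 5 falls between observations
  expect_equal(as.character(dichotomize(c(2, 4, 6, 8))),
               c("Below", "Below", "Above", "Above"))
  expect_equal(attr(dichotomize(c(2, 4, 6, 8)), "median"), 5)
  # missing values are never labelled
  lab <- dichotomize(c(1, NA, 3, 4, 5))
  expect_true(is.na(lab[2]))
  expect_error(dichotomize(c(1, NA, NA)), class = "seaomega_insufficient_data_error")
})

test_that("exclude_ties drops median-valued observations and reports them", {
  lab <- dichotomize(c(1, 2, 3, 4, 5), policy = "exclude_ties")
  expect_true(is.na(lab[3]))
  expect_equal(attr(lab, "ties_dropped"), 3L)
  expect_equal(as.character(lab[c(1, 2, 4, 5)]),
               c("Below", "Below", "Above", "Above"))
})

test_that("quadrant tabulation partitions complete pairs", {
  # reconstruct the published serving-size table from labels
  lb <- labels_for_counts(19, 15, 5, 26)
  tab <- tabulate_quadrants(lb$x, lb$y, "recommended_g_day", "lcn3_mg_day")
  expect_equal(c(tab$bb, tab$ba, tab$ab, tab$aa), c(19, 15, 5, 26))
  expect_equal(tab$n, 65)
  # degenerate layouts
  all_bb <- tabulate_quadrants(rep("Below", 7), rep("Below", 7))
  expect_equal(c(all_bb$bb, all_bb$ba, all_bb$ab, all_bb$aa), c(7, 0, 0, 0))
  one_each <- tabulate_quadrants(c("Below", "Below", "Above", "Above"),
                                 c("Below", "Above", "Below", "Above"))
  expect_equal(c(one_each$bb, one_each$ba, one_each$ab, one_each$aa),
               c(1, 1, 1, 1))
  # pairs with a missing side are dropped
  with_na <- tabulate_quadrants(c("Below", NA, "Above"),
                                c("Below", "Above", NA))
  expect_equal(with_na$n, 1)
  expect_error(tabulate_quadrants(c(NA_character_), c("Above")),
               class = "seaomega_insufficient_data_error")
})

test_that("chi-square reproduces the published quadrant statistics", {
  counts <- fbdg_quadrant_counts()
  expect_equal(pearson_chi2(counts$recommended_g_day)$chi2, 11.0029,
               tolerance = 1e-4)
  expect_equal(pearson_chi2(counts$price_rank)$chi2, 7.015, tolerance = 1e-3)
  # hand evaluation of the closed form on the total-fish counts
  expect_equal(pearson_chi2(counts$total_fish)$chi2,
               166 * (67 * 67 - 16 * 16)^2 / (83 * 83 * 83 * 83),
               tolerance = 1e-12)
  expect_lt(pearson_chi2(counts$recommended_g_day)$p_value, 0.001)
})

test_that("chi-square handles independence and degenerate margins", {
  balanced <- pearson_chi2(quadrant_table(10, 10, 10, 10))
  expect_equal(balanced$chi2, 0)
  expect_equal(balanced$p_value, 1)
  expect_warning(res <- pearson_chi2(quadrant_table(5, 7, 0, 0)),
                 class = "seaomega_degenerate_warning")
  expect_equal(res$chi2, 0)
  expect_equal(res$p_value, 1)
})

test_that("chi-square agrees with the expected-counts oracle and chisq.test", {
  withr::local_seed(42)
  for (i in 1:1000) {
    tab <- random_quadrant_table()
    expect_equal(pearson_chi2(tab)$chi2, oracle_chi2(tab), tolerance = 1e-9)
  }
  # independent library cross-check on a handful of tables
  withr::local_seed(7)
  for (i in 1:20) {
    tab <- random_quadrant_table()
    m <- matrix(c(tab$bb, tab$ba, tab$ab, tab$aa), 2, byrow = TRUE)
    ref <- suppressWarnings(chisq.test(m, correct = FALSE))
    expect_equal(pearson_chi2(tab)$chi2, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(pearson_chi2(tab)$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("association direction follows quadrant concordance", {
  expect_equal(association_direction(quadrant_table(19, 15, 5, 26)), "positive")
  expect_equal(association_direction(quadrant_table(28, 45, 44, 29)), "negative")
  expect_equal(association_direction(quadrant_table(1, 1, 1, 1)), "none")
})

test_that("quadrant analysis is invariant to strictly increasing transforms", {
  withr::local_seed(101)
  tf_names <- names(monotone_transforms)
  for (i in 1:250) {
    x <- rnorm(30)
    y <- rnorm(30)
    base <- quadrant_association(x, y)
    for (nm in tf_names) {
      f <- monotone_transforms[[nm]]
      side <- if (i %% 2 == 0) "x" else "y"
      r <- if (side == "x") quadrant_association(f(x), y) else
                            quadrant_association(x, f(y))
      expect_equal(c(r$table$bb, r$table$ba, r$table$ab, r$table$aa),
                   c(base$table$bb, base$table$ba, base$table$ab, base$table$aa))
      expect_equal(r$chi2, base$chi2, tolerance = 1e-12)
      expect_equal(r$direction, base$direction)
    }
  }
})

test_that("negating one variable preserves chi-square and flips direction", {
  # exact for even samples of distinct values: with odd n the observation at
  # the median is Below both before and after negation under strict_above
  withr::local_seed(202)
  for (i in 1:250) {
    x <- rnorm(24)
    y <- rnorm(24)
    base <- quadrant_association(x, y)
    neg <- quadrant_association(-x, y)
    # x labels swap sides: quadrant counts mirror across the x axis
    expect_equal(c(neg$table$bb, neg$table$ba, neg$table$ab, neg$table$aa),
                 c(base$table$ab, base$table$aa, base$table$bb, base$table$ba))
    expect_equal(neg$chi2, base$chi2, tolerance = 1e-12)
    expect_equal(neg$direction,
                 switch(base$direction, positive = "negative",
                        negative = "positive", none = "none"))
  }
})

test_that("run_family applies the protected alpha and per-pair subsets", {
  tab <- generate_countries(country_scenario(seed = 9))
  fam <- run_family(tab)
  expect_length(fam, 6)
  expect_equal(attr(fam, "alpha_protected"), 0.05 / 6)
  expect_equal(round(attr(fam, "alpha_protected"), 3), 0.008)
  df <- as.data.frame(fam)
  expect_true(all(df$significant == (df$p_value < 0.05 / 6)))
  # serving-size pair only uses countries that report a serving
  expect_equal(df$n[df$x == "recommended_g_day"],
               sum(!is.na(tab$recommended_g_day) & !is.na(tab$lcn3_mg_day)))
  # single-comparison family keeps the family alpha
  one <- run_family(tab, pairs = list(c("gdp_percap", "lcn3_mg_day")))
  expect_equal(attr(one, "alpha_protected"), 0.05)
  expect_error(run_family(tab, pairs = list(c("nope", "lcn3_mg_day"))),
               "nope", class = "seaomega_config_error")
})

test_that("FBDG status splits on presence of any seafood recommendation", {
  records <- data.frame(
    country_id = sprintf("C%02d", 1:8),
    lcn3_mg_day = c(10, 20, 30, 40, 50, 60, 70, 80),
    fbdg_status = factor(c("none", "no_recommendation", "rec_with_serving",
                           "rec_without_serving", "none", "rec_with_serving",
                           "no_recommendation", "rec_without_serving"),
                         levels = fbdg_levels()),
    stringsAsFactors = FALSE
  )
  fam <- run_family(records, pairs = list(c("fbdg_status", "lcn3_mg_day")))
  t <- fam[[1]]$table
  # median lcn3 = 45; Above-x = rec_with_serving/rec_without_serving rows
  expect_equal(t$ab + t$aa, 4)          # four countries with a recommendation
  expect_equal(t$aa, 2)                 # of those, lcn3 60 and 80 are above 45
  expect_equal(c(t$bb, t$ba, t$ab), c(2, 2, 2))
  expect_equal(t$n, 8)
})

test_that("pairwise-complete medians differ from global complete-case medians", {
  # gdp observed on all 6 countries, price on the first 4 only; the gdp
  # median must come from all 6, not from the price-complete subset
  records <- data.frame(
    country_id = sprintf("C%02d", 1:6),
    lcn3_mg_day = c(1, 2, 3, 4, 5, 6),
    fbdg_status = factor(rep("none", 6), levels = fbdg_levels()),
    recommended_g_day = NA_real_,
    gdp_percap = c(10, 20, 30, 40, 1000, 2000),
    price_rank = c(1L, 2L, 3L, 4L, NA, NA),
    total_fish = 1, pct_marine = 50,
    stringsAsFactors = FALSE
  )
  fam <- run_family(records, pairs = list(c("gdp_percap", "lcn3_mg_day"),
                                          c("price_rank", "lcn3_mg_day")))
  df <- as.data.frame(fam)
  expect_equal(df$n, c(6, 4))
  # gdp median 35 over all six -> 40, 1000, 2000 above, paired with lcn3 4,5,6
  expect_equal(df$aa[1], 3)
})
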