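# Independent oracles and small fixture builders used across the suite.

# Brute-force Pearson chi-square via expected counts, sum((O - E)^2 / E).
# Independent of the closed-form implementation in the package.
oracle_chi2 <- function(tab) {
  O <- matrix(c(tab$bb, tab$ba, tab$ab, tab$aa), nrow = 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  sum((O - E)^2 / E)
}

# From-scratch one-way ANOVA F via sums of squares.
oracle_anova_f <- function(score, grp) {
  grp <- droplevels(factor(grp))
  k <- nlevels(grp)
  n <- length(score)
  means <- tapply(score, grp, mean)
  ns <- as.numeric(table(grp))
  grand <- mean(score)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((score - means[as.integer(grp)])^2)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Random 2x2 quadrant table with all margins nonzero.
random_quadrant_table <- function() {
  repeat {
    counts <- sample(0:40, 4, replace = TRUE)
    tab <- quadrant_table(counts[1], counts[2], counts[3], counts[4])
    if (tab$bb + tab$ba > 0 && tab$ab + tab$aa > 0 &&
        tab$bb + tab$ab > 0 && tab$ba + tab$aa > 0) {
      return(tab)
    }
  }
}

# Aligned Above/Below label vectors realizing the given quadrant counts.
labels_for_counts <- function(bb, ba, ab, aa) {
  list(
    x = c(rep("Below", bb + ba), rep("Above", ab + aa)),
    y = c(rep("Below", bb), rep("Above", ba), rep("Below", ab), rep("Above", aa))
  )
}

# Random species-consumption profile (positive grams, positive densities).
random_profile <- function(n_species = 8) {
  data.frame(
    species = sprintf("sp%02d", seq_len(n_species)),
    grams_per_week = stats::runif(n_species, 1, 60),
    epa_dha_mg_per_100g = stats::runif(n_species, 10, 2000),
    stringsAsFactors = FALSE
  )
}

# Strictly increasing transforms for rank-invariance property tests.
monotone_transforms <- list(
  exp = exp,
  cube = function(x) x^3,
  atan = atan,
  affine = function(x) 2.5 * x + 7
)
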