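# Independent oracles used to freeze expected values; deliberately
# naive implementations, kept separate from the package code paths.

# suffix-sum of `pools` along an ordered vector of species ids
oracle_suffix_sums <- function(pools, order) {
  vapply(seq_along(order), function(i) {
    sum(pools[order[i:length(order)]])
  }, numeric(1))
}

BRANCH40 <- c("Ab49", "Ab46", "Ab43", "Ab40")
BRANCH42 <- c("Ab48", "Ab45", "Ab42", "Ab38")

# carbon/nitrogen atom counts per residue (independent typing of the
# standard residue formulas, counts only)
ORACLE_CN <- list(
  A = c(3, 1), R = c(6, 4), N = c(4, 2), D = c(4, 1), C = c(3, 1),
  E = c(5, 1), Q = c(5, 2), G = c(2, 1), H = c(6, 3), I = c(6, 1),
  L = c(6, 1), K = c(6, 2), M = c(5, 1), F = c(9, 1), P = c(5, 1),
  S = c(3, 1), T = c(4, 1), W = c(11, 2), Y = c(9, 1), V = c(5, 1)
)

oracle_cn_counts <- function(sequence) {
  letters <- strsplit(sequence, "")[[1]]
  counts <- Reduce(`+`, ORACLE_CN[letters])
  c(C = counts[1], N = counts[2])  # peptide water adds no C or N
}

# pooled-variance two-sided t-test, textbook formulas
oracle_student_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tstat, p = 2 * pt(-abs(tstat), df = na + nb - 2))
}

# closed-form OLS normal equations
oracle_ols <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

# a complete named coproduct vector built from two branch vectors
full_coproducts <- function(b40, b42) {
  c(stats::setNames(b40, c("AICD50-99", "ITL", "VIV", "IAT")),
    stats::setNames(b42, c("AICD49-99", "VIT", "TVI", "VVIA")))
}

random_pool_vector <- function() {
  stats::setNames(stats::runif(8, -200, 700), c(BRANCH40, BRANCH42))
}
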