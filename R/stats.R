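# Study-level statistics: Fisher's exact test with Bonferroni correction for
# re-entry proportions, Mann-Whitney with Dunn-Bonferroni adjustment for
# count comparisons, Kolmogorov-Smirnov normality screening, and ordinary
# least squares for the perimeter-frequency relationship.

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value by the point-probability convention: the sum of
#' hypergeometric probabilities of all tables (at fixed margins) no more
#' probable than the observed one. This is the convention under which the
#' re-entry contingency of the largest versus smallest colonies, corrected
#' for three comparisons, gives p = .028.
#'
#' @param table 2x2 matrix of non-negative integer counts
#'   (rows: group; columns: outcome yes/no).
#' @return A list with `p` and `degenerate` (TRUE when a margin is zero, in
#'   which case `p = 1`).
#' @export
fisher_exact_two_sided <- function(table) {
  m <- as.matrix(table)
  if (!identical(dim(m), c(2L, 2L)) || any(m < 0) || any(m != round(m))) {
    stop("table must be a 2x2 matrix of non-negative integer counts")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(list(p = 1, degenerate = TRUE))
  }
  list(p = fisher.test(m)$p.value, degenerate = FALSE)
}

#' Bonferroni correction
#'
#' @param p Unadjusted p-value(s).
#' @param m Number of comparisons (>= 1).
#' @return `min(1, m * p)`, elementwise.
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, m * p)
}

#' Pairwise Mann-Whitney tests with Dunn-Bonferroni adjustment
#'
#' Two-sided Mann-Whitney U per group pair — exact when both samples have at
#' most `exact_max` observations and no ties, tie-corrected normal
#' approximation otherwise — with the p-values multiplied by the number of
#' pairs (the Dunn-Bonferroni adjustment for multiple comparisons).
#'
#' @param groups Named list of at least 2 numeric vectors, each with at
#'   least 2 observations.
#' @param exact_max Largest per-group size for the exact null distribution.
#' @return Data frame with `group1`, `group2`, `u`, `p_raw`, `p_adjusted`,
#'   `exact`.
#' @export
mann_whitney_dunn <- function(groups, exact_max = 8L) {
  stopifnot(length(groups) >= 2L)
  if (any(vapply(groups, length, 1L) < 2L)) {
    stop("every group needs at least 2 observations")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  pairs <- utils::combn(length(groups), 2L)
  n_pairs <- ncol(pairs)
  out <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    x <- groups[[i]]; y <- groups[[j]]
    ties <- any(duplicated(c(x, y)))
    use_exact <- length(x) <= exact_max && length(y) <= exact_max && !ties
    wt <- suppressWarnings(
      wilcox.test(x, y, exact = use_exact, correct = !use_exact)
    )
    out[[k]] <- data.frame(group1 = names(groups)[i],
                           group2 = names(groups)[j],
                           u = unname(wt$statistic), p_raw = wt$p.value,
                           exact = use_exact)
  }
  out <- do.call(rbind, out)
  out$p_adjusted <- bonferroni(out$p_raw, n_pairs)
  out[, c("group1", "group2", "u", "p_raw", "p_adjusted", "exact")]
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test against a normal distribution with the sample's own
#' mean and standard deviation. Estimating the parameters from the sample
#' makes the classical KS null distribution conservative (the Lilliefors
#' caveat); the flag is carried in the result.
#'
#' @param sample Numeric vector, at least 5 observations.
#' @return List with `p`, `statistic`, `estimated_parameters = TRUE`
#'   (the caveat flag), and `degenerate` for constant samples (`p = NA`).
#' @export
ks_normality <- function(sample) {
  if (length(sample) < 5L) stop("ks_normality requires at least 5 observations")
  s <- sd(sample)
  if (s == 0) {
    return(list(p = NA_real_, statistic = NA_real_,
                estimated_parameters = TRUE, degenerate = TRUE))
  }
  kt <- suppressWarnings(ks.test(sample, "pnorm", mean(sample), s))
  list(p = kt$p.value, statistic = unname(kt$statistic),
       estimated_parameters = TRUE, degenerate = FALSE)
}

#' Ordinary least-squares regression
#'
#' @param x,y Numeric vectors, `n >= 3`; `x` must not be constant.
#' @return List with `slope`, `intercept`, `r_squared`, `p` (two-sided t-test
#'   on the slope), `n`.
#' @export
linear_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (sd(x) == 0) stop("x is constant: slope undefined")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))   # perfect fits are legitimate input
  list(slope = unname(coef(fit)["x"]),
       intercept = unname(coef(fit)["(Intercept)"]),
       r_squared = sm$r.squared,
       p = sm$coefficients["x", "Pr(>|t|)"],
       n = length(x))
}

#' Reproduce the printed colony-size contingency analysis
#'
#' Runs the Fisher/Bonferroni chain on re-entry counts per colony-size
#' class: each pairwise 2x2 table is tested two-sided and corrected for the
#' three pairwise comparisons.
#'
#' @param reentry Integer vector of re-entry counts per class (largest to
#'   smallest or any fixed order).
#' @param n Integer vector of recordings per class, same order.
#' @param labels Class labels.
#' @return Data frame with one row per pair: counts, `p_raw`, `p_adjusted`.
#' @export
colony_contingency_analysis <- function(reentry = c(6L, 7L, 1L),
                                        n = c(16L, 22L, 25L),
                                        labels = c("9.8", "6.4", "3.5")) {
  stopifnot(length(reentry) == length(n), length(labels) == length(n))
  pairs <- utils::combn(length(n), 2L)
  m <- ncol(pairs)
  out <- vector("list", m)
  for (k in seq_len(m)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    tab <- matrix(c(reentry[i], n[i] - reentry[i],
                    reentry[j], n[j] - reentry[j]), 2L, byrow = TRUE)
    ft <- fisher_exact_two_sided(tab)
    out[[k]] <- data.frame(class1 = labels[i], class2 = labels[j],
                           yes1 = reentry[i], n1 = n[i],
                           yes2 = reentry[j], n2 = n[j],
                           p_raw = ft$p, p_adjusted = bonferroni(ft$p, m))
  }
  do.call(rbind, out)
}
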