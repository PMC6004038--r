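test_that("Fisher p-values match full hypergeometric enumeration", {
  t1 <- matrix(c(6, 10, 1, 24), 2, byrow = TRUE)
  expect_lt(abs(fisher_exact_two_sided(t1)$p - 0.00941), 1e-4)
  expect_equal(fisher_exact_two_sided(t1)$p, fisher_oracle(t1),
               tolerance = 1e-12)
  t2 <- matrix(c(5, 0, 0, 5), 2, byrow = TRUE)
  expect_equal(fisher_exact_two_sided(t2)$p, 2 / choose(10, 5),
               tolerance = 1e-12)
  degen <- fisher_exact_two_sided(matrix(c(0, 10, 0, 10), 2, byrow = TRUE))
  expect_equal(degen$p, 1)
  expect_true(degen$degenerate)
  # exhaustive sweep over small tables
  for (a in 0:6) for (b in 0:(6 - a)) for (cc in 0:(6 - a - b)) {
    for (d in 0:(6 - a - b - cc)) {
      tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
      expect_equal(fisher_exact_two_sided(tab)$p, fisher_oracle(tab),
                   tolerance = 1e-12)
    }
  }
  expect_error(fisher_exact_two_sided(matrix(c(1.5, 1, 1, 1), 2)),
               "integer")
})

test_that("Bonferroni is the clamped multiple and reproduces the printed value", {
  expect_equal(bonferroni(0.00941, 3), 0.02823)
  expect_equal(round(bonferroni(fisher_exact_two_sided(
    matrix(c(6, 10, 1, 24), 2, byrow = TRUE))$p, 3), 3), 0.028)
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(0.01, 1), 0.01)
  # monotone in both arguments
  expect_true(all(diff(bonferroni(c(0.001, 0.01, 0.2), 3)) >= 0))
  expect_lte(bonferroni(0.02, 2), bonferroni(0.02, 5))
})

test_that("Mann-Whitney matches rank-permutation enumeration and Dunn scales", {
  res <- mann_whitney_dunn(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(res$p_raw, 0.1)
  expect_equal(res$u, 0)
  # identical groups are tied at p ~ 1 under the tie-corrected path
  same <- mann_whitney_dunn(list(a = rep(1:3, 3), b = rep(1:3, 3)))
  expect_gt(same$p_raw, 0.95)
  # exact path against the enumeration oracle
  set.seed(14)
  for (rep in 1:8) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- sample(1000, n1); y <- sample(setdiff(1:1000, x), n2)
    p_imp <- mann_whitney_dunn(list(x = x, y = y))$p_raw
    expect_equal(p_imp, mw_oracle(x, y), tolerance = 1e-12)
  }
  # three groups: each pairwise p is tripled
  three <- mann_whitney_dunn(list(a = c(1, 2, 3), b = c(4, 5, 6),
                                  c = c(7, 8, 9)))
  expect_equal(nrow(three), 3L)
  expect_equal(three$p_adjusted, pmin(1, 3 * three$p_raw))
  expect_error(mann_whitney_dunn(list(a = 1, b = c(1, 2))), "at least 2")
})

test_that("KS normality screen keeps size under the null and power off it", {
  set.seed(31)
  normal <- rnorm(10000)
  expect_gt(ks_normality(normal)$p, 0.05)
  uniform <- runif(10000)
  expect_lt(ks_normality(uniform)$p, 1e-6)
  expect_true(ks_normality(normal)$estimated_parameters)
  expect_true(ks_normality(rep(1, 10))$degenerate)
  expect_error(ks_normality(c(1, 2, 3, 4)), "at least 5")
})

test_that("linear regression recovers exact and hand-computed fits", {
  x <- 1:5
  exact <- linear_regression(x, 2 * x)
  expect_equal(exact$slope, 2)
  expect_equal(exact$r_squared, 1)
  hand <- linear_regression(c(1, 2, 3), c(1, 2, 4))
  expect_equal(hand$slope, 1.5)
  expect_equal(hand$r_squared, 27 / 28)
  # null: no slope, tiny R^2
  set.seed(7)
  xn <- rnorm(100); yn <- rnorm(100)
  null <- linear_regression(xn, yn)
  expect_lt(abs(null$slope), 0.3)
  expect_lt(null$r_squared, 0.05)
  # recovery of (a, b) to near machine precision
  fit <- linear_regression(xn, 1.7 - 0.4 * xn)
  expect_equal(fit$intercept, 1.7, tolerance = 1e-10)
  expect_equal(fit$slope, -0.4, tolerance = 1e-10)
  expect_error(linear_regression(rep(1, 5), 1:5), "constant")
})

test_that("the colony contingency chain reproduces the printed analysis", {
  res <- colony_contingency_analysis(reentry = c(6L, 7L, 1L),
                                     n = c(16L, 22L, 25L),
                                     labels = c("9.8", "6.4", "3.5"))
  largest_vs_smallest <- res[res$class1 == "9.8" & res$class2 == "3.5", ]
  expect_equal(round(largest_vs_smallest$p_adjusted, 3), 0.028)
  others <- res[!(res$class1 == "9.8" & res$class2 == "3.5"), ]
  expect_true(all(others$p_adjusted > 0.05))
})
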