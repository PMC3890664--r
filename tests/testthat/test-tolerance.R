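test_that("Howe k factor matches tabulated quantiles and its limits", {
  # independently tabulated chi-square quantile: chi2_{0.05, 31} = 19.281
  k32 <- qnorm(0.975) * sqrt(31 * (1 + 1 / 32) / 19.281)
  expect_equal(howe_k(32), k32, tolerance = 1e-4)
  expect_equal(howe_k(32), 2.5238, tolerance = 1e-4)
  # asymptotically k -> z_{(1+P)/2}
  expect_equal(howe_k(1e7), qnorm(0.975), tolerance = 1e-3)
  # monotone decreasing in n
  expect_true(howe_k(12) > howe_k(32))
  expect_true(howe_k(32) > howe_k(79))
  expect_error(howe_k(1), "integer")
  expect_error(howe_k(10, tolerance_config(side = "one-sided")), "two-sided")
})

test_that("chi-square quantile path agrees with direct numerical inversion", {
  for (n in c(5, 18, 32, 79)) {
    alpha <- 0.05
    inv <- uniroot(function(q) pchisq(q, n - 1) - alpha,
                   c(1e-8, 10 * n), tol = 1e-12)$root
    k_oracle <- qnorm(0.975) * sqrt((n - 1) * (1 + 1 / n) / inv)
    expect_equal(howe_k(n), k_oracle, tolerance = 1e-6)
  }
})

test_that("normal tolerance intervals reproduce verified published bounds", {
  ti <- normal_ti(mean = 56.8, sd = 6.1, n = 32)
  expect_equal(round(ti$lower, 1), 41.4)
  expect_equal(round(ti$upper, 1), 72.2)
  ti2 <- normal_ti(mean = 76.3, sd = 6.5, n = 42)
  expect_equal(round(ti2$lower, 1), 60.5)
  # degenerate: zero dispersion collapses to a point
  ti3 <- normal_ti(mean = 5, sd = 0, n = 10)
  expect_equal(ti3$lower, 5)
  expect_equal(ti3$upper, 5)
})

test_that("Wilson score bounds: closed form, score-inequality oracle, symmetry", {
  expect_equal(wilson_bound(0, 12), 1.6449^2 / (12 + 1.6449^2),
               tolerance = 1e-4)
  expect_equal(wilson_bound(0, 12), 0.1840, tolerance = 2e-4)
  # root-finding oracle: the upper bound solves (phat - p) = -z sqrt(p(1-p)/n)
  z <- qnorm(0.95)
  for (x in c(0, 3, 7)) {
    n <- 12
    oracle <- uniroot(function(p)
      (x / n - p) + z * sqrt(p * (1 - p) / n), c(x / n + 1e-12, 1 - 1e-12),
      tol = 1e-12)$root
    expect_equal(wilson_bound(x, n), oracle, tolerance = 1e-8)
  }
  expect_equal(wilson_bound(12, 12), 1.0)
  # lower(x, n) = 1 - upper(n - x, n)
  for (x in 0:10)
    expect_equal(wilson_bound(x, 10, direction = "lower"),
                 1 - wilson_bound(10 - x, 10), tolerance = 1e-12)
  expect_error(wilson_bound(0, 0), "n must be")
})

test_that("binomial tolerance count bounds match the published small-sample cases", {
  b <- binomial_tolerance_bound(0, 12)
  expect_equal(b$count_bound, 5L)
  expect_equal(b$proportion_bound, 5 / 12, tolerance = 1e-9)
  expect_equal(b$p_bound, 0.1840, tolerance = 2e-4)
  # evidence accumulates: the bound collapses with large observed n
  expect_equal(binomial_tolerance_bound(0, 1e4, m = 12)$count_bound, 0L)
  # lower direction via the (1-P) binomial quantile
  expect_equal(binomial_tolerance_bound(12, 12, direction = "lower")$count_bound,
               7L)
})

test_that("count bounds equal exhaustive CDF enumeration on a config grid", {
  for (P in c(0.9, 0.95)) for (conf in c(0.9, 0.95))
    for (dir in c("upper", "lower")) {
      cfg <- tolerance_config(P, conf, side = "one-sided")
      for (n in c(5, 12)) for (x in 0:n) {
        b <- binomial_tolerance_bound(x, n, m = n, config = cfg,
                                      direction = dir)
        expect_identical(b$count_bound,
                         enumerate_count_bound(b$p_bound, n, P, dir),
                         info = sprintf("x=%d n=%d P=%g conf=%g %s",
                                        x, n, P, conf, dir))
      }
    }
})

test_that("discrete diagnosis applies the disjoint-state-set rule", {
  m <- make_tiny_matrix()
  d <- diagnose_discrete(m, "A", "B", "pores")
  expect_true(d$fixed_difference)
  # pores applicability: only the 3 adult males per taxon are scored
  expect_equal(unname(d$n), c(3L, 3L))
  expect_true(all(d$caveat_bounds > 0 & d$caveat_bounds <= 1))
  # polymorphic overlap is not fixed
  expect_false(diagnose_discrete(m, "A", "B", "marks")$fixed_difference)
  # both monomorphic for the same state is not fixed
  expect_false(diagnose_discrete(m, "A", "B", "belly")$fixed_difference)
  # symmetry up to swapping per-taxon fields
  d2 <- diagnose_discrete(m, "B", "A", "pores")
  expect_equal(d2$fixed_difference, d$fixed_difference)
  expect_equal(unname(d2$caveat_bounds[["a"]]), unname(d$caveat_bounds[["b"]]))
})

test_that("diagnosis is not-assessed when a taxon has no scored individuals", {
  ind <- data.frame(id = c("x1", "x2", "y1"), taxon = c("X", "X", "Y"),
                    sex = c("male", "male", "female"),
                    age_class = "adult", stringsAsFactors = FALSE)
  m <- character_matrix(ind, cbind(pores = c(0L, 0L, 1L)),
                        c(pores = "adult-males-only"))
  d <- diagnose_discrete(m, "X", "Y", "pores")  # Y has no adult males
  expect_true(is.na(d$fixed_difference))
})

test_that("gap detection treats touching intervals as overlap", {
  ti <- function(lo, hi) structure(list(lower = lo, upper = hi,
                                        k = 1, mean = (lo + hi) / 2,
                                        sd = 1, n = 10,
                                        config = tolerance_config()),
                                   class = "tolerance_interval")
  expect_false(detect_gap(ti(41.4, 72.3), ti(45.6, 62.0)))
  expect_true(detect_gap(ti(0, 1), ti(2, 3)))
  expect_false(detect_gap(ti(0, 1), ti(1, 2)))   # shared endpoint
  # symmetric
  expect_equal(detect_gap(ti(0, 1), ti(2, 3)), detect_gap(ti(2, 3), ti(0, 1)))
})

test_that("ti_table and the wide report render agree with normal_ti", {
  s <- data.frame(taxon = c("A", "B"), character = "MBS",
                  mean = c(56.8, 53.8), sd = c(6.1, 3.6), n = c(32L, 79L))
  tis <- ti_table(s)
  expect_equal(tis$lower[1], normal_ti(56.8, 6.1, 32)$lower)
  wide <- ti_wide_table(tis)
  expect_equal(wide$A[wide$character == "MBS"], "41.4-72.2")
  expect_equal(wide$B[wide$character == "MBS"], "45.6-62.0")
})
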