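test_that("zero- and full-success intervals follow the closed forms", {
  ci0 <- clopper_pearson(0, 10)
  expect_identical(ci0$lower, 0)
  expect_equal(ci0$upper, 1 - 0.025^(1 / 10), tolerance = 1e-12)

  # full-success case is the mirror image of the zero-success case
  ci1 <- clopper_pearson(10, 10)
  expect_identical(ci1$upper, 1)
  expect_equal(ci1$lower, 1 - ci0$upper, tolerance = 1e-12)
})

test_that("endpoints agree with the tail-probability bisection oracle", {
  cases <- expand.grid(x = c(0, 1, 5, 10, 17), n = c(10, 17, 36, 50))
  cases <- cases[cases$x <= cases$n, ]
  ci <- clopper_pearson(cases$x, cases$n)
  for (i in seq_len(nrow(cases))) {
    oracle <- ci_bisect_oracle(cases$x[i], cases$n[i])
    expect_equal(ci$lower[i], unname(oracle["lower"]), tolerance = 1e-9)
    expect_equal(ci$upper[i], unname(oracle["upper"]), tolerance = 1e-9)
  }
})

test_that("interval matches the reference implementation and is symmetric in x", {
  for (n in c(7, 23, 50)) {
    x <- 0:n
    ci <- clopper_pearson(x, n)
    # base R's binom.test interval is Clopper-Pearson: independent cross-check
    for (xi in x) {
      ref <- binom.test(xi, n)$conf.int
      expect_equal(ci$lower[xi + 1], ref[1], tolerance = 1e-10)
      expect_equal(ci$upper[xi + 1], ref[2], tolerance = 1e-10)
    }
    flipped <- clopper_pearson(n - x, n)
    expect_equal(ci$lower, 1 - flipped$upper, tolerance = 1e-12)
    expect_equal(ci$upper, 1 - flipped$lower, tolerance = 1e-12)
    # monotonicity in x at fixed n
    expect_true(all(diff(ci$lower) >= 0))
    expect_true(all(diff(ci$upper) >= 0))
    # the point estimate always lies inside
    expect_true(all(ci$lower <= ci$estimate & ci$estimate <= ci$upper))
  }
})

test_that("enumerated coverage is at least the nominal level", {
  for (n in c(5, 12, 25)) {
    ci <- clopper_pearson(0:n, n)
    for (p in seq(0.05, 0.95, by = 0.15)) {
      covered <- ci$lower <= p & p <= ci$upper
      expect_gte(sum(dbinom(0:n, n, p)[covered]), 0.95)
    }
  }
})

test_that("invalid inputs are rejected and add_binom_ci augments a table", {
  expect_error(clopper_pearson(5, 0), "trials")
  expect_error(clopper_pearson(11, 10), "successes")
  expect_error(clopper_pearson(3, 10, level = 1.2), "level")

  df <- tibble::tibble(sex = c("F", "H"), k = c(9, 38), n = c(80, 80))
  out <- add_binom_ci(df, k, n)
  expect_named(out, c("sex", "k", "n", "estimate", "lower", "upper", "level"))
  expect_equal(out$estimate, c(9, 38) / 80)
})
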