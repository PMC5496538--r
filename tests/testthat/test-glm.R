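test_that("intercept-only binomial fit recovers the sample proportion exactly", {
  dat <- tibble::tibble(y = rep(c(1L, 0L), c(7, 13)))
  fit <- ovb_glm(dat, y ~ 1, "binomial")
  expect_equal(unique(round(fit$fitted, 12)), 7 / 20)
  expect_equal(fit$coefficients[["(Intercept)"]], qlogis(7 / 20),
               tolerance = 1e-8)
  # closed-form null deviance of k successes in n
  k <- 7; n <- 20
  dev <- -2 * (k * log(k / n) + (n - k) * log(1 - k / n))
  expect_equal(fit$deviance, dev, tolerance = 1e-8)
})

test_that("coefficients match a direct likelihood-maximization oracle on small data", {
  withr::local_seed(101)
  for (family in c("binomial", "poisson")) {
    for (rep in 1:5) {
      n <- sample(10:30, 1)
      X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
      eta <- drop(X %*% c(0.2, 0.6, -0.4))
      y <- if (family == "binomial") rbinom(n, 1, plogis(eta))
           else rpois(n, exp(eta))
      if (family == "binomial" && (sum(y) < 2 || sum(y) > n - 2)) next
      dat <- tibble::tibble(y = y, x1 = X[, 2], x2 = X[, 3])
      fit <- ovb_glm(dat, y ~ x1 + x2, family)
      oracle <- glm_optim_oracle(X, y, family)
      expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-6)
    }
  }
})

test_that("quasi-Poisson dispersion is recovered from overdispersed data", {
  withr::local_seed(55)
  n <- 5000
  x <- rnorm(n)
  mu <- exp(1 + 0.3 * x)
  # negative binomial with var = mu + mu^2/size; size = mu gives Pearson
  # dispersion near 2 at this scale
  y <- rnbinom(n, mu = mu, size = mu / 1)
  dat <- tibble::tibble(y = y, x = x)
  fit <- ovb_glm(dat, y ~ x, "quasipoisson")
  expect_equal(fit$dispersion, 2, tolerance = 0.1)
  # non-quasi families report dispersion exactly 1
  expect_identical(ovb_glm(dat, y ~ x, "poisson")$dispersion, 1)
})

test_that("lr_test identity, nesting checks and deviance monotonicity hold", {
  withr::local_seed(8)
  dat <- tibble::tibble(y = rbinom(60, 1, 0.4), x = rnorm(60),
                        z = rnorm(60))
  f1 <- ovb_glm(dat, y ~ x, "binomial")
  same <- lr_test(f1, f1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  f2 <- ovb_glm(dat, y ~ x + z, "binomial")
  expect_lte(f2$deviance, f1$deviance)  # adding a term never hurts
  out <- lr_test(f1, f2, term = "z")
  expect_equal(out$df1, 1L)
  # agreement with the reference implementation's analysis of deviance
  ref <- anova(glm(y ~ x, binomial, dat), glm(y ~ x + z, binomial, dat),
               test = "Chisq")
  expect_equal(out$statistic, ref$Deviance[2], tolerance = 1e-7)
  expect_equal(out$p_value, ref$`Pr(>Chi)`[2], tolerance = 1e-7)

  other <- tibble::tibble(y = rbinom(60, 1, 0.4), x = rnorm(60))
  expect_error(lr_test(ovb_glm(other, y ~ x, "binomial"), f2), "same data")
  expect_error(lr_test(f2, f1), "more residual df|not nested")
})

test_that("chi-square and F forms agree when dispersion is near 1", {
  withr::local_seed(21)
  dat <- tibble::tibble(x = rnorm(4000))
  dat$y <- rpois(4000, exp(0.5 + 0.2 * dat$x))
  f0 <- ovb_glm(dat, y ~ 1, "quasipoisson")
  f1 <- ovb_glm(dat, y ~ x, "quasipoisson")
  expect_equal(f1$dispersion, 1, tolerance = 0.1)
  chi <- lr_test(f0, f1, kind = "chisq")
  ff <- lr_test(f0, f1, kind = "f")
  expect_equal(ff$statistic * ff$df1, chi$statistic,
               tolerance = 0.05 * chi$statistic)
})

test_that("rank deficiency and separation are reported, not hidden", {
  withr::local_seed(9)
  dat <- tibble::tibble(y = rbinom(30, 1, 0.5), x = rnorm(30))
  dat$x2 <- 2 * dat$x
  expect_error(ovb_glm(dat, y ~ x + x2, "binomial"), "rank deficient.*x2")

  sep <- tibble::tibble(y = rep(c(0L, 1L), each = 15),
                        x = rep(c(0, 1), each = 15))
  expect_warning(ovb_glm(sep, y ~ x, "binomial"), "separation")
})

test_that("backward selection keeps strong terms, drops noise, and re-tests drops", {
  withr::local_seed(33)
  n <- 400
  dat <- tibble::tibble(a = rnorm(n), b = rnorm(n), noise = rnorm(n))
  dat$y <- rbinom(n, 1, plogis(-0.5 + 1.2 * dat$a - 0.9 * dat$b))
  sel <- backward_select(dat, y ~ a + b + noise, "binomial")
  expect_setequal(sel$retained, c("a", "b"))
  expect_equal(sel$dropped$term, "noise")
  # the reported test for a dropped term compares final vs final + term
  f_final <- ovb_glm(dat, y ~ a + b, "binomial")
  f_aug <- ovb_glm(dat, y ~ a + b + noise, "binomial")
  expect_equal(sel$dropped$statistic,
               lr_test(f_final, f_aug)$statistic, tolerance = 1e-10)
  expect_true(all(tidy(sel)$status %in% c("retained", "dropped")))

  # all-strong case: nothing is removed
  dat2 <- dat
  dat2$y <- rbinom(n, 1, plogis(-0.5 + 1.5 * dat2$a - 1.5 * dat2$b +
                                  1.5 * dat2$noise))
  sel2 <- backward_select(dat2, y ~ a + b + noise, "binomial")
  expect_setequal(sel2$retained, c("a", "b", "noise"))
  expect_equal(nrow(sel2$dropped), 0L)
})

test_that("interactions are removed before their main effects", {
  withr::local_seed(12)
  n <- 300
  dat <- tibble::tibble(a = rnorm(n), g = sample(c("u", "v"), n, TRUE))
  dat$y <- rbinom(n, 1, plogis(0.8 * dat$a))
  sel <- backward_select(dat, y ~ a * g, "binomial")
  if ("a:g" %in% c(sel$retained, sel$dropped$term)) {
    first_removed <- sel$trace$term[1]
    if (nrow(sel$trace) > 0 && "a:g" %in% sel$dropped$term) {
      expect_equal(first_removed, "a:g")
    }
  }
  expect_true("a" %in% c(sel$retained, sel$dropped$term))
})

test_that("exponentiated coefficient reporting matches the printed convention", {
  # a log-link coefficient of 0.029 multiplies the response by 1.029 per
  # unit, and -0.14 multiplies it by 0.87
  expect_equal(round(exp(0.029), 3), 1.029)
  expect_equal(round(exp(-0.14), 2), 0.87)
  fit <- ovb_glm(tibble::tibble(y = rpois(50, 5), x = rnorm(50)),
                 y ~ x, "poisson")
  rep <- exponentiate_report(fit)
  expect_equal(rep$exp_estimate, exp(rep$estimate))
})

test_that("egg-count-given-receipt test handles effects and degeneracies", {
  withr::local_seed(77)
  n <- 500
  dat <- tibble::tibble(sex = sample(c("F", "H"), n, TRUE))
  dat$eggs <- rpois(n, exp(0.1 + 0.5 * (dat$sex == "H")))
  out <- eggs_given_receipt_test(dat, "eggs")
  expect_lt(out$p_value, 0.05)
  expect_equal(out$n, sum(dat$eggs > 0))

  one_sex <- tibble::tibble(sex = c("F", "F", "H"), eggs = c(2L, 1L, 0L))
  expect_error(eggs_given_receipt_test(one_sex, "eggs"), "one sex")

  const <- tibble::tibble(sex = rep(c("F", "H"), 5), eggs = rep(1L, 10))
  expect_warning(eggs_given_receipt_test(const, "eggs"), "Zero-variance")
})
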