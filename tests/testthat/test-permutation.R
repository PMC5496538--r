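test_that("degenerate flower configurations give p = 1", {
  # all hermaphrodite: the statistic equals the egg total in every replicate
  all_h <- make_flowers(herm = rep(TRUE, 6), egg = c(1, 1, 0, 0, 0, 0))
  res <- flower_sexbias_permutation(all_h, b = 200, seed = 1)
  expect_equal(res$observed_stat, 2)
  expect_equal(res$p_two_tailed, 1)

  # no eggs: degenerate null, flagged
  none <- make_flowers(herm = c(TRUE, FALSE, TRUE), egg = c(0, 0, 0))
  expect_warning(res0 <- flower_sexbias_permutation(none, b = 100), "No eggs")
  expect_equal(res0$p_two_tailed, 1)
})

test_that("exact stratified null matches explicit enumeration and dhyper", {
  withr::local_seed(14)
  for (rep in 1:8) {
    n <- sample(5:9, 1)
    herm <- runif(n) < 0.5
    k <- sample(1:3, 1)
    egg <- integer(n); egg[sample(n, k)] <- 1L
    fl <- make_flowers(herm, egg)
    res <- flower_sexbias_permutation(fl, exact = "always")
    oracle <- perm_enum_oracle(herm, k, sum(egg[herm]), extremity = "inclusive")
    expect_equal(res$p_two_tailed, oracle$p, tolerance = 1e-12)
    # exact pmf equals both the enumeration and the hypergeometric closed form
    enum_pmf <- table(oracle$stats) / length(oracle$stats)
    got <- res$null_pmf[res$null_pmf$prob > 1e-14, ]
    expect_equal(got$value, as.integer(names(enum_pmf)))
    expect_equal(got$prob, as.numeric(enum_pmf), tolerance = 1e-12)
    expect_equal(got$prob, dhyper(got$value, sum(herm), sum(!herm), k),
                 tolerance = 1e-12)
  }
})

test_that("multi-population exact null is the convolution across strata", {
  fl <- dplyr::bind_rows(
    make_flowers(c(TRUE, TRUE, FALSE, FALSE), c(1, 0, 1, 0), "p1"),
    make_flowers(c(TRUE, FALSE, FALSE), c(1, 0, 0), "p2")
  )
  res <- flower_sexbias_permutation(fl, exact = "always")
  # brute-force over all placements in both strata jointly
  stats <- c()
  for (idx1 in utils::combn(4, 2, simplify = FALSE)) {
    for (idx2 in 1:3) {
      stats <- c(stats, sum(c(TRUE, TRUE, FALSE, FALSE)[idx1]) +
                   c(TRUE, FALSE, FALSE)[idx2])
    }
  }
  brute <- table(stats) / length(stats)
  got <- res$null_pmf[res$null_pmf$prob > 1e-14, ]
  expect_equal(got$value, as.integer(names(brute)))
  expect_equal(got$prob, as.numeric(brute), tolerance = 1e-12)
})

test_that("Monte-Carlo p agrees with enumeration within 3 binomial SEs", {
  withr::local_seed(20)
  for (rep in 1:6) {
    n <- sample(6:10, 1)
    herm <- runif(n) < 0.6
    k <- sample(2:3, 1)
    egg <- integer(n); egg[sample(n, k)] <- 1L
    fl <- make_flowers(herm, egg)
    mc <- flower_sexbias_permutation(fl, b = 4000, seed = rep, exact = "never")
    oracle <- perm_enum_oracle(herm, k, sum(egg[herm]), extremity = "inclusive")
    tail_ex <- oracle$p / 2
    tol <- 3 * 2 * sqrt(tail_ex * (1 - tail_ex) / 4000)
    expect_lt(abs(mc$p_two_tailed - oracle$p), max(tol, 1e-12))
  }
})

test_that("every replicate preserves the per-population egg totals", {
  # the exact path fixes them by construction; check the MC path by making
  # strata so unbalanced that a violation would show up in the statistic range
  fl <- dplyr::bind_rows(
    make_flowers(rep(TRUE, 12), c(rep(1, 4), rep(0, 8)), "hh"),
    make_flowers(rep(FALSE, 12), c(1, rep(0, 11)), "ff")
  )
  res <- flower_sexbias_permutation(fl, b = 500, seed = 2, exact = "never")
  # all 4 eggs in 'hh' always land on hermaphrodites; the 'ff' egg never does
  expect_true(all(res$null_stats == 4))
})

test_that("permutation results are deterministic given the seed", {
  fl <- survey_to_flowers(simulate_survey(sim_config(n_units = 40,
                                                     n_populations = 2)))
  r1 <- flower_sexbias_permutation(fl, b = 300, seed = 9, exact = "never")
  r2 <- flower_sexbias_permutation(fl, b = 300, seed = 9, exact = "never")
  expect_identical(r1$null_stats, r2$null_stats)
  expect_identical(r1$p_two_tailed, r2$p_two_tailed)
  r3 <- flower_sexbias_permutation(fl, b = 300, seed = 10, exact = "never")
  expect_false(identical(r1$null_stats, r3$null_stats))
})

test_that("sign-flip exact null matches the bit-mask oracle", {
  withr::local_seed(31)
  for (n_pairs in c(3, 6, 10)) {
    d <- round(rnorm(n_pairs, 0.4, 1), 2)
    pairs <- tibble::tibble(
      pair_id = rep(sprintf("p%02d", 1:n_pairs), each = 2),
      plant_id = rep(sprintf("pl%02d", 1:n_pairs), each = 2),
      flower = rep(c("egg", "control"), n_pairs),
      calyx_width = 8, seeds = 1L,
      val = as.vector(rbind(d, 0))
    )
    res <- paired_swap_permutation(pairs, "val", exact = "always")
    oracle <- signflip_enum_oracle(d, extremity = "inclusive")
    expect_equal(res$observed_stat, mean(d))
    expect_equal(res$p_two_tailed, oracle$p, tolerance = 1e-12)
    expect_equal(sort(res$null_stats), sort(oracle$stats), tolerance = 1e-12)

    mc <- paired_swap_permutation(pairs, "val", b = 4000, seed = n_pairs,
                                  exact = "never")
    tail_ex <- oracle$p / 2
    tol <- 3 * 2 * sqrt(tail_ex * (1 - tail_ex) / 4000)
    expect_lt(abs(mc$p_two_tailed - oracle$p), max(tol, 1e-12))
  }
})

test_that("identical arms give p = 1 and missing arms are dropped with a message", {
  pairs <- simulate_pairs(sim_config(rng_seed = 4L), 8)
  same <- dplyr::mutate(pairs, seeds = rep(c(5L, 5L), 8))
  res <- paired_swap_permutation(same, "seeds")
  expect_equal(res$observed_stat, 0)
  expect_equal(res$p_two_tailed, 1)

  pairs$fruit_mass[pairs$pair_id == "pair_001"] <- NA_real_
  if (all(!is.na(pairs$fruit_mass[pairs$pair_id != "pair_001"]))) {
    expect_message(paired_swap_permutation(pairs, "fruit_mass"), "Dropped 1 pair")
  }
})

test_that("doubled-tail p never exceeds 1 and the denominator option works", {
  fl <- make_flowers(c(TRUE, FALSE, TRUE, FALSE, TRUE), c(1, 0, 1, 0, 0))
  res <- flower_sexbias_permutation(fl, exact = "always")
  expect_lte(res$p_two_tailed, 1)
  mc_plain <- flower_sexbias_permutation(fl, b = 1000, seed = 3,
                                         exact = "never")
  mc_plus <- flower_sexbias_permutation(fl, b = 1000, seed = 3,
                                        exact = "never",
                                        denominator = "plus_one")
  expect_lte(mc_plain$p_two_tailed, 1)
  expect_lte(mc_plus$p_two_tailed, 1)
  expect_gte(mc_plus$p_two_tailed, mc_plain$p_two_tailed)
})

test_that("paired t-test matches its definition and flags zero variance", {
  pairs <- simulate_pairs(sim_config(rng_seed = 6L), 36)
  out <- paired_t(pairs, "calyx_width")
  expect_equal(out$df, 35)
  wide <- pairs_wide(pairs)
  d <- wide$egg_calyx_width - wide$control_calyx_width
  expect_equal(out$t_stat, mean(d) / (sd(d) / sqrt(36)), tolerance = 1e-10)

  const <- dplyr::mutate(pairs, seeds = rep(c(3L, 1L), 36))
  expect_error(paired_t(const, "seeds"), "Zero variance")
})

test_that("differences symmetric about zero give a uniform p distribution", {
  withr::local_seed(60)
  ps <- replicate(400, {
    d <- rnorm(12)
    pairs <- tibble::tibble(
      pair_id = rep(sprintf("p%02d", 1:12), each = 2),
      plant_id = "x", flower = rep(c("egg", "control"), 12),
      calyx_width = 8, seeds = 1L, val = as.vector(rbind(d, 0))
    )
    paired_t(pairs, "val")$p_value
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
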