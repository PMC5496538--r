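cfg_big <- function(...) {
  sim_config(n_units = 12500, n_populations = 4, rng_seed = 42L, ...)
}

test_that("generator moments converge to configured values at large n", {
  cfg <- cfg_big()
  survey <- simulate_survey(cfg)  # 50,000 stems
  n <- nrow(survey)

  # sex ratio within 3 binomial SEs
  se_sex <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(mean(survey$sex == "F") - 0.5), 3 * se_sex)

  # single-egg fraction among egg-bearing stems ~ 0.71
  egg_stems <- survey$eggs[survey$eggs > 0]
  se1 <- sqrt(0.71 * 0.29 / length(egg_stems))
  expect_lt(abs(mean(egg_stems == 1) - 0.71), 3 * se1)

  # hermaphrodite-deeper dimorphism and depth-driven oviposition make the
  # realized hermaphrodite egg-receipt proportion exceed the female one;
  # compare against the closed-form marginal probability per sex obtained
  # by integrating the logistic over each sex's depth distribution
  p_marg <- function(mu) {
    integrate(function(z) plogis(-9.75 + 0.5 * z) * dnorm(z, mu, 1.5),
              mu - 8 * 1.5, mu + 8 * 1.5)$value
  }
  obs <- tapply(survey$eggs > 0, survey$sex, mean)
  expect_gt(obs[["H"]], obs[["F"]])
  for (sx in c("F", "H")) {
    mu <- cfg$trait_params$flower_depth$mean[[sx]]
    n_s <- sum(survey$sex == sx)
    se <- sqrt(p_marg(mu) * (1 - p_marg(mu)) / n_s)
    expect_lt(abs(obs[[sx]] - p_marg(mu)), 3 * se)
  }
})

test_that("null config gives equal egg receipt by sex within Monte-Carlo error", {
  survey <- simulate_survey(sim_config_null(n_units = 12500,
                                            n_populations = 4,
                                            rng_seed = 7L))
  k <- tapply(survey$eggs > 0, survey$sex, sum)
  n <- table(survey$sex)
  diff_se <- sqrt(0.2 * 0.8 * (1 / n[["F"]] + 1 / n[["H"]]))
  expect_lt(abs(k[["F"]] / n[["F"]] - k[["H"]] / n[["H"]]), 3 * diff_se)
})

test_that("monitoring reproduces dimorphism, egg rates and predation means", {
  cfg <- sim_config(n_plants_per_sex = 25000, rng_seed = 11L)
  plants <- simulate_monitoring(cfg)
  depth_gap <- mean(plants$flower_depth[plants$sex == "H"]) -
    mean(plants$flower_depth[plants$sex == "F"])
  expect_equal(depth_gap, 1.0, tolerance = 0.05)

  lost_egg <- plants$fruits_damaged[plants$egg_any == 1]
  lost_no <- plants$fruits_damaged[plants$egg_any == 0]
  se_egg <- sd(lost_egg) / sqrt(length(lost_egg))
  expect_lt(abs(mean(lost_egg) - 3.85), 3 * se_egg)
  se_no <- sd(lost_no) / sqrt(length(lost_no))
  expect_lt(abs(mean(lost_no) - 1.84), 3 * se_no)

  # total fruit production near the configured scale
  expect_equal(mean(plants$fruits_expanded), 30.75, tolerance = 0.15)
  expect_equal(ncol(dplyr::select(plants, dplyr::starts_with("egg_census_"))),
               cfg$n_censuses)
})

test_that("pair generator hits the calyx offset and zero-seed fractions", {
  cfg <- sim_config(rng_seed = 3L)
  pairs <- simulate_pairs(cfg, n_pairs = 25000)
  wide <- pairs_wide(pairs)
  d <- wide$egg_calyx_width - wide$control_calyx_width
  expect_lt(abs(mean(d) - 0.50), 3 * sd(d) / sqrt(length(d)))

  z_egg <- mean(pairs$seeds[pairs$flower == "egg"] == 0)
  z_ctl <- mean(pairs$seeds[pairs$flower == "control"] == 0)
  se <- sqrt(0.61 * 0.39 / 25000)
  expect_lt(abs(z_egg - 0.61), 3 * se)
  expect_lt(abs(z_ctl - 0.39), 3 * se)

  # fruit mass recorded exactly when seeds were produced
  expect_true(all(is.na(pairs$fruit_mass) == (pairs$seeds == 0)))
})

test_that("identical rng_seed gives byte-identical datasets and files", {
  cfg <- sim_config(n_units = 30, n_populations = 2, rng_seed = 99L)
  expect_identical(simulate_survey(cfg), simulate_survey(cfg))
  expect_identical(simulate_monitoring(cfg), simulate_monitoring(cfg))
  f1 <- tempfile(); f2 <- tempfile()
  write_dataset(simulate_pairs(cfg, 8), f1)
  write_dataset(simulate_pairs(cfg, 8), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("invalid configurations are rejected with clear messages", {
  expect_error(sim_config(female_freq = 1.3), "probability")
  expect_error(sim_config(n_units = 0), "positive integer")
  expect_error(sim_config(single_egg_prob = -0.1), "probability")
  tp <- sim_config()$trait_params
  tp$flower_depth$sd <- -1
  expect_error(sim_config(trait_params = tp), "nonnegative")
  expect_error(simulate_pairs(sim_config(), n_pairs = 0), "positive")
})

test_that("config JSON round-trips through read_config/write_config", {
  cfg <- sim_config(female_freq = 0.3, rng_seed = 123L)
  path <- tempfile(fileext = ".json")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$female_freq, 0.3)
  expect_identical(cfg2$rng_seed, 123L)
  expect_identical(simulate_survey(cfg), simulate_survey(cfg2))
})

test_that("survey_to_flowers expands stems and caps eggs at open flowers", {
  survey <- tibble::tibble(
    population = "p1", stem_id = c("a", "b", "c"), sex = c("F", "H", "H"),
    open_flowers = c(3L, 1L, 2L), eggs = c(1L, 0L, 5L),
    caterpillars = 0L, leaf_damage = 0L, flower_damage = 0L
  )
  fl <- survey_to_flowers(survey)
  expect_equal(nrow(fl), 6L)
  expect_equal(sum(fl$egg), 3L)  # 1 + 0 + capped 2
  expect_equal(tapply(fl$egg, fl$stem_id, sum)[["c"]], 2L)
})
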