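#' Simulate a multi-population stem-level transect survey
#'
#' Emulates a one-visit transect survey of several natural populations:
#' each sampled stem bears at least one open flower, its sex is drawn with
#' probability `female_freq` of being female, and egg receipt follows a
#' logistic model on the stem's (latent) flower depth plus any direct sex
#' term. When an oviposition event occurs the stem carries one egg with
#' probability `single_egg_prob`, otherwise two or more. Leaf and flower
#' damage are Bernoulli with per-sex probabilities; caterpillar sightings
#' are rare Bernoulli events.
#'
#' @param config An [sim_config()] object.
#' @param seed Integer seed; defaults to `config$rng_seed`. The same seed
#'   and config always give an identical tibble.
#' @return A tibble with one row per stem: `population`, `stem_id`, `sex`
#'   (`"F"`/`"H"`), `open_flowers`, `eggs`, `caterpillars`, `leaf_damage`,
#'   `flower_damage`.
#' @examples
#' survey <- simulate_survey(sim_config(n_units = 40, n_populations = 3))
#' dplyr::count(survey, sex, egg = eggs > 0)
#' @export
simulate_survey <- function(config, seed = config$rng_seed) {
  stopifnot(inherits(config, "ovb_config"))
  withr::with_seed(seed, {
    n_pop <- config$n_populations
    n <- config$n_units * n_pop
    population <- rep(sprintf("pop_%02d", seq_len(n_pop)), each = config$n_units)
    sex <- ifelse(stats::runif(n) < config$female_freq, "F", "H")
    depth <- draw_trait(config$trait_params$flower_depth, sex)
    open_flowers <- draw_count(config$trait_params$open_flowers, sex, min = 1)
    eta <- config$ovi_intercept_survey +
      config$ovi_coefs[["flower_depth"]] * depth +
      config$ovi_coefs[["sex"]] * (sex == "H")
    event <- stats::rbinom(n, 1, stats::plogis(eta)) == 1
    eggs <- integer(n)
    eggs[event] <- draw_egg_count(sum(event), config)
    tibble::tibble(
      population = population,
      stem_id = sprintf("stem_%04d", seq_len(n)),
      sex = sex,
      open_flowers = open_flowers,
      eggs = eggs,
      caterpillars = stats::rbinom(n, 1, config$caterpillar_prob),
      leaf_damage = draw_damage(config, "leaf", sex),
      flower_damage = draw_damage(config, "flower", sex)
    )
  })
}

#' Expand a stem survey to flower-level records
#'
#' Each stem contributes `open_flowers` flower records sharing the stem's
#' sex; the stem's eggs occupy distinct flowers (at most one egg per flower,
#' capped at the number of open flowers). This is the unit of the
#' flower-level sex-bias analyses.
#'
#' @param survey A stem-survey tibble as from [simulate_survey()].
#' @return A tibble with one row per flower: `population`, `stem_id`, `sex`,
#'   `egg` (0/1).
#' @export
survey_to_flowers <- function(survey) {
  validate_survey(survey)
  survey |>
    dplyr::mutate(.egg_flowers = pmin(.data$eggs, .data$open_flowers)) |>
    tidyr::uncount(.data$open_flowers, .id = "flower_num", .remove = FALSE) |>
    dplyr::mutate(egg = as.integer(.data$flower_num <= .data$.egg_flowers)) |>
    dplyr::select("population", "stem_id", "sex", "egg")
}

#' Simulate whole-plant monitoring of one population
#'
#' Emulates a single-population season of monitoring: fixed numbers of
#' female and hermaphrodite plants, per-sex plant and floral traits, egg
#' receipt assessed at each of `n_censuses` censuses through a logistic
#' model on flower depth and stem number (plus any direct sex term), floral
#' damage assessed twice, and end-of-season expanded and predated fruit
#' counts. Fruit number follows a log-linear negative-binomial model on the
#' plant traits; fruits lost to predation have different means for plants
#' that did and did not receive eggs.
#'
#' @inheritParams simulate_survey
#' @return A tibble with one row per plant: `plant_id`, `sex`, `stems`,
#'   `height`, `projected_area`, `open_flowers`, `flower_depth`,
#'   `flower_width`, `egg_census_1..k`, `egg_any`, `eggs_total`,
#'   `bud/calyx/petal/ovary_damage_1..2`, `fruits_expanded`,
#'   `fruits_damaged`.
#' @examples
#' plants <- simulate_monitoring(sim_config(n_plants_per_sex = 40))
#' dplyr::count(plants, sex, egg_any)
#' @export
simulate_monitoring <- function(config, seed = config$rng_seed) {
  stopifnot(inherits(config, "ovb_config"))
  withr::with_seed(seed, {
    n <- 2L * config$n_plants_per_sex
    sex <- rep(c("F", "H"), each = config$n_plants_per_sex)
    tp <- config$trait_params
    out <- tibble::tibble(
      plant_id = sprintf("plant_%03d", seq_len(n)),
      sex = sex,
      stems = draw_count(tp$stems, sex, min = 1),
      height = draw_trait(tp$height, sex),
      projected_area = draw_trait(tp$projected_area, sex),
      open_flowers = draw_count(tp$open_flowers, sex, min = 1),
      flower_depth = draw_trait(tp$flower_depth, sex),
      flower_width = draw_trait(tp$flower_width, sex)
    )
    eta <- config$ovi_coefs[["intercept"]] +
      config$ovi_coefs[["flower_depth"]] * out$flower_depth +
      config$ovi_coefs[["stems"]] * out$stems +
      config$ovi_coefs[["sex"]] * (sex == "H")
    p_census <- stats::plogis(eta)
    egg_mat <- matrix(
      stats::rbinom(n * config$n_censuses, 1, rep(p_census, config$n_censuses)),
      nrow = n
    )
    colnames(egg_mat) <- sprintf("egg_census_%d", seq_len(config$n_censuses))
    out <- dplyr::bind_cols(out, tibble::as_tibble(egg_mat))
    out$egg_any <- as.integer(rowSums(egg_mat) > 0)
    # one egg per positive census with prob single_egg_prob, else 2+
    pos <- which(egg_mat == 1)
    per_event <- integer(length(egg_mat))
    per_event[pos] <- draw_egg_count(length(pos), config)
    out$eggs_total <- as.integer(rowSums(matrix(per_event, nrow = n)))
    for (type in c("bud", "calyx", "petal", "ovary")) {
      for (a in 1:2) {
        out[[sprintf("%s_damage_%d", type, a)]] <- draw_damage(config, type, sex)
      }
    }
    eta_fruit <- with(out, config$fruit_coefs[["intercept"]] +
      config$fruit_coefs[["open_flowers"]] * open_flowers +
      config$fruit_coefs[["stems"]] * stems +
      config$fruit_coefs[["height"]] * height +
      config$fruit_coefs[["flower_depth"]] * flower_depth +
      config$fruit_coefs[["projected_area"]] * projected_area +
      config$fruit_coefs[["flower_width"]] * flower_width +
      config$fruit_coefs[["sex"]] * (sex == "H") +
      config$fruit_coefs[["oviposition"]] * egg_any)
    out$fruits_expanded <- as.integer(
      stats::rnbinom(n, mu = exp(eta_fruit), size = config$fruit_size))
    pp <- config$predation_params
    mu_lost <- ifelse(out$egg_any == 1, pp[["lost_egg"]], pp[["lost_noegg"]]) *
      exp(pp[["sex"]] * (sex == "H"))
    out$fruits_damaged <- as.integer(
      stats::rnbinom(n, mu = mu_lost, size = pp[["size"]]))
    out
  })
}

#' Simulate age-matched flower pairs from egg-receiving plants
#'
#' Emulates the paired-flower design: on each of `n_pairs` plants, one
#' flower received a moth egg and a developmentally matched flower on the
#' same plant did not. Each floral trait has a plant-level mean
#' (`between_sd`), flower-level noise (`within_sd`) and an additive shift on
#' the egg-receiving flower (`egg_offset`; by default only calyx width is
#' shifted, by +0.50 mm). Each arm fails to set seed with its configured
#' zero-seed probability; nonzero seed counts are truncated-normal, and
#' fruit mass is recorded only for fruits that made seeds.
#'
#' @inheritParams simulate_survey
#' @param n_pairs Number of plant pairs (default 36).
#' @return A long tibble with two rows per pair (`flower` = `"egg"` /
#'   `"control"`): `pair_id`, `plant_id`, `sex`, the five floral traits,
#'   `seeds`, `fruit_mass` (NA when no seeds).
#' @examples
#' pairs <- simulate_pairs(sim_config(), n_pairs = 10)
#' tidyr::pivot_wider(pairs, id_cols = pair_id, names_from = flower,
#'                    values_from = seeds)
#' @export
simulate_pairs <- function(config, n_pairs = 36, seed = config$rng_seed) {
  stopifnot(inherits(config, "ovb_config"))
  if (!is.finite(n_pairs) || n_pairs < 1) {
    rlang::abort("`n_pairs` must be a positive integer.")
  }
  withr::with_seed(seed, {
    sex <- ifelse(stats::runif(n_pairs) < config$female_freq, "F", "H")
    out <- tibble::tibble(
      pair_id = rep(sprintf("pair_%03d", seq_len(n_pairs)), each = 2L),
      plant_id = rep(sprintf("plant_%03d", seq_len(n_pairs)), each = 2L),
      sex = rep(sex, each = 2L),
      flower = rep(c("egg", "control"), times = n_pairs)
    )
    is_egg <- out$flower == "egg"
    for (nm in names(config$pair_traits)) {
      pt <- config$pair_traits[[nm]]
      plant_mean <- rtruncnorm0(n_pairs, pt$mean, pt$between_sd)
      vals <- rep(plant_mean, each = 2L) +
        stats::rnorm(2L * n_pairs, 0, pt$within_sd) +
        pt$egg_offset * is_egg
      out[[nm]] <- pmax(vals, 0.01)
    }
    p_zero <- ifelse(is_egg, config$zero_seed_probs[["egg"]],
                     config$zero_seed_probs[["control"]])
    zero <- stats::rbinom(2L * n_pairs, 1, p_zero) == 1
    seeds <- integer(2L * n_pairs)
    scp <- config$seed_count_params
    seeds[!zero] <- as.integer(pmax(1, round(stats::rnorm(
      sum(!zero), scp[["mean"]], scp[["sd"]]))))
    out$seeds <- seeds
    fmp <- config$fruit_mass_params
    mass <- rep(NA_real_, 2L * n_pairs)
    mass[!zero] <- pmax(1, stats::rnorm(sum(!zero), fmp[["mean"]], fmp[["sd"]]))
    out$fruit_mass <- mass
    out
  })
}

# --- internal draws -------------------------------------------------------

# normal truncated at 0 by inverse-CDF
rtruncnorm0 <- function(n, mean, sd) {
  if (all(sd == 0)) return(rep(mean, length.out = n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (1 - lo), mean, sd)
}

draw_trait <- function(tp, sex) {
  unname(rtruncnorm0(length(sex), tp$mean[sex], tp$sd))
}

draw_count <- function(tp, sex, min = 0L) {
  mu <- pmax(tp$mean[sex] - min, 1e-8)
  as.integer(unname(min + stats::rnbinom(length(sex), mu = mu, size = tp$size)))
}

draw_damage <- function(config, type, sex) {
  p <- config$damage_probs[[type]][sex]
  unname(stats::rbinom(length(sex), 1, p))
}

# eggs per oviposition event: 1 w.p. single_egg_prob, else 2 + Poisson extra
draw_egg_count <- function(n_events, config) {
  if (n_events == 0L) return(integer(0))
  single <- stats::runif(n_events) < config$single_egg_prob
  extra <- stats::rpois(n_events, config$extra_egg_mean)
  as.integer(ifelse(single, 1L, 2L + extra))
}
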