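#' Simulation configuration for a gynodioecious study population
#'
#' Builds the parameter set that drives all three synthetic designs: a
#' multi-population stem-level transect survey, single-population whole-plant
#' monitoring over four censuses, and age-matched flower pairs collected from
#' egg-receiving plants. Defaults describe a population in which
#' hermaphrodites bear deeper flowers than females (1 mm dimorphism), moth
#' oviposition probability increases with flower depth and stem number with
#' no direct sex preference (so any realized sex bias is mediated entirely by
#' dimorphic traits), most oviposition events deposit a single egg, fruit
#' predation on egg-receiving plants is light relative to total fruit
#' production, and egg-receiving flowers usually fail to set seed.
#'
#' Continuous traits are drawn from per-sex normal distributions truncated at
#' zero; counts (stems, open flowers, fruits) are negative binomial with a
#' configurable dispersion (`size`), matching the overdispersion the
#' quasi-likelihood analyses assume. Trait standard deviations are assumed
#' values chosen to be biologically plausible, not field measurements.
#'
#' @param female_freq Probability a surveyed stem (or pair-study plant)
#'   is female. Default 0.5.
#' @param n_units Stems sampled per population in the survey design.
#' @param n_populations Number of survey populations.
#' @param n_plants_per_sex Plants of each sex in the monitoring design
#'   (default 80 females and 80 hermaphrodites).
#' @param n_censuses Egg censuses per plant in the monitoring design.
#' @param trait_params Named list of per-sex trait distributions; see
#'   Details. Continuous entries are `list(mean = c(F = , H = ), sd = )`;
#'   count entries are `list(mean = c(F = , H = ), size = )` (negative
#'   binomial, minimum 1).
#' @param ovi_coefs Log-odds coefficients of per-census plant-level egg
#'   receipt: named vector with `intercept`, `flower_depth` (per mm),
#'   `stems` (per stem) and `sex` (added for hermaphrodites; default 0).
#' @param ovi_intercept_survey Intercept of the stem-level (survey) egg
#'   model, whose linear predictor uses the `flower_depth` and `sex`
#'   coefficients only (stem counts of the parent plant are latent at stem
#'   level).
#' @param single_egg_prob Probability an oviposition event deposits exactly
#'   one egg (additional eggs are `1 + Poisson(extra_egg_mean)` beyond the
#'   first).
#' @param extra_egg_mean Poisson mean for eggs beyond the second in
#'   multi-egg events.
#' @param caterpillar_prob Per-stem probability of a caterpillar sighting.
#' @param fruit_coefs Log-scale coefficients of expanded fruit number:
#'   `intercept`, `open_flowers`, `stems`, `height`, `flower_depth`,
#'   `projected_area`, `flower_width`, `sex` (hermaphrodite), `oviposition`
#'   (egg-receiving). Defaults give a mean near 30.75 fruits.
#' @param fruit_size Negative-binomial dispersion of expanded fruits.
#' @param predation_params Named vector: mean fruits lost for egg-receiving
#'   (`lost_egg`) and non-receiving (`lost_noegg`) plants, plus
#'   negative-binomial `size`. A `sex` element (log scale, hermaphrodite)
#'   allows a sex effect on fruit loss; default 0.
#' @param zero_seed_probs Probability of a zero-seed outcome for the
#'   egg-receiving (`egg`) and control (`control`) arm of a flower pair.
#' @param seed_count_params Mean and SD of seed counts when nonzero.
#' @param fruit_mass_params Mean and SD (mg) of fruit mass when seeds > 0.
#' @param pair_traits Named list of within-plant pair-trait models, each
#'   `list(mean, between_sd, within_sd, egg_offset)`: a plant-level mean,
#'   flower-level noise, and the shift added to the egg-receiving flower.
#'   The default calyx-width entry uses offset 0.50 mm.
#' @param damage_probs Named list of per-sex damage probabilities
#'   (`c(F = , H = )`) for `leaf`, `flower`, `bud`, `calyx`, `petal`,
#'   `ovary` damage.
#' @param rng_seed Integer seed making every generated dataset reproducible.
#'
#' @return A validated list of class `"ovb_config"`.
#' @seealso [sim_config_null()] for the global-null configuration;
#'   [simulate_survey()], [simulate_monitoring()], [simulate_pairs()].
#' @export
sim_config <- function(female_freq = 0.5,
                       n_units = 50,
                       n_populations = 6,
                       n_plants_per_sex = 80,
                       n_censuses = 4,
                       trait_params = default_trait_params(),
                       ovi_coefs = c(intercept = -12.7, flower_depth = 0.5,
                                     stems = 0.15, sex = 0),
                       ovi_intercept_survey = -9.75,
                       single_egg_prob = 0.71,
                       extra_egg_mean = 0.3,
                       caterpillar_prob = 0.02,
                       fruit_coefs = c(intercept = 4.18, open_flowers = 0.029,
                                       stems = 0.020, height = 0.029,
                                       flower_depth = -0.14,
                                       projected_area = 0.00011,
                                       flower_width = 0, sex = 0,
                                       oviposition = 0),
                       fruit_size = 2,
                       predation_params = c(lost_egg = 3.85, lost_noegg = 1.84,
                                            size = 0.5, sex = 0),
                       zero_seed_probs = c(egg = 0.61, control = 0.39),
                       seed_count_params = c(mean = 50, sd = 25),
                       fruit_mass_params = c(mean = 150, sd = 40),
                       pair_traits = default_pair_traits(),
                       damage_probs = list(
                         leaf = c(F = 0.95, H = 0.95),
                         flower = c(F = 0.30, H = 0.45),
                         bud = c(F = 0.10, H = 0.10),
                         calyx = c(F = 0.07, H = 0.15),
                         petal = c(F = 0.07, H = 0.15),
                         ovary = c(F = 0.05, H = 0.05)
                       ),
                       rng_seed = 1L) {
  cfg <- list(
    female_freq = female_freq,
    n_units = n_units,
    n_populations = n_populations,
    n_plants_per_sex = n_plants_per_sex,
    n_censuses = n_censuses,
    trait_params = trait_params,
    ovi_coefs = ovi_coefs,
    ovi_intercept_survey = ovi_intercept_survey,
    single_egg_prob = single_egg_prob,
    extra_egg_mean = extra_egg_mean,
    caterpillar_prob = caterpillar_prob,
    fruit_coefs = fruit_coefs,
    fruit_size = fruit_size,
    predation_params = predation_params,
    zero_seed_probs = zero_seed_probs,
    seed_count_params = seed_count_params,
    fruit_mass_params = fruit_mass_params,
    pair_traits = pair_traits,
    damage_probs = damage_probs,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "ovb_config"
  validate_config(cfg)
}

default_trait_params <- function() {
  list(
    flower_depth = list(mean = c(F = 17.0, H = 18.0), sd = 1.5),
    flower_width = list(mean = c(F = 20.0, H = 20.0), sd = 2.0),
    calyx_width = list(mean = c(F = 7.9, H = 7.9), sd = 1.2),
    calyx_length = list(mean = c(F = 12.0, H = 12.0), sd = 1.0),
    height = list(mean = c(F = 40.0, H = 40.0), sd = 8.0),
    projected_area = list(mean = c(F = 1500, H = 1500), sd = 500),
    stems = list(mean = c(F = 10, H = 10), size = 5),
    open_flowers = list(mean = c(F = 6, H = 6), size = 4)
  )
}

default_pair_traits <- function() {
  list(
    calyx_width = list(mean = 7.66, between_sd = 1.05, within_sd = 0.67,
                       egg_offset = 0.50),
    calyx_length = list(mean = 12.0, between_sd = 1.0, within_sd = 0.5,
                        egg_offset = 0),
    flower_length = list(mean = 14.0, between_sd = 1.0, within_sd = 0.5,
                         egg_offset = 0),
    floral_face_width = list(mean = 20.0, between_sd = 2.0, within_sd = 0.7,
                             egg_offset = 0),
    tube_opening = list(mean = 3.5, between_sd = 0.5, within_sd = 0.2,
                        egg_offset = 0)
  )
}

#' Global-null simulation configuration
#'
#' Convenience constructor for the configuration in which nothing is sex-
#' biased and no trait influences oviposition: all oviposition slopes and the
#' direct sex term are 0, traits are sexually monomorphic, damage
#' probabilities are equal between the sexes, the within-pair trait offsets
#' are 0 and the two pair arms share one zero-seed probability. Downstream
#' tests run on data from this configuration should reject at their nominal
#' rate.
#'
#' @param egg_rate Marginal per-census probability of egg receipt (and the
#'   stem-level rate in the survey design).
#' @param zero_seed_prob Common zero-seed probability for both pair arms.
#' @param ... Passed on to [sim_config()] (e.g. `n_units`, `rng_seed`).
#' @return An `"ovb_config"` object.
#' @export
sim_config_null <- function(egg_rate = 0.2, zero_seed_prob = 0.5, ...) {
  tp <- default_trait_params()
  tp$flower_depth$mean[] <- mean(tp$flower_depth$mean)
  pt <- default_pair_traits()
  pt$calyx_width$egg_offset <- 0
  dp <- list(
    leaf = c(F = 0.95, H = 0.95), flower = c(F = 0.35, H = 0.35),
    bud = c(F = 0.10, H = 0.10), calyx = c(F = 0.10, H = 0.10),
    petal = c(F = 0.10, H = 0.10), ovary = c(F = 0.05, H = 0.05)
  )
  sim_config(
    trait_params = tp,
    ovi_coefs = c(intercept = stats::qlogis(egg_rate), flower_depth = 0,
                  stems = 0, sex = 0),
    ovi_intercept_survey = stats::qlogis(egg_rate),
    predation_params = c(lost_egg = 2.5, lost_noegg = 2.5, size = 0.5,
                         sex = 0),
    zero_seed_probs = c(egg = zero_seed_prob, control = zero_seed_prob),
    pair_traits = pt,
    damage_probs = dp,
    ...
  )
}

validate_config <- function(cfg) {
  chk_prob <- function(p, what) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
      rlang::abort(sprintf("`%s` must be a probability in [0, 1].", what))
    }
  }
  chk_count <- function(n, what) {
    if (length(n) != 1L || !is.finite(n) || n < 1 || n != floor(n)) {
      rlang::abort(sprintf("`%s` must be a positive integer.", what))
    }
  }
  chk_prob(cfg$female_freq, "female_freq")
  chk_prob(cfg$single_egg_prob, "single_egg_prob")
  chk_prob(cfg$caterpillar_prob, "caterpillar_prob")
  chk_prob(cfg$zero_seed_probs, "zero_seed_probs")
  chk_count(cfg$n_units, "n_units")
  chk_count(cfg$n_populations, "n_populations")
  chk_count(cfg$n_plants_per_sex, "n_plants_per_sex")
  chk_count(cfg$n_censuses, "n_censuses")
  for (nm in names(cfg$trait_params)) {
    tp <- cfg$trait_params[[nm]]
    if (length(tp$mean) != 2L || any(!is.finite(tp$mean)) || any(tp$mean < 0)) {
      rlang::abort(sprintf("trait `%s`: `mean` must be two nonnegative values (F, H).", nm))
    }
    disp <- if (!is.null(tp$sd)) tp$sd else tp$size
    if (is.null(disp) || !is.finite(disp) || disp < 0) {
      rlang::abort(sprintf("trait `%s`: `sd`/`size` must be nonnegative.", nm))
    }
  }
  for (nm in names(cfg$damage_probs)) {
    chk_prob(cfg$damage_probs[[nm]], paste0("damage_probs$", nm))
  }
  for (nm in names(cfg$pair_traits)) {
    pt <- cfg$pair_traits[[nm]]
    if (any(!is.finite(unlist(pt))) || pt$between_sd < 0 || pt$within_sd < 0) {
      rlang::abort(sprintf("pair trait `%s`: SDs must be nonnegative.", nm))
    }
  }
  if (any(cfg$predation_params[c("lost_egg", "lost_noegg", "size")] <= 0)) {
    rlang::abort("`predation_params` means and size must be positive.")
  }
  if (any(cfg$seed_count_params <= 0) || any(cfg$fruit_mass_params <= 0)) {
    rlang::abort("seed and fruit-mass parameters must be positive.")
  }
  if (!is.finite(cfg$rng_seed)) rlang::abort("`rng_seed` must be an integer.")
  cfg
}

#' @export
print.ovb_config <- function(x, ...) {
  cat("<ovb_config>\n")
  cat(sprintf("  survey    : %d populations x %d stems, female freq %.2f\n",
              x$n_populations, x$n_units, x$female_freq))
  cat(sprintf("  monitoring: %d plants/sex, %d censuses\n",
              x$n_plants_per_sex, x$n_censuses))
  cat(sprintf("  oviposition log-odds: intercept %.2f, depth %.2f/mm, stems %.2f, sex %.2f\n",
              x$ovi_coefs[["intercept"]], x$ovi_coefs[["flower_depth"]],
              x$ovi_coefs[["stems"]], x$ovi_coefs[["sex"]]))
  cat(sprintf("  flower-depth dimorphism (H - F): %.2f mm\n",
              x$trait_params$flower_depth$mean[["H"]] -
                x$trait_params$flower_depth$mean[["F"]]))
  cat(sprintf("  rng_seed: %d\n", x$rng_seed))
  invisible(x)
}

#' Read or write a simulation configuration as JSON
#'
#' The flat key-value JSON representation stores every parameter, including
#' `rng_seed`, so a configuration file fully determines the generated data.
#'
#' @param cfg An `"ovb_config"`.
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()` an
#'   `"ovb_config"`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "ovb_config"))
  # named atomic vectors must become JSON objects, not nameless arrays
  jsonable <- function(x) {
    if (is.list(x)) {
      lapply(x, jsonable)
    } else if (!is.null(names(x)) && length(x) > 1L) {
      as.list(x)
    } else {
      x
    }
  }
  jsonlite::write_json(jsonable(unclass(cfg)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  relist_trait <- function(x) lapply(x, function(tp) {
    tp$mean <- unlist(tp$mean)
    tp
  })
  raw$trait_params <- relist_trait(raw$trait_params)
  raw$damage_probs <- lapply(raw$damage_probs, unlist)
  for (nm in c("ovi_coefs", "fruit_coefs", "predation_params",
               "zero_seed_probs", "seed_count_params", "fruit_mass_params")) {
    raw[[nm]] <- unlist(raw[[nm]])
  }
  raw$rng_seed <- as.integer(raw$rng_seed)
  class(raw) <- "ovb_config"
  validate_config(raw)
}
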