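#' Expected sex shares of eggs under the proportional-null hypothesis
#'
#' The null hypothesis of every sex-bias test is that eggs (or damage) fall
#' on females and hermaphrodites in proportion to the sex ratio of the
#' sampled units: in a population that is 10% female, females are expected
#' to receive 10% of the eggs.
#'
#' @param n_female,n_herm Counts of female and hermaphrodite units
#'   (flowers, stems or plants); their sum must be at least 1.
#' @param n_eggs Total egg count.
#' @return A tibble with one row per sex: `sex`, `n_units`, `share`,
#'   `expected_eggs`.
#' @examples
#' expected_null_share(30, 270, 50)  # females expected to get 10%: 5 eggs
#' @export
expected_null_share <- function(n_female, n_herm, n_eggs) {
  if (any(!is.finite(c(n_female, n_herm, n_eggs))) ||
      any(c(n_female, n_herm, n_eggs) < 0)) {
    rlang::abort("Counts must be finite and nonnegative.")
  }
  total <- n_female + n_herm
  if (total < 1) rlang::abort("There must be at least one flower.")
  tibble::tibble(
    sex = c("F", "H"),
    n_units = c(n_female, n_herm),
    share = c(n_female, n_herm) / total,
    expected_eggs = n_eggs * c(n_female, n_herm) / total
  )
}

#' Analyse a multi-population stem survey
#'
#' Runs the survey-design analyses: stem-level binomial GLM tests of sex,
#' population and their interaction on egg receipt (restricted to
#' populations where eggs were observed), a flower-level sex test both by
#' GLM and by the stratified permutation test, per-population per-sex
#' egg-receipt proportions with exact binomial confidence intervals, a test
#' of sex differences in egg number among egg-receiving stems, and
#' leaf/flower damage sex-bias tests across all surveyed populations.
#'
#' @param survey A stem-survey tibble (see [simulate_survey()] for the
#'   schema).
#' @param b Permutation replicates (default 10000).
#' @param alpha Significance threshold recorded in the report.
#' @param seed Seed for the permutation test.
#' @param test_kind `"chisq"` (default) fits binomial models and uses LR
#'   chi-square tests; `"f"` fits quasi-binomial models and uses
#'   quasi-likelihood F tests.
#' @param extremity Permutation extremity rule, see
#'   [flower_sexbias_permutation()].
#' @return An `"ovb_report"` object; see [report_as_list()] /
#'   [write_report()] for serialization.
#' @export
analyze_survey <- function(survey, b = 10000, alpha = 0.05, seed = 1L,
                           test_kind = c("chisq", "f"),
                           extremity = c("inclusive", "strict")) {
  test_kind <- rlang::arg_match(test_kind)
  extremity <- rlang::arg_match(extremity)
  validate_survey(survey)
  family <- if (test_kind == "f") "quasibinomial" else "binomial"
  survey <- dplyr::mutate(survey, egg01 = as.integer(.data$eggs > 0))

  # oviposition analyses use only populations where eggs were observed
  egg_pops <- survey |>
    dplyr::group_by(.data$population) |>
    dplyr::filter(sum(.data$egg01) > 0) |>
    dplyr::ungroup()
  blocks <- list()

  multi_pop <- length(unique(egg_pops$population)) >= 2L
  single_sex <- egg_pops |>
    dplyr::count(.data$population, .data$sex) |>
    dplyr::count(.data$population) |>
    dplyr::filter(.data$n < 2L)
  use_interaction <- multi_pop && nrow(single_sex) == 0L
  if (multi_pop && !use_interaction) {
    rlang::warn(sprintf(
      "Population%s with a single sex: dropping the sex-by-population interaction.",
      if (nrow(single_sex) > 1) "s" else ""))
  }
  if (multi_pop) {
    f_add <- ovb_glm(egg_pops, egg01 ~ sex + population, family)
    tests <- dplyr::bind_rows(
      lr_test(ovb_glm(egg_pops, egg01 ~ population, family), f_add,
              kind = test_kind, term = "sex"),
      lr_test(ovb_glm(egg_pops, egg01 ~ sex, family), f_add,
              kind = test_kind, term = "population")
    )
    if (use_interaction) {
      f_full <- ovb_glm(egg_pops, egg01 ~ sex * population, family)
      tests <- dplyr::bind_rows(
        tests,
        lr_test(f_add, f_full, kind = test_kind, term = "sex:population")
      )
    }
    blocks$stem_sexbias <- list(
      model = sprintf("egg01 ~ sex * population (%s)", family),
      n = nrow(egg_pops), tests = tests
    )
  } else {
    f1 <- ovb_glm(egg_pops, egg01 ~ sex, family)
    blocks$stem_sexbias <- list(
      model = sprintf("egg01 ~ sex (%s)", family), n = nrow(egg_pops),
      tests = lr_test(ovb_glm(egg_pops, egg01 ~ 1, family), f1,
                      kind = test_kind, term = "sex")
    )
  }

  flowers <- survey_to_flowers(egg_pops)
  fl_terms <- if (multi_pop) egg ~ sex + population else egg ~ sex
  fl_reduced <- if (multi_pop) egg ~ population else egg ~ 1
  blocks$flower_sexbias_glm <- list(
    model = sprintf("%s (%s)", deparse(fl_terms), family),
    n = nrow(flowers),
    tests = lr_test(ovb_glm(flowers, fl_reduced, family),
                    ovb_glm(flowers, fl_terms, family),
                    kind = test_kind, term = "sex")
  )
  blocks$flower_sexbias_permutation <- flower_sexbias_permutation(
    flowers, b = b, seed = seed, extremity = extremity
  )
  blocks$null_shares <- expected_null_share(
    sum(flowers$sex == "F"), sum(flowers$sex == "H"), sum(flowers$egg)
  )

  blocks$stem_proportions <- survey |>
    dplyr::group_by(.data$population, .data$sex) |>
    dplyr::summarise(with_eggs = sum(.data$egg01), stems = dplyr::n(),
                     .groups = "drop") |>
    add_binom_ci("with_eggs", "stems")

  blocks$eggs_given_receipt <- tryCatch(
    eggs_given_receipt_test(egg_pops, "eggs"),
    error = function(e) list(error = conditionMessage(e))
  )

  # damage analyses use all surveyed populations
  damage_tests <- purrr::map(c(leaf = "leaf_damage", flower = "flower_damage"),
    function(col) {
      dat <- dplyr::mutate(survey, resp = .data[[col]])
      full <- if (multi_pop) resp ~ sex + population else resp ~ sex
      red_sex <- if (multi_pop) resp ~ population else resp ~ 1
      f_full <- ovb_glm(dat, full, family)
      tests <- lr_test(ovb_glm(dat, red_sex, family), f_full,
                       kind = test_kind, term = "sex")
      if (multi_pop) {
        tests <- dplyr::bind_rows(tests,
          lr_test(ovb_glm(dat, resp ~ sex, family), f_full,
                  kind = test_kind, term = "population"))
      }
      props <- dat |>
        dplyr::group_by(.data$sex) |>
        dplyr::summarise(damaged = sum(.data$resp), n = dplyr::n(),
                         .groups = "drop") |>
        add_binom_ci("damaged", "n")
      list(tests = tests, proportions = props)
    })
  blocks$damage <- damage_tests

  new_report("survey", blocks,
             settings = list(alpha = alpha, b = b, seed = seed,
                             test_kind = test_kind, extremity = extremity,
                             family = family))
}

#' Analyse whole-plant monitoring data
#'
#' Runs the monitoring-design analyses: (a) the sex-only binomial test of
#' ever receiving an egg; (b) backward selection over all measured plant
#' traits plus sex as predictors of egg receipt; (c) per-trait sexual
#' dimorphism tests (Gaussian linear model F tests); (d) a quasi-Poisson
#' model of expanded fruit number over the traits plus sex and oviposition
#' status, selected backward with quasi-likelihood F tests and reported
#' with exponentiated coefficients; (e) quasi-Poisson F tests of
#' oviposition and sex effects on fruits lost to predation, with a
#' leave-one-extreme-out sensitivity refit that flags significance flips;
#' and (f) per-census egg-receipt proportions by sex with exact binomial
#' confidence intervals.
#'
#' @param plants A monitoring tibble (see [simulate_monitoring()]).
#' @param alpha Significance threshold for selection and the report.
#' @return An `"ovb_report"` object.
#' @export
analyze_monitoring <- function(plants, alpha = 0.05) {
  validate_plants(plants)
  blocks <- list()

  f_sex <- ovb_glm(plants, egg_any ~ sex, "binomial")
  blocks$plant_sexbias <- list(
    model = "egg_any ~ sex (binomial)", n = nrow(plants),
    tests = lr_test(ovb_glm(plants, egg_any ~ 1, "binomial"), f_sex,
                    kind = "chisq", term = "sex")
  )

  trait_formula <- egg_any ~ open_flowers + stems + height + projected_area +
    flower_depth + flower_width + sex
  blocks$trait_selection <- backward_select(plants, trait_formula,
                                            "binomial", alpha = alpha,
                                            kind = "chisq")

  blocks$dimorphism <- purrr::map_dfr(
    c("flower_depth", "flower_width", "stems", "height", "projected_area",
      "open_flowers"),
    function(tr) {
      fit <- stats::lm(stats::reformulate("sex", tr), data = plants)
      av <- stats::anova(fit)
      means <- tapply(plants[[tr]], plants$sex, mean)
      tibble::tibble(
        trait = tr, mean_F = means[["F"]], mean_H = means[["H"]],
        kind = "f", statistic = av$`F value`[1], df1 = av$Df[1],
        df2 = av$Df[2], p_value = av$`Pr(>F)`[1]
      )
    })

  fruit_formula <- fruits_expanded ~ open_flowers + stems + height +
    flower_depth + projected_area + flower_width + sex + egg_any
  sel <- backward_select(plants, fruit_formula, "quasipoisson",
                         alpha = alpha, kind = "f")
  blocks$fruit_production <- list(
    selection = sel,
    effects = exponentiate_report(sel$final_fit)
  )

  blocks$fruit_predation <- fruit_predation_tests(plants, alpha)

  census_cols <- grep("^egg_census_", names(plants), value = TRUE)
  if (length(census_cols)) {
    blocks$census_proportions <- plants |>
      tidyr::pivot_longer(dplyr::all_of(census_cols), names_to = "census",
                          values_to = "egg") |>
      dplyr::group_by(.data$census, .data$sex) |>
      dplyr::summarise(with_eggs = sum(.data$egg), plants = dplyr::n(),
                       .groups = "drop") |>
      add_binom_ci("with_eggs", "plants")
  }

  if ("eggs_total" %in% names(plants)) {
    blocks$eggs_given_receipt <- tryCatch(
      eggs_given_receipt_test(plants, "eggs_total"),
      error = function(e) list(error = conditionMessage(e))
    )
  }

  new_report("monitoring", blocks, settings = list(alpha = alpha))
}

# quasi-Poisson F tests of oviposition and sex on fruits lost, with a
# leave-one-extreme-out sensitivity refit
fruit_predation_tests <- function(plants, alpha) {
  run <- function(dat) {
    full <- ovb_glm(dat, fruits_damaged ~ egg_any + sex, "quasipoisson")
    dplyr::bind_rows(
      lr_test(ovb_glm(dat, fruits_damaged ~ sex, "quasipoisson"), full,
              kind = "f", term = "egg_any"),
      lr_test(ovb_glm(dat, fruits_damaged ~ egg_any, "quasipoisson"), full,
              kind = "f", term = "sex")
    )
  }
  tests_full <- run(plants)
  extreme <- which.max(plants$fruits_damaged)
  tests_loo <- run(plants[-extreme, , drop = FALSE])
  flips <- (tests_full$p_value <= alpha) != (tests_loo$p_value <= alpha)
  means <- plants |>
    dplyr::group_by(egg = .data$egg_any) |>
    dplyr::summarise(mean_lost = mean(.data$fruits_damaged),
                     se_lost = stats::sd(.data$fruits_damaged) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  list(
    model = "fruits_damaged ~ egg_any + sex (quasipoisson, F)",
    tests = tests_full,
    excluded_row = extreme,
    excluded_value = plants$fruits_damaged[extreme],
    tests_without_extreme = tests_loo,
    sensitivity_flag = any(flips),
    flipped_terms = tests_full$term[flips],
    group_means = means,
    mean_fruits_expanded = mean(plants$fruits_expanded)
  )
}

#' Analyse age-matched flower pairs
#'
#' Runs the paired-flower analyses: per-trait paired t-tests between the
#' egg-receiving and control flower of each pair; comparisons of seed
#' number and fruit mass by within-pair sign-flip permutation (always) and
#' by paired t (unless `egg_removed = TRUE`, the small egg-removal design
#' where only the permutation test is appropriate); zero-seed outcome
#' proportions per arm with exact binomial confidence intervals; and the
#' both-failed / both-seeded pair outcome summary.
#'
#' @param pairs Long pair records (see [simulate_pairs()]).
#' @param egg_removed Set `TRUE` for the egg-removal design: only the
#'   permutation tests are reported for seeds and fruit mass.
#' @inheritParams analyze_survey
#' @return An `"ovb_report"` object.
#' @export
analyze_pairs <- function(pairs, egg_removed = FALSE, b = 10000,
                          alpha = 0.05, seed = 1L,
                          extremity = c("inclusive", "strict")) {
  extremity <- rlang::arg_match(extremity)
  validate_pairs(pairs)
  blocks <- list()

  trait_cols <- intersect(
    c("calyx_width", "calyx_length", "flower_length", "floral_face_width",
      "tube_opening"),
    names(pairs)
  )
  if (length(trait_cols)) {
    blocks$trait_tests <- purrr::map_dfr(trait_cols, function(tr) {
      tryCatch(paired_t(pairs, tr), error = function(e) {
        tibble::tibble(value = tr, n_pairs = NA_integer_,
                       mean_diff = NA_real_, t_stat = NA_real_,
                       df = NA_real_, p_value = NA_real_)
      })
    })
  }

  outcome_cols <- intersect(c("seeds", "fruit_mass"), names(pairs))
  blocks$outcome_tests <- purrr::map(
    stats::setNames(outcome_cols, outcome_cols),
    function(v) {
      res <- list(permutation = paired_swap_permutation(
        pairs, v, b = b, seed = seed, extremity = extremity))
      if (!egg_removed) {
        res$paired_t <- tryCatch(paired_t(pairs, v),
                                 error = function(e) {
                                   list(error = conditionMessage(e))
                                 })
      }
      res
    })

  if ("seeds" %in% names(pairs)) {
    blocks$zero_seed_proportions <- pairs |>
      dplyr::group_by(.data$flower) |>
      dplyr::summarise(zero_seed = sum(.data$seeds == 0), n = dplyr::n(),
                       .groups = "drop") |>
      add_binom_ci("zero_seed", "n")
    wide <- pairs_wide(pairs)
    blocks$pair_outcomes <- tibble::tibble(
      n_pairs = nrow(wide),
      both_failed = mean(wide$egg_seeds == 0 & wide$control_seeds == 0),
      both_seeded = mean(wide$egg_seeds > 0 & wide$control_seeds > 0)
    )
  }

  new_report("pairs", blocks,
             settings = list(alpha = alpha, b = b, seed = seed,
                             egg_removed = egg_removed,
                             extremity = extremity))
}

# --- report container -----------------------------------------------------

new_report <- function(analysis, blocks, settings) {
  settings$n_tests <- count_tests(blocks)
  structure(list(analysis = analysis, blocks = blocks, settings = settings),
            class = "ovb_report")
}

count_tests <- function(x) {
  if (inherits(x, "ovb_perm")) return(1L)
  if (inherits(x, "ovb_backward")) return(nrow(x$dropped) + nrow(x$retained_tests))
  if (is.data.frame(x)) return(sum(c("p_value", "p_two_tailed") %in% names(x)) *
                                 nrow(x))
  if (is.list(x)) return(sum(vapply(x, count_tests, integer(1))))
  0L
}

#' @export
print.ovb_report <- function(x, ...) {
  cat(sprintf("<ovb_report: %s analysis>\n", x$analysis))
  cat("  blocks:", paste(names(x$blocks), collapse = ", "), "\n")
  cat(sprintf("  settings: alpha = %s; %d test(s) reported, no multiplicity correction\n",
              format(x$settings$alpha), x$settings$n_tests))
  invisible(x)
}

#' Serialize an analysis report
#'
#' `report_as_list()` converts an `"ovb_report"` (whose blocks hold fitted
#' models, permutation results and tibbles) to plain lists/data frames;
#' `write_report()` writes that as JSON. Every stochastic result carries
#' its seed and the extremity/denominator conventions used.
#'
#' @param report An `"ovb_report"`.
#' @param path Output JSON path.
#' @return `report_as_list()` a plain list; `write_report()` `path`,
#'   invisibly.
#' @export
report_as_list <- function(report) {
  stopifnot(inherits(report, "ovb_report"))
  simplify <- function(x) {
    if (inherits(x, "ovb_perm")) {
      out <- as.data.frame(tidy(x))
      out$denominator <- x$denominator
      return(out)
    }
    if (inherits(x, "ovb_glm")) {
      return(list(coefficients = as.data.frame(tidy(x)),
                  fit = as.data.frame(glance(x))))
    }
    if (inherits(x, "ovb_backward")) {
      return(list(retained = x$retained,
                  tests = as.data.frame(tidy(x)),
                  final_fit = simplify(x$final_fit),
                  alpha = x$alpha))
    }
    if (is.data.frame(x)) return(as.data.frame(x))
    if (is.list(x)) return(lapply(x, simplify))
    x
  }
  list(analysis = report$analysis,
       settings = report$settings,
       blocks = simplify(report$blocks))
}

#' @rdname report_as_list
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report_as_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Collect every proportion-with-CI table from a report
#'
#' @param report An `"ovb_report"`.
#' @return A tibble stacking all proportion blocks, with a `block` column.
#' @export
report_proportions <- function(report) {
  stopifnot(inherits(report, "ovb_report"))
  grab <- function(x, name) {
    if (is.data.frame(x) && all(c("lower", "upper") %in% names(x))) {
      return(list(dplyr::mutate(x, block = name, .before = 1)))
    }
    if (inherits(x, "ovb_perm") || inherits(x, "ovb_backward") ||
        inherits(x, "ovb_glm")) {
      return(list())
    }
    if (is.list(x)) {
      return(purrr::flatten(purrr::imap(x, function(el, nm) {
        grab(el, paste(name, nm, sep = "."))
      })))
    }
    list()
  }
  found <- grab(report$blocks, report$analysis)
  if (!length(found)) return(tibble::tibble())
  dplyr::bind_rows(found)
}
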