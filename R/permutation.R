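#' Stratified permutation test for flower-level sex bias
#'
#' Tests whether egg-receiving flowers fall on hermaphrodite plants more (or
#' less) often than expected from the flower-level sex ratio, holding the
#' number of eggs in each population fixed. Each permutation replicate
#' reshuffles the egg indicators uniformly among the flowers *within* each
#' population independently; the statistic is the total number of
#' hermaphrodite flowers bearing eggs. The two-tailed p-value is the
#' doubled tail: twice the fraction of null statistics more extreme than
#' the observed value, in the direction of the observed departure from the
#' null mean, capped at 1.
#'
#' For small problems the null distribution is computed exactly instead of
#' sampled: under within-population reshuffling the per-population count of
#' eggs on hermaphrodite flowers is hypergeometric, and the statistic's
#' exact distribution is the convolution of those independent
#' hypergeometrics — equivalent to enumerating every distinct egg
#' placement. The exact path is used when the number of distinct placements
#' (the product over populations of `choose(flowers, eggs)`) is at most
#' `max_exact`.
#'
#' @param flowers Flower-level records: columns `population`, `sex`
#'   (`"F"`/`"H"`) and `egg` (0/1), as from [survey_to_flowers()].
#' @param b Number of Monte-Carlo replicates (default 10000; ignored on the
#'   exact path).
#' @param seed Integer seed; identical seed and input give an identical
#'   null sequence.
#' @param extremity `"inclusive"` (the default) counts null values at
#'   least as extreme as the observed statistic, the conventional
#'   permutation rule, which keeps the test conservative on discrete null
#'   distributions; `"strict"` counts only values strictly more extreme
#'   and is anticonservative when ties are common.
#' @param denominator `"plain"` computes the tail as count/B (the doubled
#'   literal formula, default); `"plus_one"` uses (count+1)/(B+1).
#' @param exact `"auto"` (default), `"never"`, or `"always"`.
#' @param max_exact Distinct-placement threshold for the automatic exact
#'   path.
#' @return An object of class `"ovb_perm"`: `observed_stat`, `null_stats`
#'   (Monte-Carlo draws, or `NULL` on the exact path), `null_pmf` (exact
#'   value/probability tibble, or `NULL`), `null_mean`, `B`,
#'   `p_two_tailed`, `extremity_rule`, `denominator`, `rng_seed`, `exact`,
#'   and per-population stratum sizes. Use [tidy()][generics::tidy] for a
#'   one-row summary.
#' @examples
#' survey <- simulate_survey(sim_config(n_units = 60, n_populations = 3))
#' flowers <- survey_to_flowers(survey)
#' tidy(flower_sexbias_permutation(flowers, b = 2000, seed = 7))
#' @export
flower_sexbias_permutation <- function(flowers, b = 10000, seed = 1L,
                                       extremity = c("inclusive", "strict"),
                                       denominator = c("plain", "plus_one"),
                                       exact = c("auto", "never", "always"),
                                       max_exact = 1e6) {
  extremity <- rlang::arg_match(extremity)
  denominator <- rlang::arg_match(denominator)
  exact <- rlang::arg_match(exact)
  validate_flowers(flowers)
  if (nrow(flowers) < 2L) {
    rlang::abort("Need at least 2 flowers for the permutation test.")
  }
  strata <- flowers |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      n_flowers = dplyr::n(),
      n_herm = sum(.data$sex == "H"),
      n_eggs = sum(.data$egg),
      observed = sum(.data$egg[.data$sex == "H"]),
      .groups = "drop"
    )
  observed <- sum(strata$observed)
  total_eggs <- sum(strata$n_eggs)
  if (total_eggs == 0) {
    rlang::warn("No eggs in the data; the permutation null is degenerate (p = 1).")
    return(new_perm_result(observed = 0, null_stats = NULL,
                           null_pmf = tibble::tibble(value = 0, prob = 1),
                           b = 0L, p = 1, extremity = extremity,
                           denominator = denominator, seed = seed,
                           exact = TRUE, strata = strata,
                           statistic = "hermaphrodite flowers with eggs"))
  }
  log_placements <- sum(lchoose(strata$n_flowers, strata$n_eggs))
  use_exact <- exact == "always" ||
    (exact == "auto" && log_placements <= log(max_exact))

  if (use_exact) {
    # convolution of independent per-population hypergeometric pmfs
    pmf <- c(1)
    offset <- 0L
    for (i in seq_len(nrow(strata))) {
      kk <- strata$n_eggs[i]
      lo <- max(0L, kk - (strata$n_flowers[i] - strata$n_herm[i]))
      hi <- min(kk, strata$n_herm[i])
      comp <- stats::dhyper(lo:hi, strata$n_herm[i],
                            strata$n_flowers[i] - strata$n_herm[i], kk)
      pmf <- convolve_pmf(pmf, comp)
      offset <- offset + lo
    }
    null_pmf <- tibble::tibble(
      value = offset + seq_along(pmf) - 1L,
      prob = pmf
    )
    null_pmf <- null_pmf[null_pmf$prob > 0, ]
    null_mean <- sum(null_pmf$value * null_pmf$prob)
    p <- doubled_tail_p(observed, center = null_mean,
                        values = null_pmf$value, probs = null_pmf$prob,
                        extremity = extremity)
    return(new_perm_result(observed, NULL, null_pmf, b = 0L, p = p,
                           extremity = extremity, denominator = denominator,
                           seed = seed, exact = TRUE, strata = strata,
                           statistic = "hermaphrodite flowers with eggs"))
  }

  # analytic null mean (sum of hypergeometric means), shared with the exact
  # path so the extremity direction does not depend on Monte-Carlo noise
  null_center <- sum(strata$n_eggs * strata$n_herm / strata$n_flowers)
  herm_by_pop <- split(flowers$sex == "H", flowers$population)
  null_stats <- withr::with_seed(seed, {
    draws <- matrix(0L, nrow = b, ncol = nrow(strata))
    for (i in seq_len(nrow(strata))) {
      h <- herm_by_pop[[strata$population[i]]]
      n_i <- strata$n_flowers[i]
      k_i <- strata$n_eggs[i]
      if (k_i == 0L) next
      draws[, i] <- vapply(seq_len(b), function(r) {
        sum(h[sample.int(n_i, k_i)])
      }, integer(1))
    }
    as.integer(rowSums(draws))
  })
  p <- doubled_tail_p(observed, center = null_center, values = null_stats,
                      probs = NULL, extremity = extremity,
                      denominator = denominator, b = b)
  new_perm_result(observed, null_stats, NULL, b = b, p = p,
                  extremity = extremity, denominator = denominator,
                  seed = seed, exact = FALSE, strata = strata,
                  statistic = "hermaphrodite flowers with eggs",
                  null_mean = null_center)
}

#' Within-pair sign-flip permutation test
#'
#' For age-matched flower pairs (one egg-receiving, one control flower per
#' plant), tests whether the mean within-pair difference (egg minus
#' control) of `value` differs from 0. Each replicate independently swaps
#' the two arm labels of each pair with probability 1/2; the statistic is
#' the mean difference. When `2^n_pairs` does not exceed `2^max_exact_pairs`
#' the full sign-flip distribution is enumerated instead of sampled. The
#' two-tailed p-value is the doubled tail around the null center 0.
#'
#' Pairs missing `value` in either arm are dropped with a message.
#'
#' @param pairs Long pair records as from [simulate_pairs()] (two rows per
#'   pair, `flower` = `"egg"`/`"control"`).
#' @param value Name of the measured variable to compare (e.g. `"seeds"`,
#'   `"fruit_mass"`).
#' @inheritParams flower_sexbias_permutation
#' @param max_exact_pairs Exact enumeration is used for up to this many
#'   pairs (default 20, i.e. 2^20 assignments).
#' @return An `"ovb_perm"` object; see [flower_sexbias_permutation()].
#' @examples
#' pairs <- simulate_pairs(sim_config(), n_pairs = 10)
#' tidy(paired_swap_permutation(pairs, "seeds", seed = 3))
#' @export
paired_swap_permutation <- function(pairs, value = "seeds", b = 10000,
                                    seed = 1L,
                                    extremity = c("inclusive", "strict"),
                                    denominator = c("plain", "plus_one"),
                                    exact = c("auto", "never", "always"),
                                    max_exact_pairs = 20L) {
  extremity <- rlang::arg_match(extremity)
  denominator <- rlang::arg_match(denominator)
  exact <- rlang::arg_match(exact)
  d <- pair_differences(pairs, value)
  n <- length(d)
  observed <- mean(d)
  use_exact <- exact == "always" ||
    (exact == "auto" && n <= max_exact_pairs)
  eps <- 1e-12 * max(1, abs(observed))

  if (use_exact) {
    sums <- 0
    for (di in d) sums <- c(sums + di, sums - di)
    null_stats <- sums / n
    p <- doubled_tail_p(observed, center = 0, values = null_stats,
                        probs = rep(1 / length(null_stats),
                                    length(null_stats)),
                        extremity = extremity, eps = eps)
    return(new_perm_result(observed, null_stats, NULL, b = length(null_stats),
                           p = p, extremity = extremity,
                           denominator = denominator, seed = seed,
                           exact = TRUE, strata = NULL,
                           statistic = sprintf("mean within-pair difference in %s", value),
                           n_pairs = n))
  }
  null_stats <- withr::with_seed(seed, {
    signs <- matrix(sign(stats::runif(n * b) - 0.5), nrow = n)
    drop(crossprod(signs, d)) / n
  })
  p <- doubled_tail_p(observed, center = 0, values = null_stats,
                      probs = NULL, extremity = extremity,
                      denominator = denominator, b = b, eps = eps)
  new_perm_result(observed, null_stats, NULL, b = b, p = p,
                  extremity = extremity, denominator = denominator,
                  seed = seed, exact = FALSE, strata = NULL,
                  statistic = sprintf("mean within-pair difference in %s", value),
                  n_pairs = n)
}

#' Paired t-test on within-pair differences
#'
#' Classical one-sample t-test on the egg-minus-control differences of
#' `value` across complete pairs (df = number of pairs minus 1, two-tailed).
#'
#' @inheritParams paired_swap_permutation
#' @return A one-row tibble: `value`, `n_pairs`, `mean_diff`, `t_stat`,
#'   `df`, `p_value`.
#' @examples
#' pairs <- simulate_pairs(sim_config(), n_pairs = 36)
#' paired_t(pairs, "calyx_width")
#' @export
paired_t <- function(pairs, value = "seeds") {
  d <- pair_differences(pairs, value)
  if (stats::var(d) == 0) {
    rlang::abort("Zero variance of within-pair differences; the t statistic is undefined.")
  }
  tt <- stats::t.test(d)
  tibble::tibble(
    value = value,
    n_pairs = length(d),
    mean_diff = mean(d),
    t_stat = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value
  )
}

# egg-minus-control differences over complete pairs, with a logged drop count
pair_differences <- function(pairs, value) {
  validate_pairs(pairs)
  if (!value %in% names(pairs)) {
    rlang::abort(sprintf("Column `%s` not found in the pair data.", value))
  }
  wide <- tidyr::pivot_wider(
    pairs[, c("pair_id", "flower", value)],
    names_from = "flower", values_from = dplyr::all_of(value)
  )
  complete <- !is.na(wide$egg) & !is.na(wide$control)
  if (sum(!complete) > 0) {
    rlang::inform(sprintf("Dropped %d pair%s with a missing `%s` arm.",
                          sum(!complete),
                          if (sum(!complete) > 1) "s" else "", value))
  }
  d <- wide$egg[complete] - wide$control[complete]
  if (length(d) < 2L) {
    rlang::abort("Need at least 2 complete pairs.")
  }
  d
}

# --- shared machinery -----------------------------------------------------

# Doubled-tail two-sided p: extremity measured in the direction of the
# observed departure from the null center; tail fraction doubled, capped at 1.
doubled_tail_p <- function(observed, center, values, probs = NULL,
                           extremity = "strict", denominator = "plain",
                           b = length(values), eps = 0) {
  direction <- observed - center
  if (abs(direction) <= eps) return(1)
  if (direction > 0) {
    hit <- if (extremity == "strict") values > observed + eps
           else values >= observed - eps
  } else {
    hit <- if (extremity == "strict") values < observed - eps
           else values <= observed + eps
  }
  tail <- if (!is.null(probs)) {
    sum(probs[hit])
  } else if (denominator == "plain") {
    sum(hit) / b
  } else {
    (sum(hit) + 1) / (b + 1)
  }
  min(1, 2 * tail)
}

convolve_pmf <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

new_perm_result <- function(observed, null_stats, null_pmf, b, p, extremity,
                            denominator, seed, exact, strata, statistic,
                            n_pairs = NULL, null_mean = NULL) {
  if (is.null(null_mean)) {
    null_mean <- if (!is.null(null_pmf)) {
      sum(null_pmf$value * null_pmf$prob)
    } else if (!is.null(null_stats)) {
      mean(null_stats)
    } else {
      NA_real_
    }
  }
  structure(list(
    statistic = statistic,
    observed_stat = observed,
    null_stats = null_stats,
    null_pmf = null_pmf,
    null_mean = null_mean,
    B = b,
    p_two_tailed = p,
    extremity_rule = extremity,
    denominator = denominator,
    rng_seed = seed,
    exact = exact,
    strata = strata,
    n_pairs = n_pairs
  ), class = "ovb_perm")
}

#' @export
print.ovb_perm <- function(x, ...) {
  cat(sprintf("<ovb_perm: %s>\n", x$statistic))
  cat(sprintf("  observed %.4g; null mean %.4g; p (two-tailed, doubled %s tail) = %.4g\n",
              x$observed_stat, x$null_mean, x$extremity_rule, x$p_two_tailed))
  cat(sprintf("  %s, B = %d, seed = %d\n",
              if (x$exact) "exact enumeration" else "Monte-Carlo",
              x$B, x$rng_seed))
  invisible(x)
}
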