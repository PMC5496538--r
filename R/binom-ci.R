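#' Exact (Clopper-Pearson) binomial confidence intervals
#'
#' Computes the exact binomial confidence interval obtained by inverting the
#' binomial tail probabilities, in its equivalent beta-quantile form: the
#' lower endpoint is the `(1 - level)/2` quantile of `Beta(x, n - x + 1)`
#' (0 when `x = 0`) and the upper endpoint is the `1 - (1 - level)/2`
#' quantile of `Beta(x + 1, n - x)` (1 when `x = n`). The interval is
#' asymmetric about the observed proportion, which is why error bars built
#' from it are unequal above and below the point estimate.
#'
#' @param successes Integer vector of success counts.
#' @param trials Integer vector of trial counts (recycled against
#'   `successes`); every element must be at least 1.
#' @param level Confidence level, a single probability strictly between 0
#'   and 1. Default 0.95.
#'
#' @return A tibble with one row per input: `successes`, `trials`,
#'   `estimate` (the observed proportion), `lower`, `upper`, `level`.
#'
#' @examples
#' clopper_pearson(0, 10)                # upper = 1 - 0.025^(1/10)
#' clopper_pearson(c(3, 47), c(80, 160))
#' @export
clopper_pearson <- function(successes, trials, level = 0.95) {
  if (length(level) != 1L || !is.finite(level) || level <= 0 || level >= 1) {
    rlang::abort("`level` must be a single probability strictly between 0 and 1.")
  }
  n_out <- max(length(successes), length(trials))
  x <- vctrs_recycle(as.numeric(successes), n_out, "successes")
  n <- vctrs_recycle(as.numeric(trials), n_out, "trials")
  if (any(!is.finite(x)) || any(!is.finite(n)) ||
      any(x != floor(x)) || any(n != floor(n))) {
    rlang::abort("`successes` and `trials` must be finite integers.")
  }
  if (any(n < 1)) {
    rlang::abort("`trials` must be at least 1.")
  }
  if (any(x < 0) || any(x > n)) {
    rlang::abort("`successes` must satisfy 0 <= successes <= trials.")
  }
  alpha <- 1 - level
  lower <- ifelse(x == 0, 0, stats::qbeta(alpha / 2, x, n - x + 1))
  upper <- ifelse(x == n, 1, stats::qbeta(1 - alpha / 2, x + 1, n - x))
  tibble::tibble(
    successes = as.integer(x),
    trials = as.integer(n),
    estimate = x / n,
    lower = lower,
    upper = upper,
    level = level
  )
}

#' Attach exact binomial confidence intervals to a table of proportions
#'
#' Convenience wrapper around [clopper_pearson()] for grouped summaries:
#' takes a data frame holding per-group success and trial counts and adds
#' `estimate`, `lower` and `upper` columns.
#'
#' @param data A data frame.
#' @param successes,trials Columns of `data` (tidy-eval) holding the counts.
#' @param level Confidence level (default 0.95).
#'
#' @return `data` with `estimate`, `lower`, `upper` and `level` columns
#'   appended.
#' @examples
#' df <- tibble::tibble(sex = c("F", "H"), eggs = c(9, 38), stems = c(80, 80))
#' add_binom_ci(df, eggs, stems)
#' @export
add_binom_ci <- function(data, successes, trials, level = 0.95) {
  x <- dplyr::pull(data, {{ successes }})
  n <- dplyr::pull(data, {{ trials }})
  ci <- clopper_pearson(x, n, level = level)
  dplyr::bind_cols(
    data,
    dplyr::select(ci, "estimate", "lower", "upper", "level")
  )
}

# minimal recycling helper (length-1 or length-n), avoids a vctrs dependency
vctrs_recycle <- function(x, n, name) {
  if (length(x) == n) return(x)
  if (length(x) == 1L) return(rep(x, n))
  rlang::abort(sprintf("`%s` must have length 1 or %d.", name, n))
}
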