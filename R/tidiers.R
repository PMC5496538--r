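#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted GLM
#'
#' @param x An `"ovb_glm"` fit.
#' @param exponentiate If `TRUE`, add an `exp_estimate` column (the
#'   multiplicative effect on the response mean or odds).
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` and `std.error` (link scale,
#'   scaled by the estimated dispersion for quasi families).
#' @export
#' @exportS3Method generics::tidy
tidy.ovb_glm <- function(x, exponentiate = FALSE, ...) {
  r_inv <- chol2inv(qr.R(x$qr))
  se <- sqrt(diag(r_inv) * x$dispersion)
  out <- tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = se
  )
  if (exponentiate) out$exp_estimate <- exp(out$estimate)
  out
}

#' @rdname tidy.ovb_glm
#' @export
#' @exportS3Method generics::glance
glance.ovb_glm <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    deviance = x$deviance,
    null_deviance = x$null_deviance,
    df_residual = x$df_residual,
    dispersion = x$dispersion,
    converged = x$converged,
    iterations = x$iterations,
    nobs = x$n_obs
  )
}

#' Tidy a backward-selection result
#'
#' One row per candidate term: retained terms carry their LR test within
#' the final model; dropped terms carry the test of adding them back to the
#' final model.
#'
#' @param x An `"ovb_backward"` object.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.ovb_backward <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$retained_tests, status = "retained"),
    dplyr::mutate(x$dropped, status = "dropped")
  )
}

#' @rdname tidy.ovb_backward
#' @export
#' @exportS3Method generics::glance
glance.ovb_backward <- function(x, ...) {
  tibble::tibble(
    n_retained = length(x$retained),
    n_dropped = nrow(x$dropped),
    alpha = x$alpha,
    family = x$family,
    deviance = x$final_fit$deviance,
    dispersion = x$final_fit$dispersion
  )
}

#' Tidy a permutation-test result
#'
#' @param x An `"ovb_perm"` object.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.ovb_perm <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    observed = x$observed_stat,
    null_mean = x$null_mean,
    p_two_tailed = x$p_two_tailed,
    B = x$B,
    exact = x$exact,
    extremity = x$extremity_rule,
    seed = x$rng_seed
  )
}

#' @rdname tidy.ovb_perm
#' @export
#' @exportS3Method generics::glance
glance.ovb_perm <- function(x, ...) tidy(x)
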