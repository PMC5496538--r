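#' Fit a generalized linear model by iteratively reweighted least squares
#'
#' Fits binomial (logit link), quasi-binomial, Poisson (log link) and
#' quasi-Poisson regressions with the IRLS algorithm: starting from a
#' mean-response initialization, each iteration solves a weighted
#' least-squares problem with working response
#' \eqn{z = \eta + (y - \mu)/\mu'(\eta)} and weights
#' \eqn{W = \mu'(\eta)^2 / V(\mu)}, until the relative change in deviance
#' falls below `tol`. For the quasi families the dispersion is estimated as
#' Pearson \eqn{\chi^2 / } residual df; for binomial and Poisson it is
#' exactly 1. Rank-deficient designs abort naming the aliased term;
#' non-convergence and quasi-complete separation (any coefficient beyond
#' ±15 on the logit scale) are flagged with a warning, never silently
#' returned.
#'
#' @param data A data frame holding the response and predictors. Character
#'   predictors are treated as factors with treatment contrasts and
#'   alphabetical reference level, so sex coded `F`/`H` yields an
#'   "if hermaphrodite" coefficient.
#' @param formula Model formula, e.g. `egg_any ~ sex + flower_depth`.
#' @param family One of `"binomial"`, `"quasibinomial"`, `"poisson"`,
#'   `"quasipoisson"`. Binomial families use the logit link and require a
#'   0/1 response; Poisson families use the log link and require
#'   nonnegative integer responses.
#' @param tol Relative deviance-change convergence tolerance (default 1e-8).
#' @param max_iter Maximum IRLS iterations (default 100).
#'
#' @return An object of class `"ovb_glm"`: coefficients on the link scale,
#'   `deviance`, `null_deviance`, `df_residual`, `dispersion`, `converged`,
#'   `iterations`, `n_obs`, plus the pieces needed for nested-model tests.
#'   Use [tidy()][generics::tidy] / [glance()][generics::glance] for tibble
#'   summaries and [lr_test()] for nested comparisons.
#' @examples
#' plants <- simulate_monitoring(sim_config(n_plants_per_sex = 40))
#' fit <- ovb_glm(plants, egg_any ~ sex + flower_depth + stems, "binomial")
#' tidy(fit)
#' @export
ovb_glm <- function(data, formula,
                    family = c("binomial", "quasibinomial", "poisson",
                               "quasipoisson"),
                    tol = 1e-8, max_iter = 100L) {
  family <- rlang::arg_match(family)
  if (!is.data.frame(data) || nrow(data) == 0) {
    rlang::abort("`data` must be a nonempty data frame.")
  }
  mf <- stats::model.frame(formula, data = data, drop.unused.levels = TRUE)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  check_response(y, family)

  n <- length(y)
  p <- ncol(X)
  binom <- family %in% c("binomial", "quasibinomial")

  # mean-response initialization
  mu <- if (binom) (y + 0.5) / 2 else y + 0.1
  eta <- if (binom) stats::qlogis(mu) else log(mu)
  dev <- glm_deviance(y, mu, binom)
  beta <- rep(0, p)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (binom) {
      w <- mu * (1 - mu)
      z <- eta + (y - mu) / w
    } else {
      w <- mu
      z <- eta + (y - mu) / mu
    }
    sw <- sqrt(w)
    qr_fit <- qr(X * sw)
    if (qr_fit$rank < p) {
      aliased <- colnames(X)[qr_fit$pivot[(qr_fit$rank + 1L):p]]
      rlang::abort(sprintf(
        "Design matrix is rank deficient; aliased term%s: %s.",
        if (length(aliased) > 1) "s" else "", paste(aliased, collapse = ", ")
      ))
    }
    beta <- qr.coef(qr_fit, z * sw)
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- if (binom) stats::plogis(eta) else exp(eta)
    dev_new <- glm_deviance(y, mu, binom)
    if (abs(dev_new - dev) / (abs(dev_new) + 0.1) < tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  if (!converged) {
    rlang::warn(sprintf("IRLS did not converge in %d iterations.", max_iter))
  }
  # slopes beyond +-15 logits flag quasi-complete separation; the intercept
  # is judged more loosely since raw-scale covariates can shift it far
  slope_idx <- which(colnames(X) != "(Intercept)")
  int_idx <- setdiff(seq_len(p), slope_idx)
  separation <- binom && (any(abs(beta[slope_idx]) > 15) ||
                            any(abs(beta[int_idx]) > 25))
  if (separation) {
    rlang::warn("Possible quasi-complete separation: a coefficient exceeds 15 on the logit scale.")
  }
  df_residual <- n - p
  quasi <- family %in% c("quasibinomial", "quasipoisson")
  v_mu <- if (binom) mu * (1 - mu) else mu
  pearson <- sum((y - mu)^2 / v_mu)
  dispersion <- if (quasi) pearson / df_residual else 1
  null_dev <- glm_deviance(y, rep(mean(y), n), binom)

  structure(list(
    coefficients = stats::setNames(drop(beta), colnames(X)),
    deviance = dev,
    null_deviance = null_dev,
    df_residual = df_residual,
    dispersion = dispersion,
    pearson_chisq = pearson,
    converged = converged,
    separation = separation,
    iterations = iter,
    n_obs = n,
    family = family,
    formula = formula,
    terms = attr(stats::terms(formula, data = data), "term.labels"),
    fitted = mu,
    y = y,
    qr = qr_fit,
    weights = w
  ), class = "ovb_glm")
}

check_response <- function(y, family) {
  if (!is.numeric(y) || any(!is.finite(y))) {
    rlang::abort("The response must be numeric and finite.")
  }
  if (family %in% c("binomial", "quasibinomial")) {
    if (!all(y %in% c(0, 1))) {
      rlang::abort("Binomial families require a 0/1 response.")
    }
  } else if (any(y < 0) || any(y != floor(y))) {
    rlang::abort("Poisson families require nonnegative integer responses.")
  }
}

# deviance with 0*log(0) = 0 handled; shared by binomial and Poisson paths
glm_deviance <- function(y, mu, binom) {
  xlogx <- function(a, b) ifelse(a == 0, 0, a * log(a / b))
  if (binom) {
    2 * sum(xlogx(y, mu) + xlogx(1 - y, 1 - mu))
  } else {
    2 * sum(xlogx(y, mu) - (y - mu))
  }
}

#' @export
print.ovb_glm <- function(x, ...) {
  cat(sprintf("<ovb_glm: %s, n = %d>\n", x$family, x$n_obs))
  cat("  ", deparse(x$formula), "\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  deviance %.3f on %d df; dispersion %.3f; %s in %d iterations\n",
              x$deviance, x$df_residual, x$dispersion,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Likelihood-ratio test between nested GLM fits
#'
#' Compares two fits of the same response that differ only in their terms.
#' The chi-square form uses the deviance difference against a
#' \eqn{\chi^2_{\Delta df}} upper tail; the F form — the quasi-likelihood
#' analogue used when a dispersion parameter is estimated — uses
#' \eqn{F = (\Delta D / \Delta df) / \hat\phi} against
#' \eqn{F_{\Delta df,\, df_{res}(full)}}, with \eqn{\hat\phi} the Pearson
#' dispersion of the full model.
#'
#' @param fit_reduced,fit_full `"ovb_glm"` fits on the same data, the
#'   reduced model's terms a subset of the full model's.
#' @param kind `"chisq"` or `"f"`. Defaults to `"f"` for quasi families and
#'   `"chisq"` otherwise.
#' @param term Optional label of the term under test (recorded in the
#'   result).
#' @return A one-row tibble: `term`, `kind`, `statistic`, `df1`, `df2`
#'   (`NA` for chi-square), `p_value`.
#' @examples
#' plants <- simulate_monitoring(sim_config(n_plants_per_sex = 40))
#' f0 <- ovb_glm(plants, egg_any ~ flower_depth, "binomial")
#' f1 <- ovb_glm(plants, egg_any ~ flower_depth + sex, "binomial")
#' lr_test(f0, f1, term = "sex")
#' @export
lr_test <- function(fit_reduced, fit_full, kind = NULL, term = NA_character_) {
  stopifnot(inherits(fit_reduced, "ovb_glm"), inherits(fit_full, "ovb_glm"))
  if (is.null(kind)) {
    kind <- if (fit_full$family %in% c("quasibinomial", "quasipoisson")) {
      "f"
    } else {
      "chisq"
    }
  }
  kind <- rlang::arg_match(kind, c("chisq", "f"))
  if (fit_reduced$n_obs != fit_full$n_obs ||
      !isTRUE(all.equal(unname(fit_reduced$y), unname(fit_full$y)))) {
    rlang::abort("Models must be fitted to the same data.")
  }
  if (fit_reduced$family != fit_full$family) {
    rlang::abort("Models must share one family.")
  }
  if (!all(fit_reduced$terms %in% fit_full$terms)) {
    rlang::abort("Models are not nested: the reduced model has terms absent from the full model.")
  }
  df1 <- fit_reduced$df_residual - fit_full$df_residual
  if (df1 < 0) {
    rlang::abort("The reduced model must have more residual df than the full model.")
  }
  delta <- max(fit_reduced$deviance - fit_full$deviance, 0)
  if (df1 == 0) {
    return(tibble::tibble(term = term, kind = kind, statistic = 0,
                          df1 = 0L, df2 = NA_integer_, p_value = 1))
  }
  if (kind == "chisq") {
    tibble::tibble(
      term = term, kind = kind, statistic = delta, df1 = as.integer(df1),
      df2 = NA_integer_,
      p_value = stats::pchisq(delta, df1, lower.tail = FALSE)
    )
  } else {
    df2 <- fit_full$df_residual
    stat <- (delta / df1) / fit_full$dispersion
    tibble::tibble(
      term = term, kind = kind, statistic = stat, df1 = as.integer(df1),
      df2 = as.integer(df2),
      p_value = stats::pf(stat, df1, df2, lower.tail = FALSE)
    )
  }
}

#' Backward model selection by likelihood-ratio testing
#'
#' Starting from the full model, repeatedly removes the least significant
#' removable term (interactions are always removed before the main effects
#' they contain) whose LR p-value exceeds `alpha`, until every remaining
#' term is significant. Each removed term is then re-tested by comparing
#' the final model against the final model plus that single term, so the
#' reported statistic for a dropped term always refers to adding it to the
#' selected model.
#'
#' @inheritParams ovb_glm
#' @param alpha Retention threshold (default 0.05).
#' @param kind Test kind passed to [lr_test()]; `NULL` picks chi-square for
#'   likelihood families and F for quasi families.
#' @return An object of class `"ovb_backward"`: `final_fit`, character
#'   vector `retained`, tibble `dropped` (term, statistic, dfs, p re-tested
#'   against the final model), tibble `retained_tests`, the step `trace`,
#'   `alpha` and `kind`.
#' @examples
#' plants <- simulate_monitoring(sim_config(n_plants_per_sex = 60))
#' sel <- backward_select(plants,
#'   egg_any ~ open_flowers + stems + height + projected_area +
#'     flower_depth + flower_width + sex, "binomial")
#' sel$retained
#' @export
backward_select <- function(data, formula, family, alpha = 0.05,
                            kind = NULL, tol = 1e-8, max_iter = 100L) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    rlang::abort("`alpha` must be a probability strictly between 0 and 1.")
  }
  response <- deparse(formula[[2]])
  tt <- stats::terms(formula, data = data)
  terms_now <- attr(tt, "term.labels")
  fit_terms <- function(labels) {
    f <- if (length(labels)) {
      stats::reformulate(labels, response)
    } else {
      stats::as.formula(paste(response, "~ 1"))
    }
    ovb_glm(data, f, family, tol = tol, max_iter = max_iter)
  }
  current <- fit_terms(terms_now)
  trace <- list()
  dropped <- character(0)
  repeat {
    cand <- droppable_terms(terms_now)
    if (!length(cand)) break
    tests <- purrr::map_dfr(cand, function(tm) {
      reduced <- fit_terms(setdiff(terms_now, tm))
      lr_test(reduced, current, kind = kind, term = tm)
    })
    worst <- tests[which.max(tests$p_value), ]
    if (worst$p_value <= alpha) break
    terms_now <- setdiff(terms_now, worst$term)
    current <- fit_terms(terms_now)
    dropped <- c(dropped, worst$term)
    trace[[length(trace) + 1L]] <- worst
  }
  # re-test every dropped term against the selected model (final vs final+term)
  dropped_tests <- purrr::map_dfr(dropped, function(tm) {
    augmented <- fit_terms(c(terms_now, tm))
    lr_test(current, augmented, kind = kind, term = tm)
  })
  retained_tests <- purrr::map_dfr(droppable_terms(terms_now), function(tm) {
    reduced <- fit_terms(setdiff(terms_now, tm))
    lr_test(reduced, current, kind = kind, term = tm)
  })
  structure(list(
    final_fit = current,
    retained = terms_now,
    dropped = dropped_tests,
    retained_tests = retained_tests,
    trace = if (length(trace)) dplyr::bind_rows(trace) else tibble::tibble(),
    alpha = alpha,
    kind = if (is.null(kind)) "auto" else kind,
    family = family
  ), class = "ovb_backward")
}

# terms whose removal respects marginality: no other current term contains them
droppable_terms <- function(labels) {
  if (length(labels) <= 1L) return(labels)
  vars <- lapply(strsplit(labels, ":", fixed = TRUE), sort)
  keep <- vapply(seq_along(labels), function(i) {
    !any(vapply(seq_along(labels), function(j) {
      i != j && all(vars[[i]] %in% vars[[j]])
    }, logical(1)))
  }, logical(1))
  labels[keep]
}

#' @export
print.ovb_backward <- function(x, ...) {
  cat("<ovb_backward selection>\n")
  cat("  retained:", if (length(x$retained)) paste(x$retained, collapse = ", ")
      else "(intercept only)", "\n")
  if (nrow(x$dropped)) {
    cat("  dropped (re-tested against the final model):\n")
    print(x$dropped)
  }
  invisible(x)
}

#' Multiplicative-effect table for a log- or logit-link fit
#'
#' Pairs each coefficient with its exponential: on a log link a one-unit
#' increase in the predictor multiplies the expected response by
#' `exp(coefficient)`; on a logit link it multiplies the odds.
#'
#' @param fit An `"ovb_glm"` fit.
#' @return A tibble: `term`, `estimate`, `exp_estimate`.
#' @examples
#' exp(0.029)   # 1.029: +1 flower multiplies expected fruits by 1.029
#' @export
exponentiate_report <- function(fit) {
  stopifnot(inherits(fit, "ovb_glm"))
  tibble::tibble(
    term = names(fit$coefficients),
    estimate = unname(fit$coefficients),
    exp_estimate = exp(unname(fit$coefficients))
  )
}

#' Test for a sex difference in egg number among egg-receiving units
#'
#' Restricts the data to units that received at least one egg and compares
#' Poisson log-link models of the egg count with and without the sex term.
#' This asks whether, given that oviposition happened, one sex accumulates
#' more eggs — a different question from whether oviposition itself is
#' sex-biased.
#'
#' @param data A data frame with a sex column coded `F`/`H`.
#' @param eggs Column holding the egg count (tidy-eval).
#' @param kind Test kind for [lr_test()] (default chi-square).
#' @return A one-row tibble as from [lr_test()], with an `n` column for the
#'   egg-receiving subset size.
#' @export
eggs_given_receipt_test <- function(data, eggs, kind = "chisq") {
  counts <- dplyr::pull(data, {{ eggs }})
  sub <- data[counts > 0, , drop = FALSE]
  sub$.eggs <- counts[counts > 0]
  if (length(unique(sub$sex)) < 2L) {
    rlang::abort("Degenerate subset: only one sex among egg-receiving units.")
  }
  if (stats::var(sub$.eggs) == 0) {
    rlang::warn("Zero-variance egg counts among egg-receiving units; the test is uninformative.")
  }
  f0 <- ovb_glm(sub, .eggs ~ 1, "poisson")
  f1 <- ovb_glm(sub, .eggs ~ sex, "poisson")
  dplyr::mutate(lr_test(f0, f1, kind = kind, term = "sex"),
                n = nrow(sub), .before = 1)
}
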