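# Independent oracles used across the suite. These deliberately avoid the
# implementation paths they check.

# Clopper-Pearson endpoints by bisection on the binomial tail probabilities:
# lower solves P(X >= x | p) = alpha/2, upper solves P(X <= x | p) = alpha/2.
ci_bisect_oracle <- function(x, n, level = 0.95, tol = 1e-12) {
  alpha <- 1 - level
  bisect <- function(f, lo, hi) {
    for (i in 1:100) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  lower <- if (x == 0) 0 else {
    bisect(function(p) (1 - pbinom(x - 1, n, p)) - alpha / 2, 0, 1)
  }
  upper <- if (x == n) 1 else {
    bisect(function(p) alpha / 2 - pbinom(x, n, p), 0, 1)
  }
  c(lower = lower, upper = upper)
}

# Exhaustive enumeration of the single-population flower permutation null:
# every distinct placement of k eggs among n flowers, statistic = eggs on
# hermaphrodite flowers. Returns the doubled-tail p for the observed value.
perm_enum_oracle <- function(herm, k, observed, extremity = "strict") {
  n <- length(herm)
  placements <- utils::combn(n, k)
  stats <- apply(placements, 2, function(idx) sum(herm[idx]))
  probs <- rep(1 / length(stats), length(stats))
  center <- mean(stats)
  d <- observed - center
  if (d == 0) return(list(p = 1, stats = stats))
  hit <- if (d > 0) {
    if (extremity == "strict") stats > observed else stats >= observed
  } else {
    if (extremity == "strict") stats < observed else stats <= observed
  }
  list(p = min(1, 2 * sum(probs[hit])), stats = stats)
}

# Exhaustive sign-flip null for paired differences via bit masks (a
# different enumeration scheme from the implementation's doubling
# recursion). Returns the doubled-tail p around 0.
signflip_enum_oracle <- function(d, extremity = "strict") {
  n <- length(d)
  masks <- 0:(2^n - 1)
  stats <- vapply(masks, function(m) {
    signs <- ifelse(bitwAnd(m, 2^(seq_len(n) - 1)) > 0, -1, 1)
    mean(signs * d)
  }, numeric(1))
  obs <- mean(d)
  eps <- 1e-12 * max(1, abs(obs))
  if (abs(obs) <= eps) return(list(p = 1, stats = stats))
  hit <- if (obs > 0) {
    if (extremity == "strict") stats > obs + eps else stats >= obs - eps
  } else {
    if (extremity == "strict") stats < obs - eps else stats <= obs + eps
  }
  list(p = min(1, 2 * mean(hit)), stats = stats)
}

# Direct likelihood maximization for binomial-logit / Poisson-log models,
# independent of IRLS: BFGS on the (negative) log-likelihood.
glm_optim_oracle <- function(X, y, family = c("binomial", "poisson")) {
  family <- match.arg(family)
  negll <- function(beta) {
    eta <- drop(X %*% beta)
    if (family == "binomial") {
      -sum(y * eta - log1p(exp(eta)))
    } else {
      -sum(y * eta - exp(eta))
    }
  }
  grad <- function(beta) {
    eta <- drop(X %*% beta)
    mu <- if (family == "binomial") plogis(eta) else exp(eta)
    -drop(crossprod(X, y - mu))
  }
  fit <- optim(rep(0, ncol(X)), negll, grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  fit$par
}

# small deterministic survey builder for permutation edge cases
make_flowers <- function(herm, egg, population = "p1") {
  tibble::tibble(
    population = population,
    stem_id = sprintf("s%03d", seq_along(herm)),
    sex = ifelse(herm, "H", "F"),
    egg = as.integer(egg)
  )
}
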