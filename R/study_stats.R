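#' Inverse relation between poison-exon usage and expression
#'
#' Spearman rank correlation between per-timepoint usage and normalised
#' expression, with a two-sided permutation p-value (expression labels
#' permuted, seeded). The developmental signature of a regulatory poison
#' exon is a strongly negative rho: inclusion falls as functional output
#' rises.
#'
#' @param table Data frame with one row per sample/timepoint.
#' @param usage,expression Columns holding the two series (tidy-eval;
#'   defaults `usage_percent`, `expression`).
#' @param n_perm Number of label permutations (>= 10000 recommended).
#' @param seed Integer seed for the permutations.
#' @return One-row tibble: `rho` (NA with a warning when either series is
#'   constant), `p_perm` (NA when n < 4), `n`, `n_perm`.
#' @export
inverse_relation <- function(table, usage = usage_percent,
                             expression = expression,
                             n_perm = 10000L, seed = NULL) {
  u <- dplyr::pull(table, {{ usage }})
  e <- dplyr::pull(table, {{ expression }})
  ok <- complete.cases(u, e)
  u <- u[ok]
  e <- e[ok]
  n <- length(u)
  if (n < 2 || sd(u) == 0 || sd(e) == 0) {
    warn("correlation undefined (fewer than 2 pairs or a constant series)")
    return(tibble(rho = NA_real_, p_perm = NA_real_, n = n, n_perm = 0L))
  }
  rho <- cor(u, e, method = "spearman")
  if (n < 4) {
    return(tibble(rho = rho, p_perm = NA_real_, n = n, n_perm = 0L))
  }
  perm <- function() {
    hits <- sum(vapply(seq_len(n_perm), function(i) {
      abs(cor(u, sample(e), method = "spearman")) >= abs(rho) - 1e-12
    }, logical(1)))
    (hits + 1) / (n_perm + 1)
  }
  p <- if (is.null(seed)) perm() else withr::with_seed(seed, perm())
  tibble(rho = rho, p_perm = p, n = n, n_perm = as.integer(n_perm))
}

#' Mann-Kendall monotone trend test
#'
#' `S` is the sum over ordered pairs of `sign(y_j - y_i) * sign(x_j - x_i)`
#' against ordinal age `x`. For n <= 10 with no ties the two-sided p-value
#' is exact, from the permutation-null distribution of S computed by the
#' inversion-count recursion; otherwise the tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param y Values in which the trend is sought (e.g. usage percent).
#' @param x Ordinal age/time; defaults to observation order.
#' @return One-row tibble: `S`, `n`, `p`, `method`.
#' @export
#' @examples
#' trend_test(c(70, 55, 30, 18, 10, 8)) # S = -15
trend_test <- function(y, x = seq_along(y)) {
  stopifnot(length(y) == length(x))
  n <- length(y)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sgn <- sign(y[pairs[, 2]] - y[pairs[, 1]]) * sign(x[pairs[, 2]] - x[pairs[, 1]])
  S <- sum(sgn)
  ties_y <- any(duplicated(y))
  ties_x <- any(duplicated(x))
  if (n <= 10 && !ties_y && !ties_x) {
    p <- mk_exact_p(S, n)
    method <- "exact"
  } else {
    tie_term <- function(v) {
      t <- table(v)
      sum(t * (t - 1) * (2 * t + 5))
    }
    v <- (n * (n - 1) * (2 * n + 5) - tie_term(y) - tie_term(x)) / 18
    if (v <= 0) {
      p <- 1
    } else {
      z <- (S - sign(S)) / sqrt(v)
      p <- 2 * pnorm(-abs(z))
    }
    method <- "normal"
  }
  tibble(S = S, n = n, p = min(p, 1), method = method)
}

# exact two-sided p for Mann-Kendall S at sample size n (no ties):
# S = C(n,2) - 2 * inversions; inversion counts come from the generating
# function prod_{i=1..n} (1 + x + ... + x^(i-1))
mk_exact_p <- function(S, n) {
  counts <- 1
  for (i in seq_len(n)[-1]) {
    new <- numeric(length(counts) + i - 1)
    for (j in 0:(i - 1)) {
      idx <- seq_along(counts) + j
      new[idx] <- new[idx] + counts
    }
    counts <- new
  }
  k <- seq_along(counts) - 1
  s_vals <- choose(n, 2) - 2 * k
  sum(counts[abs(s_vals) >= abs(S)]) / sum(counts)
}

#' Chi-square goodness of fit to a Mendelian ratio
#'
#' `chisq = sum((O - E)^2 / E)` with expected counts from the stated ratio,
#' `df = k - 1`, upper-tail p.
#'
#' @param observed Integer counts per genotype class.
#' @param ratio Expected ratio (same length), e.g. `c(1, 1)`.
#' @return One-row tibble: `chisq`, `df`, `p`.
#' @export
#' @examples
#' mendelian_gof(c(20, 53), c(1, 1)) # chisq ~ 14.92
mendelian_gof <- function(observed, ratio = rep(1, length(observed))) {
  stopifnot(length(observed) == length(ratio), all(observed >= 0), all(ratio > 0))
  expected <- sum(observed) * ratio / sum(ratio)
  chisq <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1
  tibble(chisq = chisq, df = df, p = pchisq(chisq, df, lower.tail = FALSE))
}

#' Kaplan-Meier product-limit estimator
#'
#' `S(t)` multiplies `(1 - d_i / n_i)` over event times up to `t`;
#' censoring removes subjects from the risk set without a step. With no
#' censoring the estimator equals the empirical survival function.
#'
#' @param data Data frame of survival records.
#' @param time,event,group Columns (tidy-eval): follow-up time, event
#'   indicator (1 = death, 0 = censored), optional grouping.
#' @return An object of class `km_fit`: a tibble with one row per distinct
#'   observed time (per group): `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`.
#' @export
kaplan_meier <- function(data, time = time_months, event = event,
                         group = NULL) {
  t_vals <- dplyr::pull(data, {{ time }})
  e_vals <- dplyr::pull(data, {{ event }})
  g_quo <- enquo(group)
  g_vals <- if (quo_is_null(g_quo)) {
    rep("all", length(t_vals))
  } else {
    as.character(dplyr::pull(data, !!g_quo))
  }
  stopifnot(all(t_vals >= 0), all(e_vals %in% c(0, 1)))
  out <- purrr::map_dfr(unique(g_vals), function(g) {
    tt <- t_vals[g_vals == g]
    ee <- e_vals[g_vals == g]
    times <- sort(unique(tt))
    n_risk <- vapply(times, function(u) sum(tt >= u), numeric(1))
    n_event <- vapply(times, function(u) sum(tt == u & ee == 1), numeric(1))
    n_censor <- vapply(times, function(u) sum(tt == u & ee == 0), numeric(1))
    surv <- cumprod(1 - n_event / n_risk)
    tibble(
      group = g, time = times, n_risk = n_risk, n_event = n_event,
      n_censor = n_censor, survival = surv
    )
  })
  structure(out, class = c("km_fit", class(out)))
}

#' Mantel-Cox (unweighted) log-rank test for two groups
#'
#' At each pooled event time the observed group-1 deaths are compared with
#' the hypergeometric expectation given the risk sets; the statistic is
#' `(O - E)^2 / V` referred to chi-square with 1 df.
#'
#' @inheritParams kaplan_meier
#' @param group Grouping column (exactly two groups).
#' @return One-row tibble: `statistic`, `df`, `p`, `o_minus_e`
#'   (group-1 observed minus expected deaths), `var`.
#' @export
logrank <- function(data, time = time_months, event = event, group = genotype) {
  t_vals <- dplyr::pull(data, {{ time }})
  e_vals <- dplyr::pull(data, {{ event }})
  g_vals <- as.character(dplyr::pull(data, {{ group }}))
  groups <- sort(unique(g_vals))
  if (length(groups) != 2) {
    abort("logrank requires exactly two groups", class = "pexquant_input_error")
  }
  is1 <- g_vals == groups[1]
  times <- sort(unique(t_vals[e_vals == 1]))
  o_minus_e <- 0
  v <- 0
  for (u in times) {
    at_risk <- t_vals >= u
    n_t <- sum(at_risk)
    n_1t <- sum(at_risk & is1)
    d_t <- sum(t_vals == u & e_vals == 1)
    d_1t <- sum(t_vals == u & e_vals == 1 & is1)
    o_minus_e <- o_minus_e + d_1t - d_t * n_1t / n_t
    if (n_t > 1) {
      v <- v + d_t * (n_1t / n_t) * (1 - n_1t / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  stat <- if (v > 0) o_minus_e^2 / v else 0
  tibble(
    statistic = stat, df = 1L, p = pchisq(stat, 1, lower.tail = FALSE),
    o_minus_e = o_minus_e, var = v
  )
}
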