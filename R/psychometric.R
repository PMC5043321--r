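#' Logistic psychometric function
#'
#' Probability of a correct choice at stimulus level x in a two-alternative
#' task:
#' \deqn{\psi(x) = \gamma + (1 - \gamma - \lambda) \frac{1}{1 + e^{(a-x)/b}}}
#' where gamma is the guess rate (lower asymptote, 0.5 for two alternatives),
#' lambda the lapse rate (1 minus the upper asymptote), a the position and
#' b > 0 the steepness scale.
#'
#' @param x Stimulus level(s).
#' @param a Position parameter.
#' @param b Steepness scale (> 0).
#' @param gamma Guess rate.
#' @param lapse Lapse rate.
#' @return Probabilities in `[gamma, 1 - lapse]`.
#' @export
psi <- function(x, a, b, gamma = 0.5, lapse = 0) {
  if (b <= 0) stop("steepness b must be positive", call. = FALSE)
  gamma + (1 - gamma - lapse) * stats::plogis((x - a) / b)
}

#' Binomially justified threshold criterion
#'
#' Smallest number of correct choices k out of n whose one-tailed binomial
#' tail probability P(X >= k | n, p0) falls below `alpha`; the corresponding
#' proportion k/n is the performance criterion at which thresholds are read
#' off the psychometric function. For n = 30 at chance 0.5 and alpha 0.05
#' this gives 20/30 = 66.7%.
#'
#' @param n Trials per level.
#' @param p0 Chance rate.
#' @param alpha One-tailed significance level.
#' @return List with `k_min` and `proportion`.
#' @export
binomial_criterion <- function(n, p0 = 0.5, alpha = 0.05) {
  if (n < 1 || p0 <= 0 || p0 >= 1 || alpha <= 0 || alpha >= 1)
    stop("need n >= 1, 0 < p0 < 1, 0 < alpha < 1", call. = FALSE)
  k <- 0:n
  tail <- 1 - stats::pbinom(k - 1, n, p0) # P(X >= k)
  ok <- which(tail < alpha)
  if (length(ok) == 0L)
    stop(sprintf("criterion unattainable: even %d/%d has tail probability %.3g >= %g",
                 n, n, tail[n + 1L], alpha), call. = FALSE)
  k_min <- k[ok[1L]]
  list(k_min = k_min, proportion = k_min / n)
}

#' Aggregate per-trial choice data to per-level counts
#'
#' @param df Data frame with columns `level` and `choice_correct` (0/1), or
#'   already-aggregated columns `level`, `n_trials`, `n_correct`.
#' @return Data frame with columns `level`, `n_trials`, `n_correct`.
#' @export
aggregate_trials <- function(df) {
  if (all(c("n_trials", "n_correct") %in% names(df))) {
    out <- df[, c("level", "n_trials", "n_correct")]
  } else if ("choice_correct" %in% names(df)) {
    agg <- stats::aggregate(choice_correct ~ level, data = df,
                            FUN = function(v) c(n = length(v), k = sum(v)))
    out <- data.frame(level = agg$level,
                      n_trials = agg$choice_correct[, "n"],
                      n_correct = agg$choice_correct[, "k"])
  } else {
    stop("data must have columns (level, n_trials, n_correct) or (level, choice_correct)",
         call. = FALSE)
  }
  if (any(out$n_correct > out$n_trials) || any(out$n_trials < 1))
    stop("n_correct must be between 0 and n_trials", call. = FALSE)
  out[order(out$level), , drop = FALSE]
}

psy_nll <- function(theta, level, n, k, gamma) {
  p <- psi(level, theta[1L], theta[2L], gamma, theta[3L])
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(k * log(p) + (n - k) * log(1 - p))
}

#' Fit the psychometric function by maximum likelihood
#'
#' Maximizes the binomial log-likelihood over (a, b, lapse) with the lapse
#' rate box-bounded and the guess rate fixed. A multi-start grid over
#' position (quantiles of the level range) and steepness (a decade around
#' the median level spacing) guards against the flat-likelihood local optima
#' that plague sparse 2AFC data. Levels with no performance significantly
#' above chance are flagged: if no level clears the one-tailed binomial
#' test the fit is reported unconverged with no threshold; if only the
#' highest level clears it, the threshold is set to that level with a
#' `"ceiling"` flag.
#'
#' @param data Per-level data accepted by [aggregate_trials()].
#' @param gamma Fixed guess rate.
#' @param lapse_max Upper bound of the lapse rate.
#' @param criterion Correct-choice proportion at which to read off the
#'   threshold; `"auto"` (default) derives it from the per-level trial count
#'   via [binomial_criterion()].
#' @param alpha Significance level for `"auto"` and for the above-chance
#'   screen.
#' @return An object of class `psychometric_fit`: `a`, `b`, `lapse`,
#'   `gamma`, `loglik`, `converged`, `criterion`, `threshold`, `flag`
#'   (`"ok"`, `"ceiling"`, `"no_signal"`, or `"criterion_unattainable"`) and
#'   the aggregated `data`.
#' @export
fit_psychometric <- function(data, gamma = 0.5, lapse_max = 0.25,
                             criterion = "auto", alpha = 0.05) {
  d <- aggregate_trials(data)
  if (length(unique(d$level)) < 3L)
    stop("need at least 3 distinct stimulus levels", call. = FALSE)

  if (identical(criterion, "auto")) {
    n_mode <- as.numeric(names(sort(table(d$n_trials), decreasing = TRUE))[1L])
    criterion <- binomial_criterion(n_mode, gamma, alpha)$proportion
  }
  if (criterion <= gamma || criterion >= 1)
    stop("criterion must lie in (gamma, 1)", call. = FALSE)

  # per-level one-tailed binomial screen against chance
  above <- vapply(seq_len(nrow(d)), function(i) {
    1 - stats::pbinom(d$n_correct[i] - 1, d$n_trials[i], gamma) < alpha
  }, logical(1))

  # multi-start bounded MLE
  rng <- range(d$level)
  spread <- max(diff(rng), 1e-6)
  a0s <- seq(rng[1L], rng[2L], length.out = 5L)
  b0s <- stats::median(diff(sort(unique(d$level)))) * c(0.1, 0.3, 1, 3, 10)
  best <- NULL
  for (a0 in a0s) for (b0 in b0s) {
    fit <- tryCatch(
      stats::optim(c(a0, b0, 0.02), psy_nll,
                   level = d$level, n = d$n_trials, k = d$n_correct,
                   gamma = gamma, method = "L-BFGS-B",
                   lower = c(rng[1L] - 5 * spread, 1e-4 * spread, 0),
                   upper = c(rng[2L] + 5 * spread, 100 * spread, lapse_max),
                   control = list(maxit = 500L, factr = 1e5)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("all optimizer starts failed", call. = FALSE)

  a <- best$par[1L]; b <- best$par[2L]; lapse <- best$par[3L]
  loglik <- -best$value
  converged <- best$convergence == 0

  flag <- "ok"
  threshold <- NA_real_
  if (!any(above)) {
    converged <- FALSE
    flag <- "no_signal"
  } else if (sum(above) == 1L && above[nrow(d)]) {
    threshold <- d$level[nrow(d)]
    flag <- "ceiling"
  } else if (criterion >= 1 - lapse) {
    flag <- "criterion_unattainable"
  } else {
    threshold <- a - b * log((1 - gamma - lapse) / (criterion - gamma) - 1)
  }

  structure(list(a = a, b = b, lapse = lapse, gamma = gamma,
                 loglik = loglik, converged = converged,
                 criterion = criterion, threshold = threshold,
                 flag = flag, data = d),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> a=%.3f b=%.3f lapse=%.3f (gamma=%.2f)\n",
              x$a, x$b, x$lapse, x$gamma))
  cat(sprintf("  logLik %.3f, %s, threshold at %.1f%%: %s (%s)\n",
              x$loglik, if (x$converged) "converged" else "NOT converged",
              100 * x$criterion,
              if (is.na(x$threshold)) "undefined" else sprintf("%.3f", x$threshold),
              x$flag))
  invisible(x)
}

#' Threshold level at a performance criterion
#'
#' Closed-form inverse of the logistic psychometric function:
#' \eqn{x^* = a - b \ln\left(\frac{1-\gamma-\lambda}{c-\gamma} - 1\right)}.
#'
#' @param fit A `psychometric_fit` (or a list with `a`, `b`, `gamma`,
#'   `lapse`).
#' @param criterion Correct-choice proportion, strictly between `gamma` and
#'   `1 - lapse`.
#' @return Stimulus level at which the fitted function crosses `criterion`.
#' @export
threshold_from_fit <- function(fit, criterion) {
  if (criterion <= fit$gamma || criterion >= 1 - fit$lapse)
    stop(sprintf("criterion %.4f is unattainable: fitted curve spans (%g, %g)",
                 criterion, fit$gamma, 1 - fit$lapse), call. = FALSE)
  fit$a - fit$b * log((1 - fit$gamma - fit$lapse) / (criterion - fit$gamma) - 1)
}

rank_sum_stat <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)])
}

#' Compare two groups of thresholds by Wilcoxon rank-sum
#'
#' Two-sided rank-sum test. For combined sample sizes up to 12 the p-value
#' is exact by enumeration of all group assignments (handling ties through
#' mid-ranks, so identical groups give p = 1); larger samples use the
#' normal approximation of [stats::wilcox.test()].
#'
#' @param thresholds_a,thresholds_b Numeric vectors (>= 2 values each).
#' @return List with `rank_sum` (sum of ranks of group A in the combined
#'   sample) and `p_value`.
#' @export
compare_conditions <- function(thresholds_a, thresholds_b) {
  if (length(thresholds_a) < 2L || length(thresholds_b) < 2L)
    stop("need at least 2 thresholds per group", call. = FALSE)
  na <- length(thresholds_a); nb <- length(thresholds_b)
  w_obs <- rank_sum_stat(thresholds_a, thresholds_b)
  if (na + nb <= 12L) {
    pooled <- c(thresholds_a, thresholds_b)
    r <- rank(pooled)
    mu <- na * (na + nb + 1) / 2
    combos <- utils::combn(na + nb, na)
    ws <- apply(combos, 2L, function(idx) sum(r[idx]))
    p <- mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(thresholds_a, thresholds_b,
                                              exact = FALSE, correct = TRUE))
    p <- wt$p.value
  }
  list(rank_sum = w_obs, p_value = p)
}
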