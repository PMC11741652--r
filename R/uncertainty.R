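# Beta-distribution fitting to (median, 95% CI) summaries, Monte Carlo
# propagation of uncertainty through pipeline quantities, and
# Boole-Frechet bounds that hold under arbitrary dependence.

#' Fit a beta distribution to a median and 95% CI
#'
#' Finds shape parameters `(alpha, beta)` whose 2.5%, 50% and 97.5%
#' quantiles best match the reported summary, by minimizing the sum of
#' squared differences between the beta CDF evaluated at the three
#' reported values and the target levels (0.025, 0.5, 0.975).
#' Optimization is Nelder-Mead on log-shapes from a method-of-moments
#' start (mean near the median, sd of width/3.92), with a coarse
#' log-grid restart if the local search stalls. Summaries touching the
#' boundary (e.g. a specificity of 100% with CI 98--100%) have their
#' quantile targets clipped into `[1e-4, 1 - 1e-4]` before fitting,
#' since a proper beta distribution cannot place a quantile exactly at
#' 0 or 1.
#'
#' @param median,lo,hi The reported median and 95% CI bounds, all in
#'   \[0, 1\] with `lo <= median <= hi` and `hi > lo`.
#' @return An object of class `beta_shape`: a list with `alpha`, `beta`,
#'   and `residual` (the attained objective value).
#' @examples
#' fit_beta(0.748, 0.676, 0.808)
#' @export
fit_beta <- function(median, lo, hi) {
  check_prob(median, "median"); check_prob(lo, "lo"); check_prob(hi, "hi")
  if (!(lo <= median && median <= hi))
    stop("need lo <= median <= hi", call. = FALSE)
  if (hi <= lo)
    stop("zero-width CI: treat the quantity as a fixed constant instead of fitting",
         call. = FALSE)
  eps <- 1e-4
  targets <- pmin(pmax(c(lo, median, hi), eps), 1 - eps)
  levels <- c(0.025, 0.5, 0.975)
  obj <- function(logab) {
    a <- exp(logab[1]); b <- exp(logab[2])
    sum((stats::pbeta(targets, a, b) - levels)^2)
  }
  mu <- min(max(median, eps), 1 - eps)
  sd0 <- max((hi - lo) / 3.92, 1e-3)
  nu <- max(mu * (1 - mu) / sd0^2 - 1, 0.1)
  start <- log(c(mu * nu, (1 - mu) * nu))
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (fit$value > 1e-4) {
    grid <- expand.grid(a = seq(-2, 8, by = 1), b = seq(-2, 8, by = 1))
    vals <- apply(grid, 1L, obj)
    alt <- stats::optim(as.numeric(grid[which.min(vals), ]), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (alt$value < fit$value) fit <- alt
  }
  structure(list(alpha = exp(fit$par[1]), beta = exp(fit$par[2]),
                 residual = fit$value),
            class = "beta_shape")
}

#' @export
print.beta_shape <- function(x, ...) {
  cat(sprintf("<beta_shape> alpha = %.4g, beta = %.4g (fit residual %.3g)\n",
              x$alpha, x$beta, x$residual))
  invisible(x)
}

#' Monte Carlo propagation of (median, 95% CI) uncertainty
#'
#' Draws independent beta samples for every uncertain input (a
#' `c(median, lo, hi)` triple, fitted with [fit_beta()]), passes fixed
#' scalars through unchanged, evaluates the pipeline quantity on each
#' draw, and summarizes the result by its empirical median and
#' 2.5%/97.5% percentiles. Each test characteristic is sampled
#' independently of the others. Identical seeds give bit-identical
#' summaries. Draws on which the quantity is undefined (`NA`/`NaN`/
#' infinite, e.g. a vanishing Rogan-Gladen denominator) are discarded
#' and counted; the summary is flagged when discards exceed 1%.
#'
#' @param fn A vectorized function of the named inputs: it receives each
#'   input as a numeric vector of length `n_samples` and must return a
#'   numeric vector of the same length.
#' @param inputs Named list; each element is either a single numeric
#'   (a fixed constant) or a numeric triple `c(median, lo, hi)` (an
#'   uncertain quantity). A triple with `lo == hi == median` is treated
#'   as a constant.
#' @param n_samples Number of Monte Carlo samples (>= 1000).
#' @param seed Integer seed.
#' @return An object of class `credible_summary`: a list with `median`,
#'   `lo`, `hi`, `n_samples`, `n_discarded`, `flagged`, `seed`.
#' @examples
#' cs <- mc_propagate(function(p, q) p * q,
#'                    list(p = c(0.9, 0.85, 0.95), q = 0.5),
#'                    n_samples = 1000, seed = 7)
#' @export
mc_propagate <- function(fn, inputs, n_samples = 1e5, seed = 1L) {
  stopifnot(is.function(fn), is.list(inputs), length(inputs) > 0,
            !is.null(names(inputs)), all(nzchar(names(inputs))))
  if (n_samples < 1000)
    stop("`n_samples` must be at least 1000", call. = FALSE)
  n_samples <- as.integer(n_samples)
  set.seed(as.integer(seed))
  draws <- lapply(inputs, function(x) {
    if (length(x) == 1L) return(rep(x, n_samples))
    if (length(x) != 3L)
      stop("each input must be a single constant or a c(median, lo, hi) triple",
           call. = FALSE)
    if (x[2] == x[3]) return(rep(x[1], n_samples))  # zero-width CI
    sh <- fit_beta(x[1], x[2], x[3])
    stats::rbeta(n_samples, sh$alpha, sh$beta)
  })
  vals <- do.call(fn, draws)
  if (!is.numeric(vals) || length(vals) != n_samples)
    stop("`fn` must return one numeric value per draw", call. = FALSE)
  bad <- !is.finite(vals)
  vals <- vals[!bad]
  if (length(vals) == 0L)
    stop("the quantity was undefined on every draw", call. = FALSE)
  q <- stats::quantile(vals, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  structure(list(median = q[2], lo = q[1], hi = q[3],
                 n_samples = n_samples, n_discarded = sum(bad),
                 flagged = sum(bad) > 0.01 * n_samples,
                 seed = as.integer(seed)),
            class = "credible_summary")
}

#' @export
print.credible_summary <- function(x, ...) {
  cat(sprintf("<credible_summary> median %.4g (95%% CI %.4g--%.4g), n = %d%s\n",
              x$median, x$lo, x$hi, x$n_samples,
              if (x$n_discarded > 0)
                sprintf(", %d draws discarded%s", x$n_discarded,
                        if (x$flagged) " [FLAGGED >1%]" else "")
              else ""))
  invisible(x)
}

#' Boole-Frechet bounds on aggregated characteristics
#'
#' Best-possible bounds on the sensitivity and specificity of AND, OR,
#' and majority aggregations given only the marginal characteristics of
#' the individual tests, with no assumption on their dependence
#' structure. For AND:
#' `max(0, sum(tpr_i) - (n-1)) <= tpr_and <= min(tpr_i)` and
#' `max(tnr_i) <= tnr_and <= min(1, sum(tnr_i))`; OR mirrors these with
#' the roles of the two characteristics exchanged; the majority rule
#' (odd `n`) satisfies the union span
#' `max(0, sum - (n-1)) <= . <= min(1, sum)` in both coordinates. The
#' conditional-independence closed forms always lie inside these
#' intervals.
#'
#' @param profiles List of [test_profile]s.
#' @param family `"and"`, `"or"`, or `"majority"`.
#' @return A list with elements `tpr` and `tnr`, each a
#'   `c(lo = ..., hi = ...)` probability interval.
#' @export
frechet_bounds <- function(profiles, family = c("and", "or", "majority")) {
  profiles <- check_profiles(profiles)
  family <- match.arg(tolower(family), c("and", "or", "majority"))
  n <- length(profiles)
  tprs <- vapply(profiles, `[[`, numeric(1), "tpr")
  tnrs <- vapply(profiles, `[[`, numeric(1), "tnr")
  lower_fr <- function(x) max(0, sum(x) - (n - 1))
  upper_fr <- function(x) min(1, sum(x))
  interval <- function(lo, hi) c(lo = lo, hi = hi)
  out <- switch(family,
    and = list(tpr = interval(lower_fr(tprs), min(tprs)),
               tnr = interval(max(tnrs), upper_fr(tnrs))),
    or = list(tpr = interval(max(tprs), upper_fr(tprs)),
              tnr = interval(lower_fr(tnrs), min(tnrs))),
    majority = {
      if (n %% 2L == 0L)
        stop("majority bounds require an odd number of tests", call. = FALSE)
      list(tpr = interval(lower_fr(tprs), upper_fr(tprs)),
           tnr = interval(lower_fr(tnrs), upper_fr(tnrs)))
    })
  out
}
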