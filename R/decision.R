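# Prevalence-dependent decision measures (PPV/NPV) and the test economy
# of series versus parallel administration.

# Internal: accept either an aggregate_characteristics object or a
# test_profile and return list(tpr, tnr).
char_of <- function(x) {
  if (inherits(x, "aggregate_characteristics") || inherits(x, "test_profile"))
    return(list(tpr = x$tpr, tnr = x$tnr))
  stop("expected an aggregate_characteristics or test_profile object",
       call. = FALSE)
}

#' Positive predictive value
#'
#' The probability that a subject with a positive (aggregated) call truly
#' has the condition, at prevalence `f`:
#' `PPV = f * tpr / (f * tpr + (1 - f) * (1 - tnr))`. Increasing in `f`.
#'
#' @param f Prevalence, a probability.
#' @param agg An `aggregate_characteristics` (or single [test_profile]).
#' @return The PPV.
#' @export
ppv <- function(f, agg) {
  check_prob(f, "f")
  ch <- char_of(agg)
  denom <- f * ch$tpr + (1 - f) * (1 - ch$tnr)
  if (denom == 0)
    stop("PPV undefined: the protocol makes no positive calls at this prevalence",
         call. = FALSE)
  f * ch$tpr / denom
}

#' Negative predictive value
#'
#' The probability that a subject with a negative call truly lacks the
#' condition: `NPV = (1 - f) * tnr / ((1 - f) * tnr + f * (1 - tpr))`.
#' Decreasing in `f`.
#'
#' @inheritParams ppv
#' @return The NPV.
#' @export
npv <- function(f, agg) {
  check_prob(f, "f")
  ch <- char_of(agg)
  denom <- (1 - f) * ch$tnr + f * (1 - ch$tpr)
  if (denom == 0)
    stop("NPV undefined: the protocol makes no negative calls at this prevalence",
         call. = FALSE)
  (1 - f) * ch$tnr / denom
}

#' Prevalence at which PPV and NPV cross
#'
#' Setting PPV equal to NPV gives
#' `f^2 * tpr(1 - tpr) = (1 - f)^2 * tnr(1 - tnr)`, so the crossover sits
#' at `f* = sqrt(tnr(1 - tnr)) / (sqrt(tnr(1 - tnr)) + sqrt(tpr(1 - tpr)))`
#' and `PPV >= NPV` exactly when `f >= f*`. For `tpr = tnr` the crossover
#' is at 0.5 by symmetry; a perfectly specific protocol (`tnr = 1`)
#' gives 0.
#'
#' @param agg An `aggregate_characteristics` (or single [test_profile]).
#' @return The crossover prevalence.
#' @export
ppv_npv_crossover <- function(agg) {
  ch <- char_of(agg)
  num <- sqrt(ch$tnr * (1 - ch$tnr))
  denom <- num + sqrt(ch$tpr * (1 - ch$tpr))
  if (denom == 0)
    stop("PPV/NPV crossover undefined for a protocol with tpr and tnr both in {0, 1}",
         call. = FALSE)
  num / denom
}

#' Does AND-PPV dominate OR-PPV for all prevalences?
#'
#' For two tests, the PPV of the AND rule dominates that of the OR rule
#' at every prevalence iff
#' `(tpr1 + tpr2) / (tpr1 * tpr2) <= ((1-tnr1) + (1-tnr2)) / ((1-tnr1) * (1-tnr2))`;
#' the NPV ordering (`NPV_and <= NPV_or` for all f) holds under the
#' mirrored condition with TPR and TNR swapped. Both conditions are
#' always satisfied when both tests have discriminatory power.
#'
#' @param p1,p2 [test_profile] objects.
#' @return A logical vector `c(ppv = ..., npv = ...)`: whether each
#'   ordering holds for all prevalences.
#' @export
ppv_ordering_holds <- function(p1, p2) {
  stopifnot(inherits(p1, "test_profile"), inherits(p2, "test_profile"))
  lhs_ppv <- (p1$tpr + p2$tpr) / (p1$tpr * p2$tpr)
  rhs_ppv <- ((1 - p1$tnr) + (1 - p2$tnr)) / ((1 - p1$tnr) * (1 - p2$tnr))
  lhs_npv <- (p1$tnr + p2$tnr) / (p1$tnr * p2$tnr)
  rhs_npv <- ((1 - p1$tpr) + (1 - p2$tpr)) / ((1 - p1$tpr) * (1 - p2$tpr))
  c(ppv = lhs_ppv <= rhs_ppv, npv = lhs_npv <= rhs_npv)
}

#' Parallel-to-series test-count ratio
#'
#' In series administration of a two-test protocol the second test is
#' given only when the first result leaves the call undecided: after a
#' positive first test under AND, or after a negative first test under
#' OR. The ratio of tests consumed by parallel versus series
#' administration is `2 / (1 + f*tpr1 + (1-f)(1-tnr1))` for AND and
#' `2 / (1 + f*(1-tpr1) + (1-f)*tnr1)` for OR; both lie in \[1, 2\].
#'
#' @param f Prevalence.
#' @param first [test_profile] of the test administered first.
#' @param mode `"and"` or `"or"`.
#' @return The ratio, a number in \[1, 2\].
#' @export
parallel_series_ratio <- function(f, first, mode = c("and", "or")) {
  check_prob(f, "f")
  mode <- match.arg(tolower(mode), c("and", "or"))
  ch <- char_of(first)
  p_second <- if (mode == "and") {
    f * ch$tpr + (1 - f) * (1 - ch$tnr)
  } else {
    f * (1 - ch$tpr) + (1 - f) * ch$tnr
  }
  2 / (1 + p_second)
}

#' Expected number of tests under series administration
#'
#' For a population of `N` individuals, series AND uses
#' `N * (1 + f*tpr1 + (1-f)(1-tnr1))` tests and series OR uses
#' `N * (1 + f*(1-tpr1) + (1-f)*tnr1)`, versus `2N` in parallel.
#'
#' @param N Population size.
#' @inheritParams parallel_series_ratio
#' @return Expected test count.
#' @export
expected_series_tests <- function(N, f, first, mode = c("and", "or")) {
  stopifnot(is.numeric(N), length(N) == 1L, N >= 0)
  2 * N / parallel_series_ratio(f, first, mode)
}

#' Critical prevalence where AND- and OR-series savings cross
#'
#' Below `f_c = (2*tnr1 - 1) / (2 * (tpr1 + tnr1 - 1))` a series AND
#' protocol consumes fewer tests than series OR; above it the ordering
#' reverses. The quantity is meaningful when the first test has
#' `tnr1 >= 1/2` and discriminatory power (`tpr1 + tnr1 > 1`); outside
#' that region the value is still returned but flagged with a warning.
#'
#' @param first [test_profile] of the first-administered test.
#' @return The critical prevalence.
#' @examples
#' critical_prevalence(test_profile("a", 0.95, 0.95)) # 0.5
#' @export
critical_prevalence <- function(first) {
  ch <- char_of(first)
  if (ch$tpr + ch$tnr == 1)
    stop("critical prevalence undefined: tpr1 + tnr1 = 1 (no discriminatory power)",
         call. = FALSE)
  fc <- (2 * ch$tnr - 1) / (2 * (ch$tpr + ch$tnr - 1))
  if (ch$tnr < 0.5 || ch$tpr + ch$tnr < 1)
    warning("critical prevalence is only meaningful for tnr1 >= 1/2 with ",
            "discriminatory power; interpret with care", call. = FALSE)
  fc
}

#' Test-economy table over a prevalence grid
#'
#' Tabulates the parallel-to-series ratio and the expected series test
#' count for a first test over a grid of prevalences.
#'
#' @inheritParams parallel_series_ratio
#' @param grid Numeric vector of prevalences.
#' @param N Population size used for the expected test count.
#' @return A data frame with columns `prevalence`, `ratio`,
#'   `expected_tests_series`, `mode`, `n_population`.
#' @export
economy_table <- function(first, mode = c("and", "or"),
                          grid = seq(0, 1, by = 0.01), N = 1000) {
  mode <- match.arg(tolower(mode), c("and", "or"))
  ratio <- vapply(grid, parallel_series_ratio, numeric(1),
                  first = first, mode = mode)
  data.frame(prevalence = grid, ratio = ratio,
             expected_tests_series = 2 * N / ratio,
             mode = mode, n_population = N)
}
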