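# Synthetic testing cohorts: per-subject Bernoulli test outcomes
# conditional on true disease status, optionally with pairwise positive
# dependence between consecutive tests, and their empirical aggregated
# characteristics.

#' Simulate a synthetic testing cohort
#'
#' Draws true status `X ~ Bernoulli(f)` i.i.d. per subject; given the
#' status, each test result is Bernoulli with success `tpr_i` (X = 1) or
#' `1 - tnr_i` (X = 0), independent across tests unless
#' `pairwise_lambda` is set. With a dependence factor `lambda`,
#' consecutive test pairs are coupled through a chain of conditional
#' Bernoulli draws so that
#' `Pr(Y_i = 1 | Y_{i-1} = 1, X) = lambda * Pr(Y_i = 1 | X)` while every
#' marginal is preserved; `lambda = 1` recovers independence and
#' `lambda > 1` yields positively dependent results. The same factor
#' couples positive results in both status classes. Missingness is
#' applied completely at random. Fully reproducible from the seed.
#'
#' @param n_subjects Number of subjects.
#' @param f True prevalence.
#' @param profiles List of [test_profile]s (one per test).
#' @param pairwise_lambda Optional positive dependence factor; the
#'   implied conditional probabilities must stay in \[0, 1\], otherwise
#'   the call is rejected with the feasible range in the message.
#' @param missing_rate Probability that any single result is missing.
#' @param seed Integer seed.
#' @return An object of class `cohort`: a list with `data` (a data
#'   frame: `status` plus one 0/1/`NA` column per test, named after the
#'   profiles) and `meta` (prevalence, profiles, dependence setting,
#'   missing rate, seed).
#' @examples
#' panel <- list(test_profile("a", 0.9, 0.95), test_profile("b", 0.8, 0.9))
#' co <- simulate_cohort(1000, 0.3, panel, seed = 42)
#' head(co$data)
#' @export
simulate_cohort <- function(n_subjects, f, profiles, pairwise_lambda = NULL,
                            missing_rate = 0, seed = 1L) {
  stopifnot(is.numeric(n_subjects), length(n_subjects) == 1L,
            n_subjects >= 1, n_subjects == round(n_subjects))
  check_prob(f, "f")
  check_prob(missing_rate, "missing_rate")
  profiles <- check_profiles(profiles)
  n <- length(profiles)
  p_pos <- vapply(profiles, `[[`, numeric(1), "tpr")
  p_neg <- vapply(profiles, function(p) 1 - p$tnr, numeric(1))
  if (!is.null(pairwise_lambda)) {
    stopifnot(is.numeric(pairwise_lambda), length(pairwise_lambda) == 1L,
              pairwise_lambda > 0)
    if (n < 2L)
      stop("pairwise dependence needs at least two tests", call. = FALSE)
    check_lambda_feasible(pairwise_lambda, p_pos)
    check_lambda_feasible(pairwise_lambda, p_neg)
  }
  set.seed(as.integer(seed))
  status <- stats::rbinom(n_subjects, 1L, f)
  res <- matrix(NA_integer_, nrow = n_subjects, ncol = n)
  for (cls in c(1L, 0L)) {
    idx <- which(status == cls)
    if (!length(idx)) next
    p <- if (cls == 1L) p_pos else p_neg
    res[idx, ] <- draw_results(length(idx), p, pairwise_lambda)
  }
  if (missing_rate > 0) {
    miss <- matrix(stats::runif(n_subjects * n) < missing_rate,
                   nrow = n_subjects)
    res[miss] <- NA_integer_
  }
  df <- data.frame(status = status, res)
  names(df) <- c("status", vapply(profiles, `[[`, character(1), "name"))
  structure(list(
    data = df,
    meta = list(n_subjects = as.integer(n_subjects), prevalence = f,
                profiles = profiles, pairwise_lambda = pairwise_lambda,
                missing_rate = missing_rate, seed = as.integer(seed))),
    class = "cohort")
}

# Internal: feasibility of the chain coupling for margins p (positive-
# result probabilities of consecutive tests). Requires, for each
# consecutive pair (i-1, i):
#   lambda * p[i] <= 1                      (conditional prob <= 1)
#   lambda * p[i-1] * p[i] <= min(p[i-1], p[i])   (joint <= margins)
#   lambda * p[i-1] * p[i] >= p[i-1] + p[i] - 1   (Frechet lower bound)
check_lambda_feasible <- function(lambda, p) {
  lo <- 0; hi <- Inf
  for (i in seq_along(p)[-1]) {
    pa <- p[i - 1]; pb <- p[i]
    if (pa == 0 || pb == 0) next  # joint is 0 regardless of lambda
    hi <- min(hi, 1 / pb, min(pa, pb) / (pa * pb))
    if (pa < 1) hi <- min(hi, 1 / pa)
    lo <- max(lo, (pa + pb - 1) / (pa * pb))
  }
  if (lambda < lo || lambda > hi)
    stop(sprintf(
      "pairwise_lambda = %g infeasible for these margins; feasible range is [%.4g, %.4g]",
      lambda, lo, hi), call. = FALSE)
  invisible(TRUE)
}

# Internal: m subjects x length(p) results with per-test positive
# probabilities p; chain coupling when lambda is non-NULL.
draw_results <- function(m, p, lambda) {
  n <- length(p)
  out <- matrix(0L, nrow = m, ncol = n)
  out[, 1] <- stats::rbinom(m, 1L, p[1])
  for (i in seq_len(n)[-1]) {
    if (is.null(lambda) || p[i - 1] %in% c(0, 1)) {
      prob <- if (!is.null(lambda) && p[i - 1] == 1) {
        rep(min(lambda * p[i], 1), m)  # all previous positive
      } else rep(p[i], m)
    } else {
      q1 <- lambda * p[i]
      q0 <- p[i] * (1 - lambda * p[i - 1]) / (1 - p[i - 1])
      prob <- ifelse(out[, i - 1] == 1L, q1, q0)
    }
    out[, i] <- stats::rbinom(m, 1L, prob)
  }
  out
}

#' @export
print.cohort <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<cohort> %d subjects, prevalence %.3g, %d tests (%s), lambda %s, missing %.3g, seed %d\n",
    m$n_subjects, m$prevalence, length(m$profiles),
    paste(vapply(m$profiles, `[[`, character(1), "name"), collapse = ", "),
    if (is.null(m$pairwise_lambda)) "none (independent)"
    else format(m$pairwise_lambda),
    m$missing_rate, m$seed))
  invisible(x)
}

#' Empirical characteristics of a rule on a cohort
#'
#' Applies an aggregation rule subject by subject (rows with any missing
#' result among the rule's tests are dropped and counted) and estimates
#' the aggregated sensitivity and specificity as the positive-call
#' fraction among truly positive subjects and the negative-call fraction
#' among truly negative subjects.
#'
#' @param cohort A `cohort` object or compatible data frame.
#' @param rule An [aggregation_rule] or a specification string for
#'   [parse_rule()].
#' @return An `aggregate_characteristics` object with extra fields
#'   `n_pos`, `n_neg` (subjects used per class) and `n_dropped`
#'   (incomplete rows).
#' @export
empirical_characteristics <- function(cohort, rule) {
  df <- cohort_data(cohort)
  tests <- setdiff(names(df), "status")
  n <- length(tests)
  if (is.character(rule)) rule <- parse_rule(rule, n)
  stopifnot(inherits(rule, "aggregation_rule"))
  if (rule$n != n)
    stop(sprintf("rule is over %d tests but the cohort has %d",
                 rule$n, n), call. = FALSE)
  y <- as.matrix(df[tests])
  complete <- stats::complete.cases(y)
  y <- y[complete, , drop = FALSE]
  status <- df$status[complete]
  # canonical index of each subject's outcome vector
  pow <- 2L^(n - seq_len(n))
  j <- 2L^n - as.integer(y %*% pow)
  call_pos <- rule$outputs[j] == "+"
  if (!any(status == 1L) || !any(status == 0L))
    stop("empirical characteristics undefined: a status class has no complete subjects",
         call. = FALSE)
  out <- new_aggregate_characteristics(
    tpr = mean(call_pos[status == 1L]),
    tnr = mean(!call_pos[status == 0L]),
    rule = rule)
  out$n_pos <- sum(status == 1L)
  out$n_neg <- sum(status == 0L)
  out$n_dropped <- sum(!complete)
  out
}

#' Write a cohort to a CSV file
#'
#' The file starts with `#`-prefixed metadata lines (package version,
#' seed, generator settings) followed by the subject table.
#'
#' @param cohort A `cohort` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  m <- cohort$meta
  hdr <- c(
    sprintf("# testfuse %s cohort", as.character(utils::packageVersion("testfuse"))),
    sprintf("# n_subjects=%d prevalence=%.10g lambda=%s missing_rate=%.10g seed=%d",
            m$n_subjects, m$prevalence,
            if (is.null(m$pairwise_lambda)) "NA" else
              sprintf("%.10g", m$pairwise_lambda),
            m$missing_rate, m$seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(cohort$data, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort table from a CSV file
#'
#' @param path Path to a CSV with a `status` column and 0/1/NA test
#'   columns (metadata comment lines starting with `#` are skipped).
#' @return A data frame usable wherever a cohort is accepted.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  cohort_data(df)
}
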