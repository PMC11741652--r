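# Aggregated sensitivity and specificity of Boolean rules under
# conditional independence of test results given true disease status.

# Internal: probability of each canonical outcome given X = 1 ("pos") or
# X = 0 ("neg"). Given X = 1 test i is positive with probability tpr_i;
# given X = 0 with probability 1 - tnr_i. Products are accumulated test by
# test in a fixed order so results are bit-reproducible.
outcome_probs <- function(profiles, status = c("pos", "neg")) {
  status <- match.arg(status)
  n <- length(profiles)
  bits <- outcome_bits(n)
  p_pos <- vapply(profiles, function(pr)
    if (status == "pos") pr$tpr else 1 - pr$tnr, numeric(1))
  probs <- rep(1, nrow(bits))
  for (i in seq_len(n)) {
    probs <- probs * ifelse(bits[, i] == 1L, p_pos[i], 1 - p_pos[i])
  }
  probs
}

new_aggregate_characteristics <- function(tpr, tnr, rule) {
  structure(list(tpr = tpr, tnr = tnr, rule = rule),
            class = "aggregate_characteristics")
}

#' @export
print.aggregate_characteristics <- function(x, ...) {
  cat(sprintf(
    "<aggregate_characteristics> sens %.4g%%, spec %.4g%% (FPR %.4g%%), rule %s\n",
    100 * x$tpr, 100 * x$tnr, 100 * (1 - x$tnr),
    if (is.null(x$rule)) "<unspecified>" else rule_string(x$rule)))
  invisible(x)
}

#' Characteristics of an arbitrary aggregation rule
#'
#' Computes the aggregated sensitivity and specificity of a Boolean
#' aggregation rule applied to `n` tests, assuming test results are
#' conditionally independent given the true disease status. The
#' aggregated sensitivity is the sum, over outcome vectors mapped to
#' `+`, of the product over tests of `tpr_i` (test positive) or
#' `1 - tpr_i` (test negative); the aggregated specificity sums the
#' mirrored products of `tnr_i` and `1 - tnr_i` over outcomes mapped to
#' `-`. Parallel and series administration of the same rule share these
#' characteristics, so no separate "series" computation exists.
#'
#' @param rule An [aggregation_rule] (or a specification string accepted
#'   by [parse_rule()]).
#' @param profiles A list of [test_profile] objects, one per test, in
#'   rule order.
#' @return An object of class `aggregate_characteristics` with fields
#'   `tpr`, `tnr`, and `rule`.
#' @examples
#' panel <- list(test_profile("a", 0.748, 0.997),
#'               test_profile("b", 0.681, 0.990),
#'               test_profile("c", 0.687, 1.000))
#' rule_characteristics(parse_rule("(1&2)|3", 3), panel)
#' @export
rule_characteristics <- function(rule, profiles) {
  profiles <- check_profiles(profiles)
  if (is.character(rule)) rule <- parse_rule(rule, length(profiles))
  stopifnot(inherits(rule, "aggregation_rule"))
  check_profiles(profiles, n_required = rule$n)
  pos <- outcome_probs(profiles, "pos")
  neg <- outcome_probs(profiles, "neg")
  plus <- rule$outputs == "+"
  new_aggregate_characteristics(
    tpr = sum(pos[plus]),
    tnr = sum(neg[!plus]),
    rule = rule
  )
}

#' Characteristics of the AND (conjunctive) rule
#'
#' Positive call iff all tests are positive: `tpr = prod(tpr_i)`,
#' `tnr = 1 - prod(1 - tnr_i)`. Closed form of the all-AND truth table.
#'
#' @inheritParams rule_characteristics
#' @return An `aggregate_characteristics` object.
#' @export
and_characteristics <- function(profiles) {
  profiles <- check_profiles(profiles)
  n <- length(profiles)
  tprs <- vapply(profiles, `[[`, numeric(1), "tpr")
  tnrs <- vapply(profiles, `[[`, numeric(1), "tnr")
  new_aggregate_characteristics(prod(tprs), 1 - prod(1 - tnrs),
                                rule_k_of_n(n, n))
}

#' Characteristics of the OR (disjunctive) rule
#'
#' Positive call iff any test is positive: `tpr = 1 - prod(1 - tpr_i)`,
#' `tnr = prod(tnr_i)`.
#'
#' @inheritParams rule_characteristics
#' @return An `aggregate_characteristics` object.
#' @export
or_characteristics <- function(profiles) {
  profiles <- check_profiles(profiles)
  n <- length(profiles)
  tprs <- vapply(profiles, `[[`, numeric(1), "tpr")
  tnrs <- vapply(profiles, `[[`, numeric(1), "tnr")
  new_aggregate_characteristics(1 - prod(1 - tprs), prod(tnrs),
                                rule_k_of_n(1L, n))
}

#' Characteristics of the k-of-n rule
#'
#' Positive call iff at least `k` of `n` tests are positive. `k = 1`
#' collapses to OR, `k = n` to AND; odd `n` with `k = (n + 1) / 2` is the
#' majority rule, which is sandwiched between AND and OR in both
#' sensitivity and specificity.
#'
#' @inheritParams rule_characteristics
#' @param k Minimum number of positive tests.
#' @return An `aggregate_characteristics` object.
#' @export
k_of_n_characteristics <- function(profiles, k) {
  profiles <- check_profiles(profiles)
  rule_characteristics(rule_k_of_n(k, length(profiles)), profiles)
}

#' Characteristics of the majority rule
#'
#' At least `(n + 1) / 2` of an odd number `n` of tests must be positive.
#'
#' @inheritParams rule_characteristics
#' @return An `aggregate_characteristics` object.
#' @export
majority_characteristics <- function(profiles) {
  profiles <- check_profiles(profiles)
  n <- length(profiles)
  if (n %% 2L == 0L)
    stop("majority aggregation requires an odd number of tests",
         call. = FALSE)
  k_of_n_characteristics(profiles, (n + 1L) %/% 2L)
}
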