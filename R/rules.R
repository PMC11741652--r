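#' Construct an aggregation rule from an output sequence
#'
#' An aggregation rule is a Boolean function mapping each of the `2^n`
#' ordered outcome vectors of `n` tests to a single `+`/`-` call. It is
#' stored as its output sequence (truth table) over the canonical outcome
#' order of [canonical_outcomes()].
#'
#' @param outputs Character vector of `2^n` signs (`"+"` or `"-"`), or a
#'   single string like `"+---"`.
#' @param n Number of tests; inferred from `length(outputs)` if missing.
#' @return An object of class `aggregation_rule` with fields `n` and
#'   `outputs`.
#' @examples
#' aggregation_rule("+---")  # AND of two tests
#' @export
aggregation_rule <- function(outputs, n = NULL) {
  if (is.character(outputs) && length(outputs) == 1L && nchar(outputs) > 1L)
    outputs <- strsplit(outputs, "")[[1]]
  if (!is.character(outputs) || !all(outputs %in% c("+", "-")))
    stop("`outputs` must consist of \"+\" and \"-\" signs only",
         call. = FALSE)
  r <- length(outputs)
  n_implied <- log2(r)
  if (n_implied != round(n_implied))
    stop(sprintf("`outputs` has length %d, which is not a power of two", r),
         call. = FALSE)
  n_implied <- as.integer(round(n_implied))
  if (is.null(n)) n <- n_implied
  if (n != n_implied)
    stop(sprintf("`outputs` has length %d but 2^n = %d", r, 2^n),
         call. = FALSE)
  structure(list(n = as.integer(n), outputs = outputs),
            class = "aggregation_rule")
}

#' @export
print.aggregation_rule <- function(x, ...) {
  cat(sprintf("<aggregation_rule> n = %d, outputs = %s\n",
              x$n, rule_string(x)))
  invisible(x)
}

#' Serialize a rule as its truth-table sign string
#'
#' @param rule An [aggregation_rule].
#' @return A single string such as `"+---"` (canonical outcome order).
#' @export
rule_string <- function(rule) {
  stopifnot(inherits(rule, "aggregation_rule"))
  paste(rule$outputs, collapse = "")
}

#' Parse a rule specification
#'
#' Accepts, in order of precedence:
#' * a truth-table sign string of length `2^n` over `{+, -}`, e.g.
#'   `"+---"` (canonical outcome order, all-positive outcome first);
#' * a named rule: `"AND"`, `"OR"`, `"MAJORITY"` (odd `n` only), or
#'   `"k-of-n"` shorthand such as `"2-of-3"` (positive iff at least `k`
#'   tests positive);
#' * a Boolean expression over 1-based test identifiers with `&`, `|`,
#'   `!` and parentheses (the words AND/OR/NOT are also accepted), e.g.
#'   `"(1&2)|3"`; a bare identifier such as `"3"` projects onto that
#'   single test.
#'
#' @param spec Character rule specification.
#' @param n Number of tests.
#' @return An [aggregation_rule] with its fully materialized output
#'   sequence.
#' @examples
#' rule_string(parse_rule("AND", 2))      # "+---"
#' rule_string(parse_rule("OR", 2))       # "+++-"
#' rule_string(parse_rule("(1&2)|3", 3))  # "+++-+-+-"
#' @export
parse_rule <- function(spec, n) {
  n <- check_n(n)
  if (!is.character(spec) || length(spec) != 1L || !nzchar(spec))
    stop("`spec` must be a single non-empty string", call. = FALSE)
  r <- 2L^n
  if (grepl("^[+-]+$", spec)) {
    if (nchar(spec) != r)
      stop(sprintf("truth-table string must have length 2^n = %d, got %d",
                   r, nchar(spec)), call. = FALSE)
    return(aggregation_rule(spec, n))
  }
  upper <- toupper(trimws(spec))
  if (upper == "AND") return(rule_k_of_n(n, n))
  if (upper == "OR") return(rule_k_of_n(1L, n))
  if (upper == "MAJORITY") {
    if (n %% 2L == 0L)
      stop("MAJORITY requires an odd number of tests", call. = FALSE)
    return(rule_k_of_n((n + 1L) %/% 2L, n))
  }
  m <- regmatches(upper, regexec("^([0-9]+)-OF-([0-9]+)$", upper))[[1]]
  if (length(m) == 3L) {
    k <- as.integer(m[2])
    if (as.integer(m[3]) != n)
      stop(sprintf("rule \"%s\" does not match n = %d", spec, n),
           call. = FALSE)
    return(rule_k_of_n(k, n))
  }
  rule_from_expression(spec, n)
}

#' k-of-n aggregation rule
#'
#' The rule that calls a subject positive iff at least `k` of the `n`
#' tests are positive. `k = n` is AND, `k = 1` is OR, and
#' `k = (n + 1) / 2` with odd `n` is the majority rule.
#'
#' @param k Minimum number of positive tests, `1 <= k <= n`.
#' @param n Number of tests.
#' @return An [aggregation_rule].
#' @export
rule_k_of_n <- function(k, n) {
  n <- check_n(n)
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 1 || k > n)
    stop(sprintf("`k` must be an integer in [1, %d]", n), call. = FALSE)
  bits <- outcome_bits(n)
  aggregation_rule(ifelse(rowSums(bits) >= k, "+", "-"), n)
}

#' Single-test projection rule
#'
#' The rule whose call equals the result of test `i`, ignoring all others.
#'
#' @param i 1-based test index.
#' @param n Number of tests.
#' @return An [aggregation_rule].
#' @export
rule_projection <- function(i, n) {
  n <- check_n(n)
  if (!is.numeric(i) || length(i) != 1L || i != round(i) || i < 1 || i > n)
    stop(sprintf("test index must be in [1, %d]", n), call. = FALSE)
  bits <- outcome_bits(n)
  aggregation_rule(ifelse(bits[, i] == 1L, "+", "-"), n)
}

#' Rule from a Boolean expression
#'
#' Evaluates an infix Boolean expression over 1-based test identifiers on
#' every canonical outcome vector and materializes the resulting output
#' sequence. Operators: `&` (AND), `|` (OR), `!` (NOT), parentheses; the
#' words AND/OR/NOT (any case) are accepted as synonyms.
#'
#' @param expr Expression text, e.g. `"(1&2)|3"`.
#' @param n Number of tests.
#' @return An [aggregation_rule].
#' @export
rule_from_expression <- function(expr, n) {
  n <- check_n(n)
  txt <- expr
  txt <- gsub("\\bAND\\b", "&", txt, ignore.case = TRUE)
  txt <- gsub("\\bOR\\b", "|", txt, ignore.case = TRUE)
  txt <- gsub("\\bNOT\\b", "!", txt, ignore.case = TRUE)
  if (grepl("[^0-9&|!() ]", txt))
    stop(sprintf(
      "malformed rule expression \"%s\": only test identifiers 1..%d, &, |, !, and parentheses are allowed",
      expr, n), call. = FALSE)
  ids <- unique(as.integer(regmatches(txt, gregexpr("[0-9]+", txt))[[1]]))
  if (length(ids) == 0L)
    stop(sprintf("rule expression \"%s\" references no test", expr),
         call. = FALSE)
  if (any(ids < 1L | ids > n))
    stop(sprintf(
      "rule expression \"%s\" references test %d, but n = %d",
      expr, ids[which(ids < 1L | ids > n)[1]], n), call. = FALSE)
  rtxt <- gsub("([0-9]+)", "y\\1", txt)
  parsed <- tryCatch(str2lang(rtxt), error = function(e)
    stop(sprintf("malformed rule expression \"%s\": %s",
                 expr, conditionMessage(e)), call. = FALSE))
  bits <- outcome_bits(n)
  env <- new.env(parent = baseenv())
  for (i in seq_len(n)) assign(paste0("y", i), bits[, i] == 1L, envir = env)
  vals <- eval(parsed, envir = env)
  if (!is.logical(vals) || length(vals) != nrow(bits))
    stop(sprintf("rule expression \"%s\" did not evaluate to one call per outcome",
                 expr), call. = FALSE)
  aggregation_rule(ifelse(vals, "+", "-"), n)
}

# Internal: flip every output sign (complement rule).
complement_rule <- function(rule) {
  aggregation_rule(ifelse(rule$outputs == "+", "-", "+"), rule$n)
}
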