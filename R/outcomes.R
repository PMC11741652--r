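# Canonical ordering of joint test outcomes.
#
# Every rule in this package is an output sequence over the 2^n ordered
# outcome vectors of n tests. The canonical order is lexicographic with
# "+" before "-", so the all-positive vector comes first and the
# all-negative vector last; for n = 2 the order is
# (+,+), (+,-), (-,+), (-,-). The bijection to 0/1 bit tuples maps "+" to
# 1, test 1 being the most significant bit: outcome j (1-based) carries
# the bits of 2^n - j.

# Full enumeration of rules is 2^(2^n); cap at n = 4 (65,536 rules).
MAX_ENUM_N <- 4L

check_n <- function(n, cap = 16L) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != round(n))
    stop("`n` must be a single integer >= 1", call. = FALSE)
  if (n > cap)
    stop(sprintf("`n` = %d exceeds the enumeration cap of %d", n, cap),
         call. = FALSE)
  as.integer(n)
}

#' Canonical ordering of joint test outcomes
#'
#' Returns all `2^n` outcome vectors of `n` binary tests in the canonical
#' order used throughout the package: lexicographic with `+` before `-`,
#' so the all-positive vector is first and the all-negative vector last.
#' This order indexes every rule's output sequence (truth-table string).
#'
#' @param n Number of tests, an integer >= 1.
#' @return A `2^n` by `n` character matrix of `"+"`/`"-"` signs, one row
#'   per outcome vector.
#' @examples
#' canonical_outcomes(2)
#' # (+,+), (+,-), (-,+), (-,-)
#' @export
canonical_outcomes <- function(n) {
  n <- check_n(n)
  bits <- outcome_bits(n)
  m <- matrix(ifelse(bits == 1L, "+", "-"), nrow = nrow(bits))
  colnames(m) <- paste0("test", seq_len(n))
  m
}

# Internal: 2^n x n integer matrix, row j = bits of 2^n - j (MSB = test 1),
# i.e. 1 for "+" and 0 for "-" in canonical order.
outcome_bits <- function(n) {
  r <- 2L^n
  vals <- r - seq_len(r)  # r-1, r-2, ..., 0
  m <- matrix(0L, nrow = r, ncol = n)
  for (i in seq_len(n)) {
    m[, i] <- (vals %/% 2L^(n - i)) %% 2L
  }
  m
}

# Internal: canonical index (1-based) of a 0/1 outcome row vector.
outcome_index <- function(bits) {
  n <- length(bits)
  2L^n - sum(bits * 2L^(n - seq_len(n)))
}
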