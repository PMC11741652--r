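# Independent oracles and fixture builders shared across the suite.

# Brute-force joint-distribution oracle. Enumerates every joint outcome
# of n conditionally independent tests by its integer encoding
# v = sum_i bit_i * 2^(n-i) (bit = 1 for a positive result), multiplies
# conditional Bernoulli probabilities, and places each outcome at
# canonical rule index j = 2^n - v. Shares no code with the package's
# sum-of-products path.
oracle_joint_probs <- function(tprs, tnrs) {
  n <- length(tprs)
  r <- 2^n
  pos <- numeric(r)
  neg <- numeric(r)
  for (v in 0:(r - 1)) {
    bits <- (v %/% 2^(n - seq_len(n))) %% 2
    j <- r - v
    pos[j] <- prod(ifelse(bits == 1, tprs, 1 - tprs))
    neg[j] <- prod(ifelse(bits == 1, 1 - tnrs, tnrs))
  }
  list(pos = pos, neg = neg)
}

oracle_characteristics <- function(signs, tprs, tnrs) {
  if (length(signs) == 1L && nchar(signs) > 1L)
    signs <- strsplit(signs, "")[[1]]
  jp <- oracle_joint_probs(tprs, tnrs)
  plus <- signs == "+"
  c(tpr = sum(jp$pos[plus]), tnr = sum(jp$neg[!plus]))
}

# Direct n = 2 frontier oracle: no hull machinery, just pairwise
# segment comparisons. A point is kept iff it satisfies tpr >= fpr and
# no chord between two other achievable points passes on or above it;
# the two trivial corners are always kept.
frontier_oracle_n2 <- function(profiles) {
  tprs <- vapply(profiles, `[[`, numeric(1), "tpr")
  tnrs <- vapply(profiles, `[[`, numeric(1), "tnr")
  pts <- t(vapply(enumerate_rules(2), function(s) {
    ch <- oracle_characteristics(s, tprs, tnrs)
    c(fpr = 1 - ch[["tnr"]], tpr = ch[["tpr"]])
  }, numeric(2)))
  pts[abs(pts) < 1e-12] <- 0
  pts[abs(pts - 1) < 1e-12] <- 1
  key <- paste(signif(pts[, 1], 12), signif(pts[, 2], 12))
  pts <- pts[!duplicated(key), , drop = FALSE]
  keep <- logical(nrow(pts))
  for (p in seq_len(nrow(pts))) {
    x <- pts[p, "fpr"]; y <- pts[p, "tpr"]
    if ((x == 0 && y == 0) || (x == 1 && y == 1)) {
      keep[p] <- TRUE
      next
    }
    if (y < x) next
    excluded <- FALSE
    for (a in seq_len(nrow(pts))) {
      for (b in seq_len(nrow(pts))) {
        if (a == p || b == p || pts[a, "fpr"] >= pts[b, "fpr"]) next
        if (x < pts[a, "fpr"] || x > pts[b, "fpr"]) next
        interp <- pts[a, "tpr"] + (pts[b, "tpr"] - pts[a, "tpr"]) *
          (x - pts[a, "fpr"]) / (pts[b, "fpr"] - pts[a, "fpr"])
        if (interp >= y - 1e-12) excluded <- TRUE
      }
      if (!excluded) {
        # vertical dominance at equal fpr
        same <- pts[, "fpr"] == x & pts[, "tpr"] >= y
        if (sum(same) > 1L) excluded <- TRUE
      }
    }
    keep[p] <- !excluded
  }
  m <- pts[keep, , drop = FALSE]
  m[order(m[, "fpr"], m[, "tpr"]), , drop = FALSE]
}

random_profiles <- function(n, lo = 0, hi = 1) {
  lapply(seq_len(n), function(i)
    test_profile(paste0("t", i),
                 tpr = stats::runif(1, lo, hi),
                 tnr = stats::runif(1, lo, hi)))
}

antigen_panel <- function() {
  read_test_profiles(
    system.file("extdata", "antigen_panel.csv", package = "testfuse"),
    percent = TRUE)
}

antibody_panel <- function() {
  read_test_profiles(
    system.file("extdata", "norrbotten_tests.csv", package = "testfuse"),
    percent = TRUE)
}

norrbotten_strata <- function() {
  utils::read.csv(
    system.file("extdata", "norrbotten_strata.csv", package = "testfuse"),
    comment.char = "#", stringsAsFactors = FALSE)
}
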