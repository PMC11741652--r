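# ROC-frontier search over all Boolean aggregation rules.
#
# For n tests there are 2^n joint outcomes and 2^(2^n) rules. Each rule's
# (FPR, TPR) point is a subset sum of the outcome probability vectors, so
# the whole enumeration is a binary-mask matrix product. The frontier is
# the upper-left convex hull chain from (0,0) to (1,1); both endpoints are
# always achievable (the constant-negative and constant-positive rules).

#' Enumerate every aggregation rule for n tests
#'
#' Yields all `2^(2^n)` output sequences (truth-table strings in
#' canonical outcome order). Full enumeration is capped at `n <= 4`
#' (65,536 rules); beyond that use named families (`AND`, `OR`, k-of-n,
#' projections, expressions) via [roc_frontier()]'s `families` argument.
#'
#' @param n Number of tests, `1 <= n <= 4`.
#' @return A character vector of sign strings, one per rule, in mask
#'   order (constant `-` first, constant `+` last).
#' @examples
#' length(enumerate_rules(2)) # 16
#' @export
enumerate_rules <- function(n) {
  n <- check_n(n, cap = MAX_ENUM_N)
  r <- 2L^n
  masks <- rule_mask_matrix(n)
  apply(masks, 1L, function(row) paste(ifelse(row, "+", "-"), collapse = ""))
}

# Internal: 2^r x r logical matrix; row m+1 gives which outcomes rule mask
# m maps to "+". Bit j of the mask governs canonical outcome j.
rule_mask_matrix <- function(n) {
  r <- 2L^n
  m <- 2^r
  masks <- matrix(FALSE, nrow = m, ncol = r)
  idx <- seq_len(m) - 1
  for (j in seq_len(r)) {
    masks[, j] <- (idx %/% 2^(j - 1)) %% 2 >= 1
  }
  masks
}

#' Efficient ROC frontier of aggregated tests
#'
#' Computes the (FPR, TPR) operating point of every aggregation rule for
#' the given test panel under conditional independence, then extracts the
#' ROC frontier: the upper-left convex-hull chain from (0,0) to (1,1).
#' No returned rule can be improved in one coordinate without worsening
#' the other. Coincident operating points are merged and every rule
#' attaining a frontier vertex is reported (sorted by truth-table string;
#' the first is the representative). Collinear points interior to a hull
#' edge are excluded; if all non-trivial points are collinear the
#' frontier falls back to a plain dominance scan.
#'
#' @param profiles List of [test_profile] objects (the panel).
#' @param families Optional character vector of rule specifications
#'   understood by [parse_rule()] (e.g. `c("AND", "OR", "2-of-3", "1")`).
#'   Required for `n > 4`, where full enumeration is refused; if supplied,
#'   only these rules (plus the two constant rules) compete.
#' @return An object of class `roc_frontier`: a list with `points` (a
#'   data frame with columns `fpr`, `tpr`, `representative_rule`,
#'   `n_attaining_rules`), `rules` (list of character vectors of all
#'   attaining truth-table strings per point), `n`, `profile_names`, and
#'   `nondiscriminatory` (names of tests flagged as lacking
#'   discriminatory power; such tests are allowed but reported).
#' @examples
#' panel <- list(test_profile("a", 0.9, 0.95), test_profile("b", 0.8, 0.9))
#' roc_frontier(panel)
#' @export
roc_frontier <- function(profiles, families = NULL) {
  profiles <- check_profiles(profiles)
  n <- length(profiles)
  if (is.null(families) && n > MAX_ENUM_N)
    stop(sprintf(
      paste0("full enumeration is capped at n = %d (2^(2^n) rules); ",
             "for n = %d supply named rule families via `families` ",
             "(e.g. c(\"AND\", \"OR\", \"%d-of-%d\"))"),
      MAX_ENUM_N, n, (n + 1L) %/% 2L, n), call. = FALSE)
  pos <- outcome_probs(profiles, "pos")
  neg <- outcome_probs(profiles, "neg")
  r <- 2L^n
  if (is.null(families)) {
    masks <- rule_mask_matrix(n)
  } else {
    rules <- lapply(unique(families), parse_rule, n = n)
    strs <- c(strrep("-", r), strrep("+", r),
              vapply(rules, rule_string, character(1)))
    masks <- t(vapply(strsplit(unique(strs), ""),
                      function(s) s == "+", logical(r)))
  }
  snap <- function(x) {  # guard the exact endpoints against summation noise
    x[abs(x) < 1e-12] <- 0
    x[abs(x - 1) < 1e-12] <- 1
    x
  }
  tpr <- snap(as.numeric(masks %*% pos))
  fpr <- snap(as.numeric(masks %*% neg))
  strs <- apply(masks, 1L, function(row)
    paste(ifelse(row, "+", "-"), collapse = ""))

  # merge coincident points (12 significant digits)
  key <- paste(signif(fpr, 12), signif(tpr, 12))
  grp <- split(seq_along(key), key)
  ufpr <- vapply(grp, function(i) fpr[i[1]], numeric(1))
  utpr <- vapply(grp, function(i) tpr[i[1]], numeric(1))
  urules <- lapply(grp, function(i) sort(strs[i], method = "radix"))

  keep <- frontier_indices(ufpr, utpr)
  ord <- keep[order(ufpr[keep], utpr[keep])]

  pts <- data.frame(
    fpr = ufpr[ord],
    tpr = utpr[ord],
    representative_rule = vapply(urules[ord], `[[`, character(1), 1L),
    n_attaining_rules = vapply(urules[ord], length, integer(1)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  nondisc <- vapply(profiles, function(p)
    if (!has_discriminatory_power(p)) p$name else NA_character_,
    character(1))
  nondisc <- nondisc[!is.na(nondisc)]
  if (length(nondisc))
    warning("tests without discriminatory power: ",
            paste(nondisc, collapse = ", "), call. = FALSE)
  structure(list(points = pts, rules = unname(urules[ord]), n = n,
                 profile_names = vapply(profiles, `[[`, character(1), "name"),
                 nondiscriminatory = nondisc),
            class = "roc_frontier")
}

# Internal: indices of frontier vertices among deduplicated points.
# Dominance sweep first, then an upper-concave-chain walk from (0,0) to
# (1,1) that drops collinear interior points. Falls back to the plain
# dominance scan when every surviving point is collinear with the
# endpoints (zero-area hull).
frontier_indices <- function(fpr, tpr) {
  i00 <- which(fpr == 0 & tpr == 0)[1]
  i11 <- which(fpr == 1 & tpr == 1)[1]
  stopifnot(!is.na(i00), !is.na(i11))  # constant rules always present
  # non-dominated sweep: sort by fpr asc, tpr desc; keep strictly rising tpr
  ord <- order(fpr, -tpr)
  best <- -Inf
  dom <- logical(length(fpr))
  for (i in ord) {
    if (tpr[i] > best) {
      dom[i] <- TRUE
      best <- tpr[i]
    }
  }
  cand <- setdiff(which(dom), c(i00, i11))
  cand <- cand[tpr[cand] >= fpr[cand]]  # ROC points satisfy TPR >= FPR
  cand <- cand[order(fpr[cand], tpr[cand])]
  seq_pts <- c(i00, cand, i11)
  cross <- function(a, b, c) {
    (fpr[b] - fpr[a]) * (tpr[c] - tpr[a]) -
      (tpr[b] - tpr[a]) * (fpr[c] - fpr[a])
  }
  if (length(cand) &&
      all(abs(vapply(cand, function(m) cross(i00, m, i11), numeric(1)))
          < 1e-12)) {
    return(seq_pts)  # degenerate hull: dominance scan result
  }
  chain <- i00
  for (i in seq_pts[-1]) {
    while (length(chain) >= 2L &&
           cross(chain[length(chain) - 1L], chain[length(chain)], i) >= 0)
      chain <- chain[-length(chain)]
    chain <- c(chain, i)
  }
  chain
}

#' @export
print.roc_frontier <- function(x, ...) {
  cat(sprintf("<roc_frontier> n = %d tests (%s), %d efficient points\n",
              x$n, paste(x$profile_names, collapse = ", "),
              nrow(x$points)))
  print(x$points, digits = 6)
  invisible(x)
}
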