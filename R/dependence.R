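# Pairwise dependence factors estimated from raw cohort data. A factor of
# 1 indicates conditional independence of the two tests given status;
# values above 1 indicate positively dependent results.

#' Pairwise dependence factors from a testing cohort
#'
#' For each pair of tests `(i, j)` estimates
#' `lambda11|1 = Pr(Yi=1, Yj=1 | X=1) / (Pr(Yi=1 | X=1) Pr(Yj=1 | X=1))`
#' from the truly positive subjects, and the analogous
#' `lambda00|0` from the truly negative subjects. All frequencies for a
#' pair are computed on the subjects of the relevant status class with
#' both tests observed (pairwise-complete data), so missing entries
#' reduce the per-pair count but never bias the marginals relative to
#' the joint. Both matrices are symmetric by construction. A pair with
#' no complete observations, or with a zero marginal frequency, is
#' reported as `NA` (unavailable), never as 0. These factors are
#' descriptive diagnostics of departure from conditional independence;
#' they do not feed back into the aggregation formulas.
#'
#' @param cohort A `cohort` object from [simulate_cohort()] or a data
#'   frame with a `status` column (0/1) and one 0/1/`NA` column per
#'   test.
#' @return An object of class `dependence_factors`: a list with
#'   symmetric matrices `lambda_pp` (positive concordance given X=1),
#'   `lambda_nn` (negative concordance given X=0), matching
#'   complete-observation count matrices `counts_pos` and `counts_neg`,
#'   and `means`, a data frame with the unweighted and
#'   count-weighted means of the off-diagonal factors.
#' @examples
#' panel <- list(test_profile("a", 0.9, 0.95), test_profile("b", 0.8, 0.9))
#' co <- simulate_cohort(5000, 0.3, panel, seed = 1)
#' dependence_factors(co)
#' @export
dependence_factors <- function(cohort) {
  df <- cohort_data(cohort)
  tests <- setdiff(names(df), "status")
  if (length(tests) < 2L)
    stop("dependence factors need at least two test columns", call. = FALSE)
  n <- length(tests)
  lam <- function(status_val, concordant_on) {
    sub <- df[df$status == status_val, tests, drop = FALSE]
    m <- matrix(NA_real_, n, n, dimnames = list(tests, tests))
    cnt <- matrix(0L, n, n, dimnames = list(tests, tests))
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ok <- !is.na(sub[[i]]) & !is.na(sub[[j]])
        cnt[i, j] <- cnt[j, i] <- sum(ok)
        if (!any(ok)) next
        yi <- sub[[i]][ok] == concordant_on
        yj <- sub[[j]][ok] == concordant_on
        pi_ <- mean(yi); pj <- mean(yj)
        if (pi_ == 0 || pj == 0) next  # zero marginal: unavailable
        m[i, j] <- m[j, i] <- mean(yi & yj) / (pi_ * pj)
      }
    }
    list(lambda = m, counts = cnt)
  }
  pp <- lam(1L, 1L)
  nn <- lam(0L, 0L)
  mean_of <- function(m, w) {
    v <- m[upper.tri(m)]
    wt <- w[upper.tri(w)]
    ok <- !is.na(v)
    if (!any(ok)) return(c(NA_real_, NA_real_))
    c(mean(v[ok]), sum(v[ok] * wt[ok]) / sum(wt[ok]))
  }
  mp <- mean_of(pp$lambda, pp$counts)
  mn <- mean_of(nn$lambda, nn$counts)
  structure(list(
    lambda_pp = pp$lambda, lambda_nn = nn$lambda,
    counts_pos = pp$counts, counts_neg = nn$counts,
    means = data.frame(
      factor = c("lambda11|1", "lambda00|0"),
      unweighted = c(mp[1], mn[1]),
      count_weighted = c(mp[2], mn[2]))),
    class = "dependence_factors")
}

#' @export
print.dependence_factors <- function(x, ...) {
  cat("<dependence_factors>\n")
  cat("lambda11|1 (positive concordance given X = 1):\n")
  print(round(x$lambda_pp, 4))
  cat("lambda00|0 (negative concordance given X = 0):\n")
  print(round(x$lambda_nn, 4))
  cat("means:\n")
  print(x$means, row.names = FALSE)
  invisible(x)
}

# Internal: extract the data frame from a cohort object or validate a
# raw data frame.
cohort_data <- function(cohort) {
  df <- if (inherits(cohort, "cohort")) cohort$data else cohort
  if (!is.data.frame(df) || !"status" %in% names(df))
    stop("`cohort` must be a cohort object or a data frame with a `status` column",
         call. = FALSE)
  if (anyNA(df$status) || !all(df$status %in% c(0L, 1L)))
    stop("`status` must be 0/1 with no missing values", call. = FALSE)
  vals <- unlist(df[setdiff(names(df), "status")], use.names = FALSE)
  if (!all(is.na(vals) | vals %in% c(0, 1)))
    stop("test columns must contain only 0, 1, or NA", call. = FALSE)
  df
}
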