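#' Create a test profile
#'
#' A test profile holds the operating characteristics of one binary
#' diagnostic or screening test: its sensitivity (true positive rate, the
#' probability of a positive result given the subject truly has the
#' condition) and specificity (true negative rate, the probability of a
#' negative result given the subject lacks it), each optionally with a 95%
#' confidence interval as reported by a validation study.
#'
#' @param name Character label identifying the test.
#' @param tpr Sensitivity, a probability in \[0, 1\].
#' @param tnr Specificity, a probability in \[0, 1\].
#' @param tpr_ci Optional numeric pair `c(lo, hi)` with
#'   `lo <= tpr <= hi`, the 95% CI of the sensitivity.
#' @param tnr_ci Optional numeric pair, the 95% CI of the specificity.
#'
#' @return An object of class `test_profile`.
#' @examples
#' test_profile("panbio", tpr = 0.748, tnr = 0.997,
#'              tpr_ci = c(0.676, 0.808), tnr_ci = c(0.996, 0.998))
#' @export
test_profile <- function(name, tpr, tnr, tpr_ci = NULL, tnr_ci = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  check_prob(tpr, "tpr")
  check_prob(tnr, "tnr")
  check_ci(tpr_ci, tpr, "tpr")
  check_ci(tnr_ci, tnr, "tnr")
  structure(
    list(name = name, tpr = tpr, tnr = tnr,
         tpr_ci = tpr_ci, tnr_ci = tnr_ci),
    class = "test_profile"
  )
}

check_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single probability in [0, 1], got %s",
                 what, deparse(x)), call. = FALSE)
  invisible(x)
}

check_ci <- function(ci, point, what) {
  if (is.null(ci)) return(invisible(NULL))
  if (!is.numeric(ci) || length(ci) != 2L || anyNA(ci))
    stop(sprintf("`%s_ci` must be a numeric pair c(lo, hi)", what),
         call. = FALSE)
  if (ci[1] < 0 || ci[2] > 1 || ci[1] > point || point > ci[2])
    stop(sprintf(
      "`%s_ci` must satisfy 0 <= lo <= %s <= hi <= 1, got (%g, %g)",
      what, what, ci[1], ci[2]), call. = FALSE)
  invisible(ci)
}

#' @export
print.test_profile <- function(x, ...) {
  fmt_ci <- function(ci) {
    if (is.null(ci)) "" else sprintf(" (%.1f--%.1f%%)", 100 * ci[1], 100 * ci[2])
  }
  cat(sprintf("<test_profile> %s: sens %.1f%%%s, spec %.1f%%%s\n",
              x$name, 100 * x$tpr, fmt_ci(x$tpr_ci),
              100 * x$tnr, fmt_ci(x$tnr_ci)))
  invisible(x)
}

#' Coerce a data frame to a list of test profiles
#'
#' Accepts a data frame with columns `name`, `tpr`, `tnr` and optional
#' CI columns `tpr_lo`, `tpr_hi`, `tnr_lo`, `tnr_hi` (empty or `NA`
#' entries mean "no interval reported").
#'
#' @param df A data frame as described above.
#' @param percent If `TRUE`, all numeric columns are percentages and are
#'   divided by 100 on input. Percent and proportion input are never
#'   auto-detected from magnitudes.
#' @return A list of [test_profile] objects.
#' @export
as_test_profiles <- function(df, percent = FALSE) {
  stopifnot(is.data.frame(df), all(c("name", "tpr", "tnr") %in% names(df)))
  sc <- if (isTRUE(percent)) 0.01 else 1
  get_ci <- function(i, lo, hi) {
    if (!all(c(lo, hi) %in% names(df))) return(NULL)
    l <- df[[lo]][i]; h <- df[[hi]][i]
    if (is.na(l) || is.na(h)) return(NULL)
    c(l, h) * sc
  }
  lapply(seq_len(nrow(df)), function(i) {
    test_profile(as.character(df$name[i]),
                 tpr = df$tpr[i] * sc, tnr = df$tnr[i] * sc,
                 tpr_ci = get_ci(i, "tpr_lo", "tpr_hi"),
                 tnr_ci = get_ci(i, "tnr_lo", "tnr_hi"))
  })
}

#' Read test profiles from a delimited text file
#'
#' Expects a header `name,tpr,tpr_lo,tpr_hi,tnr,tnr_lo,tnr_hi`; the CI
#' columns may be empty or absent.
#'
#' @param path Path to a CSV file.
#' @inheritParams as_test_profiles
#' @return A list of [test_profile] objects.
#' @export
read_test_profiles <- function(path, percent = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  as_test_profiles(df, percent = percent)
}

# Internal: validate a list of profiles, returning it invisibly.
check_profiles <- function(profiles, n_required = NULL) {
  if (inherits(profiles, "test_profile")) profiles <- list(profiles)
  if (!is.list(profiles) || length(profiles) == 0L ||
      !all(vapply(profiles, inherits, logical(1), "test_profile")))
    stop("`profiles` must be a non-empty list of test_profile objects",
         call. = FALSE)
  if (!is.null(n_required) && length(profiles) != n_required)
    stop(sprintf("expected %d profiles, got %d",
                 n_required, length(profiles)), call. = FALSE)
  invisible(profiles)
}

#' Does a test have discriminatory power?
#'
#' A test has discriminatory power when its true positive rate exceeds its
#' false positive rate, i.e. `tpr + tnr > 1`; such a test performs better
#' than a random classifier.
#'
#' @param profile A [test_profile].
#' @return `TRUE` or `FALSE`.
#' @examples
#' has_discriminatory_power(test_profile("a", 0.95, 0.95)) # TRUE
#' has_discriminatory_power(test_profile("b", 0.5, 0.5))   # FALSE
#' @export
has_discriminatory_power <- function(profile) {
  stopifnot(inherits(profile, "test_profile"))
  profile$tpr + profile$tnr > 1
}
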