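# Generalized Rogan-Gladen prevalence correction for aggregated testing
# protocols, and severity ratios (IFR/IHR) built on the corrected
# prevalence.

#' Measured (apparent) prevalence implied by a true prevalence
#'
#' Under a protocol with aggregated characteristics `(tpr_s, tnr_s)`, a
#' true prevalence `f` produces the apparent positivity rate
#' `f* = f * tpr_s + (1 - f) * (1 - tnr_s)`. This is the forward map that
#' [correct_prevalence()] inverts.
#'
#' @param f True prevalence.
#' @param agg An `aggregate_characteristics` (or single [test_profile]).
#' @return The measured prevalence.
#' @export
measured_from_true <- function(f, agg) {
  check_prob(f, "f")
  ch <- char_of(agg)
  f * ch$tpr + (1 - f) * (1 - ch$tnr)
}

#' Rogan-Gladen prevalence correction for an aggregated protocol
#'
#' Inverts the apparent-positivity map of the combined protocol:
#' `f_hat = (measured + tnr_s - 1) / (tpr_s + tnr_s - 1)`. This
#' generalizes the classical single-test Rogan-Gladen estimator to any
#' Boolean aggregation of tests, via the protocol's aggregated
#' sensitivity and specificity. The raw inverse can fall outside
#' \[0, 1\] (e.g. a measured prevalence below the protocol's
#' false-positive floor); the returned record keeps both the raw value
#' and the clamped value together with a `clamped` flag, and downstream
#' severity computations use the clamped estimate.
#'
#' @param measured Measured (apparent) prevalence, a probability.
#' @param agg An `aggregate_characteristics` (or single [test_profile]).
#' @param stratum Optional stratum label carried through to the record.
#' @return An object of class `prevalence_record`: a list with fields
#'   `stratum`, `measured`, `corrected` (clamped), `corrected_raw`, and
#'   `clamped`.
#' @examples
#' agg <- and_characteristics(list(test_profile("igg", 0.831, 1),
#'                                 test_profile("elisa", 0.911, 1)))
#' correct_prevalence(0.019, agg) # corrected ~ 2.5%
#' @export
correct_prevalence <- function(measured, agg, stratum = "all") {
  check_prob(measured, "measured")
  ch <- char_of(agg)
  denom <- ch$tpr + ch$tnr - 1
  if (denom == 0)
    stop("prevalence correction undefined: tpr_s + tnr_s = 1 ",
         "(non-informative protocol)", call. = FALSE)
  raw <- (measured + ch$tnr - 1) / denom
  clamped <- min(max(raw, 0), 1)
  if (clamped != raw)
    warning(sprintf(
      "corrected prevalence %.4g clamped into [0, 1] for stratum \"%s\"",
      raw, stratum), call. = FALSE)
  structure(list(stratum = stratum, measured = measured,
                 corrected = clamped, corrected_raw = raw,
                 clamped = clamped != raw),
            class = "prevalence_record")
}

#' @export
print.prevalence_record <- function(x, ...) {
  cat(sprintf("<prevalence_record> %s: measured %.1f%% -> corrected %.1f%%%s\n",
              x$stratum, 100 * x$measured, 100 * x$corrected,
              if (x$clamped) sprintf(" (raw %.4g, clamped)", x$corrected_raw)
              else ""))
  invisible(x)
}

#' Severity ratio (IFR / IHR)
#'
#' Divides a cumulative event count (fatalities for the infection
#' fatality ratio, hospitalizations for the infection hospitalization
#' ratio) by the estimated number of infections `f_hat * N` in the
#' stratum of population size `N`.
#'
#' @param count Event count (number of fatalities or hospitalizations).
#' @param f_hat Corrected prevalence estimate, must be > 0.
#' @param N Population size of the stratum, must be > 0.
#' @return The severity ratio.
#' @examples
#' agg <- and_characteristics(list(test_profile("igg", 0.831, 1),
#'                                 test_profile("elisa", 0.911, 1)))
#' f_hat <- correct_prevalence(0.019, agg)$corrected
#' severity_ratio(59, f_hat, 249614)  # IFR ~ 0.9%
#' severity_ratio(242, f_hat, 249614) # IHR ~ 3.9%
#' @export
severity_ratio <- function(count, f_hat, N) {
  stopifnot(is.numeric(count), length(count) == 1L, count >= 0,
            is.numeric(N), length(N) == 1L)
  if (!is.numeric(f_hat) || length(f_hat) != 1L || f_hat <= 0 || N <= 0)
    stop("severity ratio undefined: requires f_hat > 0 and N > 0",
         call. = FALSE)
  if (count > N)
    stop("event count exceeds the stratum population", call. = FALSE)
  count / (f_hat * N)
}

#' Correct measured prevalences for a table of strata
#'
#' Applies the generalized Rogan-Gladen correction stratum by stratum
#' and, where fatality/hospitalization counts and population sizes are
#' present, computes IFR and IHR. When a measured 95% CI is supplied and
#' `n_samples > 0`, Monte Carlo 95% CIs for the corrected prevalence are
#' propagated with [mc_propagate()] from beta distributions fitted to
#' the measured prevalence and to each test's reported CIs.
#'
#' @param strata Data frame with columns `stratum`, `measured`, and
#'   optionally `measured_lo`, `measured_hi`, `fatalities`,
#'   `hospitalizations`, `population`.
#' @param profiles List of [test_profile]s making up the protocol.
#' @param rule Rule specification for [parse_rule()] (default `"AND"`).
#' @param n_samples Monte Carlo sample count (0 disables CI
#'   propagation).
#' @param seed Integer seed for the Monte Carlo draws.
#' @return A data frame with the input columns plus `corrected`,
#'   `corrected_raw`, `clamped`, optional `corrected_lo`/`corrected_hi`,
#'   and optional `ifr`, `ihr`.
#' @export
correct_prevalence_table <- function(strata, profiles, rule = "AND",
                                     n_samples = 1e5, seed = 1L) {
  stopifnot(is.data.frame(strata),
            all(c("stratum", "measured") %in% names(strata)))
  profiles <- check_profiles(profiles)
  rule <- if (is.character(rule)) parse_rule(rule, length(profiles)) else rule
  agg <- rule_characteristics(rule, profiles)
  recs <- lapply(seq_len(nrow(strata)), function(i)
    correct_prevalence(strata$measured[i], agg,
                       stratum = as.character(strata$stratum[i])))
  out <- strata
  out$corrected <- vapply(recs, `[[`, numeric(1), "corrected")
  out$corrected_raw <- vapply(recs, `[[`, numeric(1), "corrected_raw")
  out$clamped <- vapply(recs, `[[`, logical(1), "clamped")

  has_ci <- all(c("measured_lo", "measured_hi") %in% names(strata))
  if (has_ci && n_samples > 0) {
    out$corrected_lo <- NA_real_
    out$corrected_hi <- NA_real_
    for (i in seq_len(nrow(out))) {
      if (is.na(strata$measured_lo[i]) || is.na(strata$measured_hi[i])) next
      inputs <- c(
        list(measured = c(strata$measured[i], strata$measured_lo[i],
                          strata$measured_hi[i])),
        profile_mc_inputs(profiles)
      )
      cs <- mc_propagate(corrected_prevalence_fn(rule, length(profiles)),
                         inputs, n_samples = n_samples, seed = seed + i)
      out$corrected_lo[i] <- cs$lo
      out$corrected_hi[i] <- cs$hi
    }
  }
  if (all(c("fatalities", "population") %in% names(strata)))
    out$ifr <- strata$fatalities / (out$corrected * strata$population)
  if (all(c("hospitalizations", "population") %in% names(strata)))
    out$ihr <- strata$hospitalizations / (out$corrected * strata$population)
  out
}

# Internal: Monte Carlo input summaries for each profile's tpr/tnr; a
# characteristic without a CI enters as a fixed constant.
profile_mc_inputs <- function(profiles) {
  inputs <- list()
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    inputs[[paste0("tpr", i)]] <-
      if (is.null(p$tpr_ci)) p$tpr else c(p$tpr, p$tpr_ci)
    inputs[[paste0("tnr", i)]] <-
      if (is.null(p$tnr_ci)) p$tnr else c(p$tnr, p$tnr_ci)
  }
  inputs
}

# Internal: vectorized corrected-prevalence pipeline for mc_propagate.
# Receives per-draw vectors measured, tpr1..tprn, tnr1..tnrn; rebuilds
# the rule characteristics per draw and inverts, clamping into [0, 1].
corrected_prevalence_fn <- function(rule, n) {
  plus <- rule$outputs == "+"
  bits <- outcome_bits(n)
  function(measured, ...) {
    args <- list(...)
    n_draw <- length(measured)
    tpr_s <- numeric(n_draw)
    tnr_s <- numeric(n_draw)
    for (j in seq_len(nrow(bits))) {
      prob_pos <- rep(1, n_draw)
      prob_neg <- rep(1, n_draw)
      for (i in seq_len(n)) {
        ti <- args[[paste0("tpr", i)]]
        si <- args[[paste0("tnr", i)]]
        if (bits[j, i] == 1L) {
          prob_pos <- prob_pos * ti
          prob_neg <- prob_neg * (1 - si)
        } else {
          prob_pos <- prob_pos * (1 - ti)
          prob_neg <- prob_neg * si
        }
      }
      if (plus[j]) tpr_s <- tpr_s + prob_pos else tnr_s <- tnr_s + prob_neg
    }
    raw <- (measured + tnr_s - 1) / (tpr_s + tnr_s - 1)
    raw[tpr_s + tnr_s == 1] <- NA_real_
    pmin(pmax(raw, 0), 1)
  }
}
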