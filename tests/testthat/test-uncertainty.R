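test_that("beta fits round-trip exact quantile summaries", {
  q <- stats::qbeta(c(0.025, 0.5, 0.975), 2, 5)
  sh <- fit_beta(q[2], q[1], q[3])
  expect_lt(abs(sh$alpha - 2) / 2, 0.01)
  expect_lt(abs(sh$beta - 5) / 5, 0.01)
  # shapes across the practical range
  for (ab in list(c(0.5, 0.5), c(1, 3), c(5, 80), c(50, 50), c(200, 120))) {
    q <- stats::qbeta(c(0.025, 0.5, 0.975), ab[1], ab[2])
    sh <- fit_beta(q[2], q[1], q[3])
    expect_lt(abs(sh$alpha - ab[1]) / ab[1], 0.01)
    expect_lt(abs(sh$beta - ab[2]) / ab[2], 0.01)
  }
})

test_that("a symmetric summary yields a symmetric beta", {
  sh <- fit_beta(0.5, 0.35, 0.65)
  expect_lt(abs(sh$alpha - sh$beta) / sh$alpha, 1e-3)
})

test_that("reported antigen sensitivity summary is captured within 0.005", {
  sh <- fit_beta(0.748, 0.676, 0.808)
  got <- stats::qbeta(c(0.025, 0.5, 0.975), sh$alpha, sh$beta)
  expect_lt(max(abs(got - c(0.676, 0.748, 0.808))), 0.005)
})

test_that("degenerate summaries are clipped or rejected", {
  expect_error(fit_beta(0.9, 0.9, 0.9), "zero-width")
  expect_error(fit_beta(0.5, 0.6, 0.9), "lo <= median <= hi")
  # boundary-touching summary fits after clipping quantile targets
  sh <- fit_beta(1, 0.965, 1)
  expect_gt(sh$alpha, 0)
  expect_gt(stats::qbeta(0.5, sh$alpha, sh$beta), 0.97)
})

test_that("Monte Carlo propagation is seed-reproducible and exact on constants", {
  fn <- function(p, q) p * q
  inputs <- list(p = c(0.9, 0.85, 0.94), q = 0.5)
  a <- mc_propagate(fn, inputs, n_samples = 2000, seed = 9)
  b <- mc_propagate(fn, inputs, n_samples = 2000, seed = 9)
  expect_identical(a, b)
  d <- mc_propagate(fn, inputs, n_samples = 2000, seed = 10)
  expect_false(identical(a$median, d$median))
  const <- mc_propagate(fn, list(p = 0.8, q = 0.5), n_samples = 1000, seed = 1)
  expect_equal(const$median, 0.4)
  expect_equal(const$hi - const$lo, 0)
  # zero-width CI treated as constant
  cw <- mc_propagate(fn, list(p = c(0.8, 0.8, 0.8), q = 0.5),
                     n_samples = 1000, seed = 1)
  expect_equal(cw$median, 0.4)
})

test_that("undefined draws are discarded, counted, and flagged past 1%", {
  fn <- function(p) ifelse(p > 0.5, p, NA_real_)
  cs <- mc_propagate(fn, list(p = c(0.6, 0.3, 0.85)),
                     n_samples = 2000, seed = 3)
  expect_gt(cs$n_discarded, 0)
  expect_true(cs$flagged)
  expect_error(
    mc_propagate(function(p) rep(NA_real_, length(p)),
                 list(p = c(0.5, 0.4, 0.6)), n_samples = 1000, seed = 1),
    "every draw")
})

test_that("intervals tighten as the sample count grows", {
  fn <- function(p, q) p * q
  inputs <- list(p = c(0.7, 0.6, 0.8), q = c(0.9, 0.85, 0.95))
  w_small <- with(mc_propagate(fn, inputs, 1000, seed = 2), hi - lo)
  w_big <- with(mc_propagate(fn, inputs, 50000, seed = 2), hi - lo)
  expect_lt(w_big, w_small + 3 * w_small / sqrt(1000))
})

test_that("serosurvey corrected-prevalence interval brackets the point estimate", {
  panel <- antibody_panel()
  rule <- parse_rule("AND", 2)
  inputs <- list(measured = c(0.019, 0.008, 0.037),
                 tpr1 = c(0.831, 0.754, 1.000),
                 tnr1 = 1,
                 tpr2 = c(0.911, 0.807, 0.961),
                 tnr2 = c(1.000, 0.965, 1.000))
  fn <- testfuse:::corrected_prevalence_fn(rule, 2)
  cs <- mc_propagate(fn, inputs, n_samples = 20000, seed = 11)
  point <- correct_prevalence(0.019, and_characteristics(panel))$corrected
  expect_lt(cs$lo, point)
  expect_gt(cs$hi, point)
  # plausibility against the published 1.1--5.0% interval, not equality
  expect_gt(cs$lo, 0.004)
  expect_lt(cs$hi, 0.10)
  # two independent seeds agree within Monte Carlo error
  cs2 <- mc_propagate(fn, inputs, n_samples = 20000, seed = 12)
  expect_lt(abs(cs$median - cs2$median), 0.002)
})

test_that("Frechet bounds collapse for one test and match extremal couplings", {
  single <- list(test_profile("a", 0.8, 0.9))
  b <- frechet_bounds(single, "and")
  expect_equal(unname(b$tpr), c(0.8, 0.8))
  expect_equal(unname(b$tnr), c(0.9, 0.9))
  # comonotone / countermonotone couplings attain the AND-TPR endpoints
  p1 <- 0.9; p2 <- 0.8
  b2 <- frechet_bounds(list(test_profile("a", p1, 0.9),
                            test_profile("b", p2, 0.95)), "and")
  expect_equal(unname(b2$tpr), c(0.7, 0.8))
  # comonotone joint: P(Y1=1, Y2=1) = min(p1, p2)
  expect_equal(min(p1, p2), b2$tpr[["hi"]])
  # countermonotone joint: P(Y1=1, Y2=1) = max(0, p1 + p2 - 1)
  expect_equal(max(0, p1 + p2 - 1), b2$tpr[["lo"]])
  expect_error(frechet_bounds(random_profiles(2), "majority"), "odd")
})

test_that("independence closed forms always lie inside the Frechet bounds", {
  set.seed(71)
  inside <- function(x, iv) x >= iv[["lo"]] - 1e-12 && x <= iv[["hi"]] + 1e-12
  for (rep in 1:200) {
    n <- sample(2:3, 1)
    profiles <- random_profiles(n)
    a <- and_characteristics(profiles)
    o <- or_characteristics(profiles)
    ba <- frechet_bounds(profiles, "and")
    bo <- frechet_bounds(profiles, "or")
    expect_true(inside(a$tpr, ba$tpr) && inside(a$tnr, ba$tnr))
    expect_true(inside(o$tpr, bo$tpr) && inside(o$tnr, bo$tnr))
    if (n %% 2 == 1) {
      m <- majority_characteristics(profiles)
      bm <- frechet_bounds(profiles, "majority")
      expect_true(inside(m$tpr, bm$tpr) && inside(m$tnr, bm$tnr))
      # majority bounds span the union of the AND and OR bounds
      expect_lte(bm$tpr[["lo"]], ba$tpr[["lo"]] + 1e-12)
      expect_gte(bm$tpr[["hi"]], bo$tpr[["hi"]] - 1e-12)
    }
  }
})

test_that("dependence factors match a hand contingency-count oracle", {
  # among 100 truly positive subjects: both positive 40, test i positive
  # 50, test j positive 60 -> lambda = 0.40 / (0.5 * 0.6)
  yi <- c(rep(1, 40), rep(1, 10), rep(0, 20), rep(0, 30))
  yj <- c(rep(1, 40), rep(0, 10), rep(1, 20), rep(0, 30))
  df <- data.frame(status = 1L, ti = yi, tj = yj)
  # add a negative class so lambda_nn is defined too
  df <- rbind(df, data.frame(status = 0L,
                             ti = rep(c(0, 1), c(90, 10)),
                             tj = rep(c(0, 1, 0), c(80, 10, 10))))
  dep <- dependence_factors(df)
  expect_equal(dep$lambda_pp["ti", "tj"], 0.40 / (0.5 * 0.6))
  expect_equal(dep$lambda_pp["ti", "tj"], dep$lambda_pp["tj", "ti"])
  expect_equal(dep$counts_pos["ti", "tj"], 100L)
})

test_that("a test paired with its duplicate gives lambda = 1 / tpr empirically", {
  set.seed(73)
  y <- stats::rbinom(4000, 1, 0.7)
  df <- data.frame(status = 1L, a = y, b = y)
  df <- rbind(df, data.frame(status = 0L,
                             a = stats::rbinom(500, 1, 0.1),
                             b = stats::rbinom(500, 1, 0.1)))
  dep <- dependence_factors(df)
  expect_equal(dep$lambda_pp["a", "b"],
               1 / mean(df$a[df$status == 1]), tolerance = 1e-12)
})

test_that("pairs with no information are unavailable, never zero", {
  df <- data.frame(status = c(1L, 1L, 0L, 0L),
                   a = c(1L, 0L, NA, NA), b = c(NA, NA, 0L, 1L))
  dep <- dependence_factors(df)
  expect_true(is.na(dep$lambda_pp["a", "b"]))
  expect_true(is.na(dep$lambda_nn["a", "b"]))
  # zero marginal frequency also yields NA
  df2 <- data.frame(status = 1L, a = c(0L, 0L, 0L), b = c(1L, 0L, 1L))
  df2 <- rbind(df2, data.frame(status = 0L, a = 0L, b = 0L))
  expect_true(is.na(dependence_factors(df2)$lambda_pp["a", "b"]))
})
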