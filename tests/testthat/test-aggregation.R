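test_that("parse_rule materializes named rules, truth tables, and expressions", {
  expect_equal(rule_string(parse_rule("AND", 2)), "+---")
  expect_equal(rule_string(parse_rule("OR", 2)), "+++-")
  expect_equal(rule_string(parse_rule("(1&2)|3", 3)), "+++-+-+-")
  expect_equal(rule_string(parse_rule("1|3", 3)), "+++++-+-")
  expect_equal(rule_string(parse_rule("3", 3)), "+-+-+-+-")
  expect_equal(rule_string(parse_rule("2-of-3", 3)),
               rule_string(rule_k_of_n(2, 3)))
  expect_equal(rule_string(parse_rule("+--+", 2)), "+--+")
  expect_equal(rule_string(parse_rule("!1", 1)), "-+")
  # words as operator synonyms
  expect_equal(rule_string(parse_rule("(1 AND 2) OR 3", 3)), "+++-+-+-")
})

test_that("parse_rule rejects malformed specifications", {
  expect_error(parse_rule("+--", 2), "length 2\\^n = 4")
  expect_error(parse_rule("MAJORITY", 2), "odd")
  expect_error(parse_rule("1&4", 3), "references test 4")
  expect_error(parse_rule("1&&|2", 2), "malformed")
  expect_error(parse_rule("1%2", 2), "only test identifiers")
  expect_error(parse_rule("5-of-3", 3), "k.*must be an integer in \\[1, 3\\]")
})

test_that("rule_characteristics matches the brute-force joint-distribution oracle", {
  set.seed(101)
  for (n in 1:4) {
    for (rep in 1:5) {
      profiles <- random_profiles(n)
      tprs <- vapply(profiles, `[[`, numeric(1), "tpr")
      tnrs <- vapply(profiles, `[[`, numeric(1), "tnr")
      signs <- sample(c("+", "-"), 2^n, replace = TRUE)
      got <- rule_characteristics(aggregation_rule(signs), profiles)
      want <- oracle_characteristics(signs, tprs, tnrs)
      expect_equal(got$tpr, want[["tpr"]], tolerance = 1e-12)
      expect_equal(got$tnr, want[["tnr"]], tolerance = 1e-12)
    }
  }
})

test_that("constant rules give the trivial limiting characteristics", {
  profiles <- random_profiles(3)
  all_pos <- rule_characteristics(aggregation_rule(strrep("+", 8)), profiles)
  all_neg <- rule_characteristics(aggregation_rule(strrep("-", 8)), profiles)
  expect_equal(c(all_pos$tpr, all_pos$tnr), c(1, 0))
  expect_equal(c(all_neg$tpr, all_neg$tnr), c(0, 1))
})

test_that("AND and OR closed forms agree with their truth tables", {
  profiles <- list(test_profile("a", 0.95, 0.95),
                   test_profile("b", 0.90, 0.95))
  a <- and_characteristics(profiles)
  expect_equal(a$tpr, 0.855)
  expect_equal(a$tnr, 0.9975)
  expect_equal(a$tpr, rule_characteristics("+---", profiles)$tpr)
  expect_equal(a$tnr, rule_characteristics("+---", profiles)$tnr)
  o <- or_characteristics(profiles)
  expect_equal(o$tpr, rule_characteristics("+++-", profiles)$tpr)
  expect_equal(o$tnr, rule_characteristics("+++-", profiles)$tnr)
  # two perfect tests
  perfect <- list(test_profile("p1", 1, 1), test_profile("p2", 1, 1))
  expect_equal(c(and_characteristics(perfect)$tpr,
                 and_characteristics(perfect)$tnr), c(1, 1))
  expect_equal(c(or_characteristics(perfect)$tpr,
                 or_characteristics(perfect)$tnr), c(1, 1))
})

test_that("antibody AND protocol reproduces its aggregated sensitivity", {
  agg <- and_characteristics(antibody_panel())
  expect_equal(agg$tpr, 0.831 * 0.911, tolerance = 1e-12)
  expect_equal(agg$tnr, 1)
})

test_that("k-of-n collapses to OR at k = 1 and AND at k = n", {
  set.seed(7)
  profiles <- random_profiles(3)
  expect_equal(k_of_n_characteristics(profiles, 1)$tpr,
               or_characteristics(profiles)$tpr)
  expect_equal(k_of_n_characteristics(profiles, 1)$tnr,
               or_characteristics(profiles)$tnr)
  expect_equal(k_of_n_characteristics(profiles, 3)$tpr,
               and_characteristics(profiles)$tpr)
  expect_equal(k_of_n_characteristics(profiles, 3)$tnr,
               and_characteristics(profiles)$tnr)
  expect_error(k_of_n_characteristics(profiles, 4), "k")
})

test_that("majority of three identical tests matches the pairwise closed form", {
  # tpr = sum of pairwise products - 2 * triple product, same for tnr
  profiles <- replicate(3, test_profile("t", 0.8, 0.9), simplify = FALSE)
  m <- k_of_n_characteristics(profiles, 2)
  expect_equal(m$tpr, 3 * 0.8^2 - 2 * 0.8^3)  # 0.896
  expect_equal(m$tnr, 3 * 0.9^2 - 2 * 0.9^3)  # 0.972
  expect_equal(m$tpr, 0.896)
  expect_equal(m$tnr, 0.972)
  perfect <- replicate(3, test_profile("p", 1, 1), simplify = FALSE)
  expect_equal(majority_characteristics(perfect)$tpr, 1)
  expect_equal(majority_characteristics(perfect)$tnr, 1)
  # symbolic check with unequal tests
  set.seed(11)
  pr <- random_profiles(3)
  t_ <- vapply(pr, `[[`, numeric(1), "tpr")
  s_ <- vapply(pr, `[[`, numeric(1), "tnr")
  mm <- majority_characteristics(pr)
  expect_equal(mm$tpr,
               t_[1] * t_[2] + t_[1] * t_[3] + t_[2] * t_[3] -
                 2 * prod(t_), tolerance = 1e-12)
  expect_equal(mm$tnr,
               s_[1] * s_[2] + s_[1] * s_[3] + s_[2] * s_[3] -
                 2 * prod(s_), tolerance = 1e-12)
})

test_that("AND/OR bound individual tests and sandwich the majority rule", {
  set.seed(23)
  for (rep in 1:50) {
    n <- sample(2:4, 1)
    profiles <- random_profiles(n)
    tprs <- vapply(profiles, `[[`, numeric(1), "tpr")
    tnrs <- vapply(profiles, `[[`, numeric(1), "tnr")
    a <- and_characteristics(profiles)
    o <- or_characteristics(profiles)
    expect_true(a$tpr <= min(tprs) + 1e-12 && max(tprs) <= o$tpr + 1e-12)
    expect_true(o$tnr <= min(tnrs) + 1e-12 && max(tnrs) <= a$tnr + 1e-12)
    if (n %% 2 == 1) {
      m <- majority_characteristics(profiles)
      expect_true(a$tpr <= m$tpr + 1e-12 && m$tpr <= o$tpr + 1e-12)
      expect_true(o$tnr <= m$tnr + 1e-12 && m$tnr <= a$tnr + 1e-12)
    }
  }
})

test_that("complementing every output sign maps (tpr, tnr) to (1-tpr, 1-tnr)", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(1:3, 1)
    profiles <- random_profiles(n)
    signs <- sample(c("+", "-"), 2^n, replace = TRUE)
    flipped <- ifelse(signs == "+", "-", "+")
    ch <- rule_characteristics(aggregation_rule(signs), profiles)
    chf <- rule_characteristics(aggregation_rule(flipped), profiles)
    expect_equal(chf$tpr, 1 - ch$tpr, tolerance = 1e-12)
    expect_equal(chf$tnr, 1 - ch$tnr, tolerance = 1e-12)
  }
})

test_that("profile count must match the rule arity", {
  profiles <- random_profiles(2)
  expect_error(rule_characteristics(parse_rule("AND", 3), profiles),
               "expected 3 profiles")
  expect_error(and_characteristics(list()), "non-empty list")
})
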