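test_that("value functions map raw performance to ratings as specified", {
  expect_equal(apply_value_function(0, value_function("one_minus_risk"),
                                    "harm"), 1)
  expect_equal(apply_value_function(0.3, value_function("one_minus_risk"),
                                    "harm"), 0.7)
  expect_error(apply_value_function(1.2, value_function("one_minus_risk"),
                                    "harm"), "probability")

  vf <- value_function("linear_anchor", worst_raw = 30, best_raw = 0,
                       units = "days")
  expect_equal(apply_value_function(15, vf, "harm"), 0.5)
  expect_equal(apply_value_function(45, vf, "harm"), 0)  # clipped
  expect_error(apply_value_function(15, vf, "harm", units = "hours"),
               "units mismatch")
  expect_error(value_function("linear_anchor", worst_raw = 5, best_raw = 5),
               "must differ")

  vf2 <- value_function("reference_anchored", reference_rating = 0.5,
                        scale = 0.5)
  expect_equal(apply_value_function(0.24, vf2, "harm"), 0.62)
  expect_equal(apply_value_function(-0.01, vf2, "harm"), 0.495)

  expect_equal(apply_value_function(1.7, value_function("identity"),
                                    "benefit"), 1)  # clipped
})

test_that("expected-value scores are the weighted sum of ratings", {
  # identical ratings across options => identical scores
  crits <- lapply(1:4, function(j) criterion(paste0("c", j)))
  m <- decision_model(c("A", "B"), crits,
                      matrix(rep(c(0.2, 0.6, 0.9, 0.1), each = 2), nrow = 2))
  s <- expected_value_scores(m, rep(1, 4))
  expect_equal(unname(s[1]), unname(s[2]))

  # all weight on one criterion => score equals the rating there
  s1 <- expected_value_scores(m, c(0, 0, 1, 0))
  expect_equal(unname(s1), unname(m$ratings[, 3]))

  # bundled model under equal weights vs the naive double-loop oracle
  fx <- tavi_savr_model()
  w <- equal_weights(fx)
  expect_equal(expected_value_scores(fx, w),
               naive_scores(fx, w$normalized), tolerance = 1e-9)

  expect_error(mcda_score(fx, rep(1, 4)), "criteria")
})

test_that("score contributions break down exactly and scores stay in [0,1]", {
  set.seed(11)
  for (rep in 1:20) {
    m <- random_model(sample(2:6, 1), sample(2:12, 1))
    w <- random_weights(m)
    s <- mcda_score(m, w, mode = sample(c("multiplicative", "shrink"), 1))
    expect_equal(rowSums(s$contributions$unadjusted), s$unadjusted,
                 tolerance = 1e-9)
    expect_equal(rowSums(s$contributions$adjusted), s$adjusted,
                 tolerance = 1e-9)
    expect_true(all(s$unadjusted >= 0 & s$unadjusted <= 1))
    expect_true(all(s$adjusted >= 0 & s$adjusted <= 1))
  }
})

test_that("certainty adjustment behaves at its limits in both modes", {
  fx <- tavi_savr_model(overrides = list(
    certainty = setNames(rep("high", 7),
                         c("mortality", "stroke", "bleeding",
                           "atrial_fibrillation", "heart_failure",
                           "pacemaker", "reintervention"))))
  w <- equal_weights(fx)
  for (mode in c("multiplicative", "shrink")) {
    s <- mcda_score(fx, w, mode = mode)
    expect_equal(s$adjusted, s$unadjusted, tolerance = 1e-12)
  }

  # multiplicative adjustment can only shrink nonnegative ratings
  set.seed(5)
  for (rep in 1:10) {
    m <- random_model(2, 6)
    s <- mcda_score(m, random_weights(m), mode = "multiplicative")
    expect_true(all(s$adjusted <= s$unadjusted + 1e-12))
  }

  # multipliers -> 0 under shrink mode pull every score to neutral 0.5
  m <- random_model(3, 5)
  tiny <- certainty_mapping(0, 1e-12, 2e-12, 3e-12)
  s <- mcda_score(m, random_weights(m), mode = "shrink", mapping = tiny)
  expect_equal(unname(s$adjusted), rep(0.5, 3), tolerance = 1e-9)
})

test_that("fixture scores with moderate evidence certainty match the extended oracle", {
  fx <- tavi_savr_model()  # evidence criteria default to moderate
  # put everything on moderate so the oracle's c = 0.7 applies uniformly
  fx_mod <- tavi_savr_model(overrides = list(
    certainty = setNames(rep("moderate", 3),
                         c("avoid_open_heart", "recovery_burden",
                           "valve_durability"))))
  w <- equal_weights(fx_mod)
  for (mode in c("multiplicative", "shrink")) {
    s <- mcda_score(fx_mod, w, mode = mode)
    expect_equal(s$adjusted, naive_scores(fx_mod, w$normalized, mode = mode),
                 tolerance = 1e-9)
  }
  # and the mixed-certainty default against the same oracle
  w0 <- equal_weights(fx)
  s0 <- mcda_score(fx, w0)
  expect_equal(s0$adjusted,
               naive_scores(fx, w0$normalized, mode = "multiplicative"),
               tolerance = 1e-9)
})

test_that("scores are invariant under consistent permutation of criteria", {
  set.seed(23)
  for (rep in 1:10) {
    k <- sample(3:10, 1)
    m <- random_model(2, k)
    w <- random_weights(m)
    s <- mcda_score(m, w)
    p <- sample(k)
    mp <- decision_model(m$options, m$criteria[p],
                         m$ratings[, p, drop = FALSE])
    wp <- normalize_weights(w$raw[p])
    sp <- mcda_score(mp, wp)
    expect_equal(sp$unadjusted, s$unadjusted, tolerance = 1e-12)
    expect_equal(sp$adjusted, s$adjusted, tolerance = 1e-12)
  }
})

test_that("dominance is detected exactly when one option is weakly better everywhere", {
  expect_true(is.na(dominance_check(tavi_savr_model())$dominant))

  crits <- lapply(1:3, function(j) criterion(paste0("c", j)))
  dom <- decision_model(c("A", "B"), crits,
                        matrix(c(0.9, 0.1, 0.8, 0.2, 0.7, 0.3), nrow = 2))
  expect_identical(dominance_check(dom)$dominant, "A")
  expect_true(all(dominance_check(dom)$comparison == "first_better"))

  tie <- decision_model(c("A", "B"), crits,
                        matrix(rep(c(0.4, 0.4), 3), nrow = 2))
  expect_true(is.na(dominance_check(tie)$dominant))
  expect_true(all(dominance_check(tie)$comparison == "tie"))

  # weak dominance: >= everywhere, > somewhere
  weak <- decision_model(c("A", "B"), crits,
                         matrix(c(0.5, 0.5, 0.8, 0.2, 0.5, 0.5), nrow = 2))
  expect_identical(dominance_check(weak)$dominant, "A")
})

test_that("a dominant option scores at least as high under any weighting", {
  set.seed(99)
  found <- 0
  while (found < 30) {
    m <- random_model(2, sample(2:8, 1))
    res <- dominance_check(m)
    if (is.na(res$dominant)) next
    found <- found + 1
    better <- match(res$dominant, m$options)
    other <- 3 - better
    for (draw in 1:30) {
      w <- random_weights(m)
      s <- expected_value_scores(m, w)
      expect_gte(s[better], s[other])
      strictly <- res$comparison == if (better == 1) "first_better" else "second_better"
      if (any(w$normalized[strictly] > 0)) expect_gt(s[better], s[other])
    }
  }
})

test_that("score object methods expose the fit like a fitted model", {
  fx <- tavi_savr_model()
  w <- equal_weights(fx)
  s <- mcda_score(fx, w)
  cf <- coef(s)
  expect_identical(dim(cf), c(2L, 2L))
  expect_identical(colnames(cf), c("unadjusted", "adjusted"))
  sm <- summary(s)
  expect_identical(sm$preferred_unadjusted, "TAVI")
  expect_output(print(s), "multiplicative")

  sh <- simulate(s, nsim = 500, seed = 3, model = fx)
  expect_s3_class(sh, "preference_shares")
  expect_equal(sum(sh$shares), 1, tolerance = 1e-9)
  fx2 <- set_user_rating(fx, "avoid_open_heart", "SAVR", 0.7)
  expect_error(simulate(s, nsim = 10, seed = 1, model = fx2), "stale")
})
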