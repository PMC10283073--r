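test_that("compose_local is the inclusion-exclusion union with its bounds", {
  expect_equal(compose_local(0.5, 0.5), 0.75)
  expect_equal(compose_local(0, 0.37), 0.37)
  expect_equal(compose_local(1, 0.2), 1)
  g <- seq(0, 1, length.out = 100)
  grid <- expand.grid(p = g, q = g)
  u <- compose_local(grid$p, grid$q)
  expect_identical(u, grid$p + grid$q - grid$p * grid$q)
  expect_identical(u, compose_local(grid$q, grid$p))  # symmetric
  expect_true(all(u >= pmax(grid$p, grid$q) - 1e-15))
  expect_true(all(u <= pmin(1, grid$p + grid$q) + 1e-15))
})

test_that("condition scores follow their definitions", {
  cs <- curve_set(
    response_curve("simple", simple_params(1, -10), "target", 60),
    response_curve("simple", simple_params(1, -12), "neighboring", 60),
    response_curve("simple", simple_params(1, -15), "death", 60))
  x <- c(8, 10, 12)
  pt <- predict(cs$target, x)
  pn <- predict(cs$neighboring, x)
  pd <- predict(cs$death, x)
  expect_equal(condition_score(cs, 1, x), pt * (1 - pn))
  expect_equal(condition_score(cs, 2, x),
               compose_local(pt, pn) * (1 - pd))
  # a direct local curve is used when present
  cs2 <- curve_set(cs$target, cs$neighboring, cs$death,
                   local = response_curve("simple", simple_params(1, -11),
                                          "local", 60))
  expect_equal(condition_score(cs2, 2, x),
               predict(cs2$local, x) * (1 - pd))
  # hand arithmetic: p_t = 0.6, p_n = 0.5 gives condition-1 score 0.30
  cs3 <- curve_set(
    response_curve("simple", simple_params(0, qlogis(0.6)), "target", 60),
    response_curve("simple", simple_params(0, 0), "neighboring", 60),
    response_curve("simple", simple_params(0, -35), "death", 60))
  expect_equal(condition_score(cs3, 1, 10), 0.6 * 0.5)
  # p_neighboring = 0: condition 1 equals p_target
  cs4 <- curve_set(cs$target,
                   response_curve("simple", simple_params(0, -35),
                                  "neighboring", 60),
                   cs$death)
  expect_equal(condition_score(cs4, 1, x), pt, tolerance = 1e-10)
  # p_death = 1: condition 2 is zero everywhere
  cs5 <- curve_set(cs$target, cs$neighboring,
                   response_curve("simple", simple_params(0, 35), "death", 60))
  expect_equal(condition_score(cs5, 2, x), rep(0, 3), tolerance = 1e-10)
})

test_that("optimize_condition matches an exhaustive 0.001-mW scan", {
  set.seed(88)
  for (i in 1:25) {
    cs <- random_simple_curve_set()
    cond <- sample(1:2, 1)
    rec <- optimize_condition(cs, cond, c(5.5, 20))
    fine <- seq(5.5, 20, by = 0.001)
    scores <- condition_score(cs, cond, fine)
    best <- fine[which.max(scores)]
    expect_lt(abs(rec$optimal_power - best), 0.01)
    # no strictly better score anywhere on the oracle grid
    expect_lte(max(scores), rec$achieved_score + 1e-9)
  }
})

test_that("optimize_condition boundary and degenerate cases", {
  # no neighbor response, no death: score increases monotonically
  cs <- curve_set(
    response_curve("simple", simple_params(1, -10), "target", 60),
    response_curve("simple", simple_params(0, -35), "neighboring", 60),
    response_curve("simple", simple_params(0, -35), "death", 60))
  rec <- optimize_condition(cs, 1, c(5.5, 20))
  expect_equal(rec$optimal_power, 20, tolerance = 1e-6)
  # death certain everywhere: condition-2 score identically ~0
  cs0 <- curve_set(cs$target, cs$neighboring,
                   response_curve("simple", simple_params(0, 40), "death", 60))
  rec0 <- optimize_condition(cs0, 2, c(5.5, 20))
  expect_true(rec0$degenerate)
  expect_equal(rec0$optimal_power, 5.5)
})

test_that("raising_point matches the closed-form inverse on random curves", {
  set.seed(99)
  for (i in 1:50) {
    lim <- runif(1, 0.15, 1)
    a <- runif(1, 0.3, 2)
    b <- -a * runif(1, 6, 14)
    t <- runif(1, 0.05, lim * 0.9)
    curve <- response_curve("bounded", bounded_params(lim, a, b), "target", 60)
    closed <- (qlogis(t / lim) - b) / a
    rng <- c(max(0.01, closed - 8), closed + 8)
    rp <- raising_point(curve, t, rng)
    expect_identical(rp$status, "ok")
    expect_lt(abs(predict(curve, rp$power) - t), 1e-6)
    expect_lt(abs(rp$power - closed), 1e-4)
  }
  # simple logistic with p(0) = 0.10: raising point at power 0
  curve <- response_curve("simple", simple_params(1, -log(9)), "target", 60)
  rp <- raising_point(curve, 0.10, c(0, 20))
  expect_equal(rp$power, 0, tolerance = 1e-6)
})

test_that("raising_point flags unreachable thresholds and bad curves", {
  low <- response_curve("bounded", bounded_params(0.08, 1, -10), "target", 60)
  rp <- raising_point(low, 0.10, c(0, 50))
  expect_identical(rp$status, "unreachable")
  expect_true(is.na(rp$power))
  flat <- response_curve("simple", simple_params(-0.5, 2), "target", 60)
  expect_error(raising_point(flat, 0.10, c(0, 20)), "not increasing")
  # thresholds rise monotonically along an increasing curve
  curve <- response_curve("bounded", bounded_params(0.6, 1, -10), "target", 60)
  powers <- vapply(c(0.05, 0.1, 0.2, 0.4),
                   function(t) raising_point(curve, t, c(0, 40))$power,
                   numeric(1))
  expect_true(all(diff(powers) > 0))
})

test_that("direct and composed local curves agree under independence", {
  ds <- simulate_trials(uniform_design(60, n_per_power = 5000),
                        active_truth_60s(), seed = 60)
  fits <- lapply(c(target = "target", neighboring = "neighboring",
                   death = "death", local = "local"),
                 function(ep) fit_logistic(ds, ep))
  cs <- curve_set(fits$target$curve, fits$neighboring$curve,
                  fits$death$curve)
  gap <- local_consistency_check(fits$local$curve, cs, c(5.5, 20))
  expect_lt(as.numeric(gap), 0.05)
  # identical direct and composed curves give zero discrepancy
  composed_as_direct <- fits$local$curve
  cs_same <- curve_set(
    response_curve("simple", simple_params(0, -35), "target", 60),
    composed_as_direct_n <- response_curve(
      "simple", composed_as_direct$params, "neighboring", 60),
    fits$death$curve)
  gap0 <- local_consistency_check(composed_as_direct, cs_same, c(5.5, 20))
  expect_lt(as.numeric(gap0), 1e-12)
})

test_that("correlated events inflate the direct-vs-composed discrepancy", {
  ind <- simulate_trials(uniform_design(60, n_per_power = 3000),
                         active_truth_60s(0), seed = 61)
  cor <- simulate_trials(uniform_design(60, n_per_power = 3000),
                         active_truth_60s(0.9), seed = 61)
  gap_of <- function(ds) {
    f <- lapply(c("target", "neighboring", "death", "local"),
                function(ep) fit_logistic(ds, ep)$curve)
    names(f) <- c("target", "neighboring", "death", "local")
    local_consistency_check(f$local, curve_set(f$target, f$neighboring,
                                               f$death), c(5.5, 20))
  }
  expect_gt(as.numeric(gap_of(cor)), as.numeric(gap_of(ind)))
})

test_that("size-conditional recommendations track the size effect", {
  mk <- function(ep, a1, a2, b) {
    response_curve("size", size_params(a1, a2, 0, b), ep, 60,
                   size_stats = list(mean = 3000, sd = 1500),
                   c_range = c(-2, 2))
  }
  # a2 > 0: larger cells respond at lower powers, so the recommended
  # power decreases with c
  cs <- curve_set(mk("target", 1.2, 1.0, -11), mk("neighboring", 1.0, 1.0, -13),
                  mk("death", 0.9, 1.0, -16))
  recs <- size_conditional_recommendation(cs, 1, c(3, 25), c(-1, 0, 1))
  powers <- vapply(recs, `[[`, numeric(1), "optimal_power")
  expect_true(all(diff(powers) < 0))
  # each matches its own brute-force scan
  for (k in seq_along(recs)) {
    fine <- seq(3, 25, by = 0.001)
    best <- fine[which.max(condition_score(cs, 1, fine, c = c(-1, 0, 1)[k]))]
    expect_lt(abs(powers[k] - best), 0.01)
  }
  # at c = 0 with no size terms the result equals the size-ignored one
  cs0 <- curve_set(mk("target", 1.2, 0, -11), mk("neighboring", 1.0, 0, -13),
                   mk("death", 0.9, 0, -16))
  red <- curve_set(
    response_curve("simple", simple_params(1.2, -11), "target", 60),
    response_curve("simple", simple_params(1.0, -13), "neighboring", 60),
    response_curve("simple", simple_params(0.9, -16), "death", 60))
  rec0 <- size_conditional_recommendation(cs0, 1, c(3, 25), 0)[[1]]
  rec_red <- optimize_condition(red, 1, c(3, 25))
  expect_equal(rec0$optimal_power, rec_red$optimal_power, tolerance = 1e-6)
  # far-outside c draws an extrapolation warning
  expect_warning(size_conditional_recommendation(cs, 1, c(3, 25), 5),
                 "outside")
  # size-free curves are refused
  expect_error(size_conditional_recommendation(red, 1, c(3, 25), 0),
               "size-aware")
})
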