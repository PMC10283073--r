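# shared fixtures and small oracles, built in code at test time

# a minimal valid records data frame
make_records <- function(n = 3, power = 10, duration = 60, size = NA_real_,
                         outcome = "NONE") {
  data.frame(
    trial_id = sprintf("t%03d", seq_len(n)),
    power_mw = rep_len(power, n),
    duration_s = rep_len(duration, n),
    cell_size_um2 = rep_len(size, n),
    tissue = rep_len("root epidermis", n),
    outcome = rep_len(outcome, n),
    stringsAsFactors = FALSE
  )
}

# one record of every outcome category, with assorted sizes
six_category_dataset <- function() {
  rec <- make_records(6)
  rec$outcome <- c("NONE", "TARGET_ONLY", "TARGET_AND_NEIGHBOR",
                   "NEIGHBOR_ONLY", "DEATH_TARGET", "DEATH_AND_EXPRESSION")
  rec$power_mw <- c(5.5, 8.5, 11.5, 14, 17, 20)
  rec$cell_size_um2 <- c(2000, 3000, 4000, NA, 2500, 3500)
  trial_dataset(rec)
}

# a two-arm Bernoulli dataset: k0/n0 successes at x0, k1/n1 at x1, on the
# target endpoint (TARGET_ONLY = success, NONE = failure)
two_point_dataset <- function(x0, n0, k0, x1, n1, k1) {
  rec <- make_records(n0 + n1)
  rec$power_mw <- c(rep(x0, n0), rep(x1, n1))
  rec$outcome <- c(rep("TARGET_ONLY", k0), rep("NONE", n0 - k0),
                   rep("TARGET_ONLY", k1), rep("NONE", n1 - k1))
  trial_dataset(rec)
}

# truth whose only active endpoint is the bounded target curve: the death
# and neighboring events are switched off so the observed target endpoint
# equals the latent event exactly (no lossy death-category collapse)
bounded_target_truth <- function(lim = 0.4, a = 1.5, b = -12) {
  off <- function(ep) response_curve("simple", simple_params(0, -35),
                                     endpoint = ep, duration = 60)
  truth_spec(
    target = response_curve("bounded", bounded_params(lim, a, b),
                            endpoint = "target", duration = 60),
    neighboring = off("neighboring"),
    death = off("death")
  )
}

# independent-endpoint truth with all three curves active (60-s shapes)
active_truth_60s <- function(correlation = 0) {
  truth_spec(
    target = response_curve("simple", simple_params(1.2, -10),
                            endpoint = "target", duration = 60),
    neighboring = response_curve("simple", simple_params(1.0, -12),
                                 endpoint = "neighboring", duration = 60),
    death = response_curve("simple", simple_params(0.9, -15.3),
                           endpoint = "death", duration = 60),
    correlation = correlation
  )
}

# random curve set of simple-family curves with ordered raising powers,
# for optimizer-vs-brute-force comparisons
random_simple_curve_set <- function() {
  mid_t <- runif(1, 7, 12)    # power at p = 0.5
  mid_n <- mid_t + runif(1, 0.5, 4)
  mid_d <- mid_n + runif(1, 0.5, 4)
  slope <- function() runif(1, 0.4, 2)
  mk <- function(mid, ep) {
    a <- slope()
    response_curve("simple", simple_params(a, -a * mid),
                   endpoint = ep, duration = 60)
  }
  curve_set(mk(mid_t, "target"), mk(mid_n, "neighboring"),
            mk(mid_d, "death"))
}

expect_prob <- function(p) {
  expect_true(all(p >= 0 & p <= 1))
}
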