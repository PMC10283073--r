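#' Replicate the published irradiation designs
#'
#' Returns the power-bin design of the root-epidermis experiments: for
#' 1-s irradiation, bins 10.0-16.0 mW (n = 20), 17.0-19.0 mW (n = 30)
#' and 20.0-24.0 mW (n = 40); for 60-s irradiation, 5.5-8.0 mW (n = 50),
#' 8.5-11.0 mW (n = 40), 11.5-14.0 mW (n = 30) and 15.0-20.0 mW (n = 9).
#' Within each bin individual trial powers are placed on a 0.5-mW
#' lattice, cycled so the trials spread uniformly over the bin (the
#' published figures give per-bin totals, not per-power counts).
#'
#' @param duration irradiation duration in seconds: 1 or 60.
#' @param inflate integer factor multiplying every per-bin n (for
#'   recovery studies on larger synthetic datasets).
#' @return object of class `design_spec`: list with `duration`, `bins`
#'   (data frame `lo`, `hi`, `n`) and `powers` (one entry per trial).
#' @export
replicate_design <- function(duration, inflate = 1L) {
  if (!duration %in% c(1, 60)) {
    stop("unsupported duration: ", duration, " s (use 1 or 60)")
  }
  stopifnot(inflate >= 1L)
  bins <- if (duration == 1) {
    data.frame(lo = c(10.0, 17.0, 20.0), hi = c(16.0, 19.0, 24.0),
               n = c(20L, 30L, 40L))
  } else {
    data.frame(lo = c(5.5, 8.5, 11.5, 15.0), hi = c(8.0, 11.0, 14.0, 20.0),
               n = c(50L, 40L, 30L, 9L))
  }
  bins$n <- bins$n * as.integer(inflate)
  powers <- unlist(lapply(seq_len(nrow(bins)), function(i) {
    lattice <- seq(bins$lo[i], bins$hi[i], by = 0.5)
    rep(lattice, length.out = bins$n[i])
  }))
  structure(list(duration = duration, bins = bins, powers = powers),
            class = "design_spec")
}

#' Balanced design with a fixed number of trials per power
#'
#' A design placing `n_per_power` trials at each supplied power — the
#' layout used by the parameter-recovery studies, where estimation
#' precision, not the historical per-bin allocation, is the point.
#'
#' @param duration irradiation duration in seconds (any positive value).
#' @param powers vector of laser powers in mW.
#' @param n_per_power trials at each power.
#' @return a `design_spec`, see [replicate_design()].
#' @export
uniform_design <- function(duration, powers = seq(5.5, 20, by = 0.5),
                           n_per_power = 1L) {
  stopifnot(duration > 0, all(powers > 0), n_per_power >= 1L)
  powers <- sort(powers)
  bins <- data.frame(lo = min(powers), hi = max(powers),
                     n = length(powers) * as.integer(n_per_power))
  structure(list(duration = duration, bins = bins,
                 powers = rep(powers, each = as.integer(n_per_power))),
            class = "design_spec")
}

#' Bin edges matching a design's printed bins
#'
#' Consecutive half-open bins covering the design's power span, suitable
#' for [bin_frequencies()]: each bin starts at its printed lower label
#' and ends where the next begins; the last bin is closed at the top.
#'
#' @param design a [replicate_design()] result.
#' @return numeric vector of k+1 edges.
#' @export
design_bin_edges <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  c(design$bins$lo, design$bins$hi[nrow(design$bins)])
}

#' Sample target-cell areas
#'
#' Lognormal cell areas calibrated to the observed average of about
#' 3,000 µm² with a coefficient of variation of 0.5:
#' `meanlog = ln(3000) - ln(1.25)/2`, `sdlog = sqrt(ln(1.25))`.
#'
#' @param n number of cells.
#' @param seed optional integer seed for reproducible draws.
#' @param mean_um2 distribution mean in µm² (default 3000).
#' @param cv coefficient of variation (default 0.5).
#' @return vector of n positive areas in µm².
#' @export
sample_cell_sizes <- function(n, seed = NULL, mean_um2 = 3000, cv = 0.5) {
  stopifnot(n >= 1, mean_um2 > 0, cv > 0)
  if (!is.null(seed)) set.seed(seed)
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = log(mean_um2) - s2 / 2, sdlog = sqrt(s2))
}

#' Specify the generative truth for simulated trials
#'
#' Holds the true response curves for the three latent per-trial events
#' — target-cell recombination (T), neighboring-cell recombination (N)
#' and cell death (D) — plus the cell-size distribution and an optional
#' dependence parameter.  The local endpoint is derived as `T or N`, so
#' its true curve is the inclusion-exclusion composition of the target
#' and neighboring curves.
#'
#' By default the three events are drawn independently at each trial,
#' which is exactly the assumption under which composing the local
#' probability from the target and neighboring ones is valid.  Setting
#' `correlation > 0` couples the events through a shared latent
#' "heat dose" variable (Gaussian copula) while preserving each event's
#' marginal curve — a stress test for the independence approximation.
#'
#' @param target,neighboring,death [response_curve()] objects (any
#'   family) giving each event's true probability versus power (and
#'   normalized size).
#' @param size_mean,size_cv cell-size distribution: mean (µm²) and
#'   coefficient of variation; normalized size is computed against these
#'   population values (`sd = cv * mean`).
#' @param correlation latent-variable correlation in `[0, 1)`; 0 =
#'   independent events.
#' @return object of class `truth_spec`.
#' @export
truth_spec <- function(target, neighboring, death, size_mean = 3000,
                       size_cv = 0.5, correlation = 0) {
  for (cv in list(target, neighboring, death)) {
    stopifnot(inherits(cv, "response_curve"))
  }
  stopifnot(size_mean > 0, size_cv > 0, correlation >= 0, correlation < 1)
  structure(list(target = target, neighboring = neighboring, death = death,
                 size_mean = size_mean, size_cv = size_cv,
                 correlation = correlation),
            class = "truth_spec")
}

#' Default generative truth curves per irradiation duration
#'
#' Plausible true curves consistent with the qualitative shape of the
#' published 1-s and 60-s root-epidermis experiments: raising points
#' ordered target < neighboring < death, a 60-s target curve that
#' plateaus near 40%, negligible response at the bottom of each design
#' and majority cell death at its top.  Used as the default truth of the
#' simulation front-end; recovery tests state their own truths.
#'
#' @param duration 1 or 60 (seconds).
#' @return a [truth_spec()].
#' @export
default_truth <- function(duration) {
  if (!duration %in% c(1, 60)) {
    stop("unsupported duration: ", duration, " s (use 1 or 60)")
  }
  if (duration == 60) {
    truth_spec(
      target = response_curve("bounded", bounded_params(0.4, 1.5, -12),
                              endpoint = "target", duration = 60),
      neighboring = response_curve("simple", simple_params(1.0, -12),
                                   endpoint = "neighboring", duration = 60),
      death = response_curve("simple", simple_params(0.9, -15.3),
                             endpoint = "death", duration = 60)
    )
  } else {
    truth_spec(
      target = response_curve("simple", simple_params(0.35, -7),
                              endpoint = "target", duration = 1),
      neighboring = response_curve("simple", simple_params(0.35, -7.8),
                                   endpoint = "neighboring", duration = 1),
      death = response_curve("simple", simple_params(0.55, -13.5),
                             endpoint = "death", duration = 1)
    )
  }
}

# map the latent event triple (T, N, D) to the categorical outcome; death
# together with any expression collapses (lossily) into DEATH_AND_EXPRESSION
# because the published taxonomy has no finer death categories
.category_from_events <- function(t, n, d) {
  ifelse(d == 1,
         ifelse(t == 1 | n == 1, "DEATH_AND_EXPRESSION", "DEATH_TARGET"),
         ifelse(t == 1 & n == 1, "TARGET_AND_NEIGHBOR",
                ifelse(t == 1, "TARGET_ONLY",
                       ifelse(n == 1, "NEIGHBOR_ONLY", "NONE"))))
}

#' Simulate irradiation trials from known truth
#'
#' For each trial in the design: draw a cell size, compute its
#' normalized value against the truth's population size distribution,
#' evaluate the three true event curves at the trial's power, draw the
#' latent events (independently, or coupled through a Gaussian copula
#' when `truth$correlation > 0`), and record the categorical outcome.
#' The generator is pure: identical (design, truth, seed) give an
#' identical dataset.
#'
#' @param design a [replicate_design()] result (or any `design_spec`).
#' @param truth a [truth_spec()].
#' @param seed integer seed.
#' @param tissue tissue label written on every record.
#' @return a [trial_dataset()].
#' @export
simulate_trials <- function(design, truth, seed,
                            tissue = "root epidermis") {
  stopifnot(inherits(design, "design_spec"), inherits(truth, "truth_spec"))
  set.seed(seed)
  x <- design$powers
  n <- length(x)
  sizes <- sample_cell_sizes(n, mean_um2 = truth$size_mean,
                             cv = truth$size_cv)
  cc <- (sizes - truth$size_mean) / (truth$size_cv * truth$size_mean)
  p_t <- predict(truth$target, x, c = cc)
  p_n <- predict(truth$neighboring, x, c = cc)
  p_d <- predict(truth$death, x, c = cc)
  if (truth$correlation > 0) {
    rho <- sqrt(truth$correlation)
    shared <- rnorm(n)
    latent <- function(p) {
      zi <- rho * shared + sqrt(1 - rho^2) * rnorm(n)
      as.integer(pnorm(zi) < p)
    }
    t_ev <- latent(p_t)
    n_ev <- latent(p_n)
    d_ev <- latent(p_d)
  } else {
    t_ev <- rbinom(n, 1L, p_t)
    n_ev <- rbinom(n, 1L, p_n)
    d_ev <- rbinom(n, 1L, p_d)
  }
  rec <- data.frame(
    trial_id = sprintf("t%04d", seq_len(n)),
    power_mw = x,
    duration_s = design$duration,
    cell_size_um2 = sizes,
    tissue = tissue,
    outcome = .category_from_events(t_ev, n_ev, d_ev),
    stringsAsFactors = FALSE
  )
  trial_dataset(rec)
}

#' The in-paper leaf-mesophyll worked example
#'
#' The 20 leaf-mesophyll irradiation trials performed at the
#' root-optimized condition (8.5 mW, 60 s), of which exactly 4 gave
#' single-cell VENUS induction and 16 gave no induction.  Deterministic;
#' the published report gives per-category counts, not per-trial rows,
#' so rows are ordered successes-first.
#'
#' @return a [trial_dataset()] of 20 records.
#' @export
leaf_fixture <- function() {
  rec <- data.frame(
    trial_id = sprintf("leaf%02d", 1:20),
    power_mw = 8.5,
    duration_s = 60,
    cell_size_um2 = NA_real_,
    tissue = "leaf mesophyll",
    outcome = c(rep("TARGET_ONLY", 4L), rep("NONE", 16L)),
    stringsAsFactors = FALSE
  )
  trial_dataset(rec)
}

#' Serialize a truth specification to JSON
#'
#' Sidecar document written next to simulated trial CSVs so recovery
#' analyses know the generating curves, size distribution and seed.
#'
#' @param truth a [truth_spec()].
#' @param seed the seed used for the paired simulation.
#' @param path destination file; when `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
truth_to_json <- function(truth, seed = NULL, path = NULL) {
  doc <- list(
    curves = lapply(truth[c("target", "neighboring", "death")],
                    function(cv) jsonlite::fromJSON(curve_to_json(cv))),
    size_distribution = list(mean_um2 = truth$size_mean, cv = truth$size_cv),
    correlation = truth$correlation,
    seed = seed
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(path)
}
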