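#' Pipeline front-end
#'
#' `run_simulate()`, `run_fit()`, `run_optimize()` and `run_lrt()` tie
#' the modules together behind file-based interfaces: trial CSVs in,
#' JSON reports out.  Every JSON artifact embeds the package version,
#' the resolved configuration (with its MD5 hash) and the seed, so any
#' reported number can be re-derived from the artifact alone.  A thin
#' command-line wrapper over these functions ships in
#' `system.file("cli", "irdose.R", package = "irdose")`.
#'
#' @name pipeline
NULL

.run_meta <- function(config, seed = NULL) {
  resolved <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               null = "null")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(resolved), tmp)
  list(package = "irdose",
       version = as.character(packageVersion("irdose")),
       seed = seed,
       config = config,
       config_hash = unname(tools::md5sum(tmp)))
}

.write_report <- function(doc, path) {
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                          null = "null", pretty = TRUE)
  writeLines(as.character(txt), path)
  invisible(path)
}

#' Simulate a trial dataset to disk
#'
#' @param out_csv destination trials CSV.
#' @param duration 1 or 60 (seconds); selects the published design and
#'   the default truth curves.
#' @param seed integer seed.
#' @param truth a [truth_spec()]; defaults to [default_truth()] for the
#'   duration.
#' @param inflate design inflation factor, see [replicate_design()].
#' @param truth_json optional path for the truth sidecar JSON.
#' @return the simulated [trial_dataset()], invisibly.
#' @export
run_simulate <- function(out_csv, duration = 60, seed = 1L,
                         truth = default_truth(duration), inflate = 1L,
                         truth_json = NULL) {
  design <- replicate_design(duration, inflate = inflate)
  ds <- simulate_trials(design, truth, seed = seed)
  write_trials(ds, out_csv)
  if (!is.null(truth_json)) truth_to_json(truth, seed = seed,
                                          path = truth_json)
  invisible(ds)
}

#' Fit a response curve from a trials CSV
#'
#' Dispatches to [fit_logistic()] for the `simple` and `size` families
#' and to [fit_bounded_mcmc()] for the bounded families (which require a
#' [sampler_config()]).  Writes a JSON fit report and, for bounded
#' families, a posterior-draw CSV next to it.
#'
#' @param trials_csv trials CSV path (see [read_trials()]).
#' @param endpoint endpoint to model.
#' @param family one of `"simple"`, `"size"`, `"bounded"`,
#'   `"bounded_size"`.
#' @param out_json destination report path.
#' @param config a [sampler_config()] (bounded families only).
#' @param priors a [prior_spec()] (bounded families only).
#' @param posterior_csv path for posterior draws; default replaces the
#'   report's extension with `_posterior.csv`.
#' @return the fit object, invisibly.
#' @export
run_fit <- function(trials_csv, endpoint, family, out_json,
                    config = NULL, priors = prior_spec(),
                    posterior_csv = NULL) {
  family <- match.arg(family, CURVE_FAMILIES)
  ds <- read_trials(trials_csv)
  if (.uses_size(family)) ds <- normalize_cell_size(ds)
  bounded <- family %in% c("bounded", "bounded_size")
  if (bounded && is.null(config)) {
    stop("bounded families need a sampler_config (chains, iterations, seed)")
  }
  meta_cfg <- list(trials = trials_csv, endpoint = endpoint,
                   family = family,
                   sampler = if (bounded) unclass(config),
                   priors = if (bounded) unclass(priors))
  if (bounded) {
    fit <- fit_bounded_mcmc(ds, endpoint, family, priors = priors,
                            config = config)
    if (is.null(posterior_csv)) {
      posterior_csv <- sub("\\.json$", "_posterior.csv", out_json)
    }
    write.csv(fit$samples, posterior_csv, row.names = FALSE)
    doc <- list(
      meta = .run_meta(meta_cfg, seed = config$seed),
      curve = jsonlite::fromJSON(curve_to_json(fit$curve_at_medians)),
      medians = as.list(fit$medians), rhat = as.list(fit$rhat),
      ess = as.list(fit$ess), n_used = fit$n_used,
      posterior_csv = posterior_csv
    )
  } else {
    fit <- fit_logistic(ds, endpoint, family)
    doc <- list(
      meta = .run_meta(meta_cfg),
      curve = jsonlite::fromJSON(curve_to_json(fit$curve)),
      loglik = fit$loglik, n_used = fit$n_used,
      converged = fit$converged, separation_flag = fit$separation_flag,
      stderr = as.list(fit$stderr)
    )
  }
  .write_report(doc, out_json)
  invisible(fit)
}

#' Optimize laser power from fitted-curve files
#'
#' Loads three or four curve JSONs (the local curve is composed from
#' target and neighboring when absent), maximizes the requested
#' condition score, computes the raising point of every loaded curve,
#' and writes a JSON report plus a score-versus-power CSV for plotting.
#'
#' @param curve_files named list/vector of curve JSON paths with names
#'   among `target`, `neighboring`, `death`, `local`.
#' @param condition 1 or 2.
#' @param power_range numeric `c(lo, hi)` in mW.
#' @param out_json destination report path.
#' @param score_csv optional path for the score-curve CSV.
#' @param threshold raising-point threshold (default 0.10).
#' @param c normalized cell size at which to optimize.
#' @return the [optimize_condition()] result, invisibly.
#' @export
run_optimize <- function(curve_files, condition, power_range, out_json,
                         score_csv = NULL, threshold = 0.10, c = 0) {
  curve_files <- as.list(curve_files)
  needed <- c("target", "neighboring", "death")
  if (!all(needed %in% names(curve_files))) {
    stop("curve_files must name at least: ",
         paste(needed, collapse = ", "))
  }
  for (f in unlist(curve_files)) {
    if (!file.exists(f)) stop("curve file does not exist: ", f)
  }
  curves <- lapply(curve_files, curve_from_json)
  cs <- curve_set(curves$target, curves$neighboring, curves$death,
                  local = curves$local)
  rec <- optimize_condition(cs, condition, power_range, c = c)
  rps <- lapply(curves, function(cv) {
    tryCatch(unclass(raising_point(cv, threshold, power_range, c = c)),
             error = function(e) list(endpoint = cv$endpoint,
                                      error = conditionMessage(e)))
  })
  grid <- seq(power_range[1L], power_range[2L], by = 0.1)
  score <- condition_score(cs, condition, grid, c = c)
  if (!is.null(score_csv)) {
    write.csv(data.frame(power_mw = grid, score = score), score_csv,
              row.names = FALSE)
  }
  meta_cfg <- list(curves = curve_files, condition = condition,
                   power_range = power_range, threshold = threshold,
                   c = c)
  doc <- list(
    meta = .run_meta(meta_cfg),
    condition = condition,
    power_range = power_range,
    optimal_power = rec$optimal_power,
    optimal_power_rounded = round(rec$optimal_power, 1),
    achieved_score = rec$achieved_score,
    grid_step = rec$grid_step,
    degenerate = rec$degenerate,
    raising_points = rps,
    score_csv = score_csv
  )
  .write_report(doc, out_json)
  invisible(rec)
}

#' Run a cell-size likelihood-ratio test from a trials CSV
#'
#' For the ML families this fits the size-covariate and power-only
#' models and runs [lrt_nested()]; for the bounded families it fits both
#' by MCMC and runs the deviance-based [manual_lrt()].
#'
#' @param trials_csv trials CSV path.
#' @param endpoint endpoint to test.
#' @param family `"simple"` (tests size vs simple) or `"bounded"` (tests
#'   bounded_size vs bounded).
#' @param out_json destination report path.
#' @param config,priors sampler settings for the bounded route.
#' @return the `lrt_result`, invisibly.
#' @export
run_lrt <- function(trials_csv, endpoint, family = c("simple", "bounded"),
                    out_json, config = NULL, priors = prior_spec()) {
  family <- match.arg(family)
  ds <- normalize_cell_size(read_trials(trials_csv))
  if (family == "simple") {
    full <- fit_logistic(ds, endpoint, "size")
    reduced <- fit_logistic(ds, endpoint, "simple")
    res <- lrt_nested(full, reduced)
    fams <- c("size", "simple")
    seed <- NULL
  } else {
    if (is.null(config)) stop("bounded LRT needs a sampler_config")
    full <- fit_bounded_mcmc(ds, endpoint, "bounded_size",
                             priors = priors, config = config)
    reduced <- fit_bounded_mcmc(ds, endpoint, "bounded",
                                priors = priors, config = config)
    res <- manual_lrt(full, reduced, ds)
    fams <- c("bounded_size", "bounded")
    seed <- config$seed
  }
  meta_cfg <- list(trials = trials_csv, endpoint = endpoint,
                   family_full = fams[1L], family_reduced = fams[2L],
                   sampler = if (!is.null(config)) unclass(config))
  doc <- list(
    meta = .run_meta(meta_cfg, seed = seed),
    statistic = res$statistic, df = res$df, p_value = res$p_value,
    loglik_full = res$loglik_full, loglik_reduced = res$loglik_reduced
  )
  .write_report(doc, out_json)
  invisible(res)
}
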