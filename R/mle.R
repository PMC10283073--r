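#' Maximum-likelihood fit of a logistic dose-response model
#'
#' Fits the simple (power-only) or size-covariate logistic model to one
#' binary endpoint by iteratively reweighted least squares
#' ([stats::glm()] with a binomial logit link).  The size-covariate model
#' adds the normalized cell size as a main effect and a power-by-size
#' interaction.
#'
#' Quasi-complete separation is flagged (not repaired) when any fitted
#' linear predictor exceeds 30 in absolute value or the IRLS iterations
#' fail to converge; a flagged fit is returned with `converged = FALSE`.
#'
#' @param dataset a [trial_dataset()]; for `family = "size"` it must have
#'   been passed through [normalize_cell_size()] (records without a
#'   measured size are excluded from size-covariate fits).
#' @param endpoint endpoint to model, see [endpoint_outcomes()].
#' @param family `"simple"` or `"size"`.
#' @return object of class `mle_fit`: list with `curve`
#'   ([response_curve()]), `loglik`, `converged`, `n_used`,
#'   `separation_flag`, `stderr` (per parameter) and `vcov`.
#' @export
fit_logistic <- function(dataset, endpoint, family = c("simple", "size")) {
  family <- match.arg(family)
  endpoint <- match.arg(endpoint, ENDPOINTS)
  mf <- .model_frame(dataset, endpoint, family)
  if (nrow(mf) == 0L) stop("no usable records for endpoint '", endpoint, "'")
  if (all(mf$y == 1) || all(mf$y == 0)) {
    stop("degenerate outcome: endpoint '", endpoint,
         "' is constant (all ", mf$y[1L], ")")
  }
  fml <- if (family == "simple") y ~ x else y ~ x * c
  saturated_warn <- FALSE
  fit <- withCallingHandlers(
    glm(fml, data = mf, family = binomial(link = "logit")),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        saturated_warn <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  eta <- predict(fit, type = "link")
  # IRLS stalls on separated data with |eta| around 25 and no warning, so
  # the diagnostic cutoff sits at 20 (fitted p within 2e-9 of 0 or 1)
  separation <- saturated_warn || any(abs(eta) > 20) || !fit$converged
  cf <- coef(fit)
  params <- if (family == "simple") {
    simple_params(a = unname(cf["x"]), b = unname(cf["(Intercept)"]))
  } else {
    size_params(a1 = unname(cf["x"]), a2 = unname(cf["c"]),
                a3 = unname(cf["x:c"]), b = unname(cf["(Intercept)"]))
  }
  dur <- unique(dataset$records$duration_s)
  curve <- response_curve(
    family, params, endpoint = endpoint,
    duration = if (length(dur) == 1L) dur else NA_real_,
    size_stats = dataset$size_stats,
    c_range = if (family == "size") range(mf$c) else NULL
  )
  se <- sqrt(diag(vcov(fit)))
  structure(list(curve = curve, loglik = as.numeric(logLik(fit)),
                 converged = fit$converged && !separation,
                 n_used = nrow(mf), separation_flag = separation,
                 stderr = se, vcov = vcov(fit)),
            class = "mle_fit")
}

#' @export
print.mle_fit <- function(x, ...) {
  cat("ML fit (", x$curve$family, ", endpoint ", x$curve$endpoint,
      "): logLik = ", signif(x$loglik, 6), ", n = ", x$n_used,
      if (x$separation_flag) " [separation]",
      if (!x$converged) " [not converged]", "\n", sep = "")
  print(x$curve)
  invisible(x)
}

# parameter count of a curve family
.n_params <- function(family) {
  switch(family, simple = 2L, bounded = 3L, size = 4L, bounded_size = 6L)
}

#' Likelihood-ratio test between nested model fits
#'
#' Compares a full model against a reduced model nested within it (the
#' size-covariate model against the power-only model, or the bounded
#' size-covariate model against the bounded model) fitted to the same
#' data and endpoint.  The statistic `2 (logLik_full - logLik_reduced)`
#' (clipped at zero) is referred to a chi-square distribution with
#' degrees of freedom equal to the difference in parameter count: 2 for
#' size vs simple (`a2`, `a3` added), 3 for bounded_size vs bounded
#' (`a2`, `a3`, `a4` added).
#'
#' @param full,reduced `mle_fit` objects.
#' @return object of class `lrt_result`: list with `statistic`, `df`,
#'   `p_value`, `loglik_full`, `loglik_reduced`.
#' @export
lrt_nested <- function(full, reduced) {
  stopifnot(inherits(full, "mle_fit"), inherits(reduced, "mle_fit"))
  df <- .nesting_df(full$curve$family, reduced$curve$family)
  if (!identical(full$curve$endpoint, reduced$curve$endpoint)) {
    stop("fits model different endpoints")
  }
  .lrt_from_loglik(full$loglik, reduced$loglik, df)
}

.nesting_df <- function(full_family, reduced_family) {
  ok <- (full_family == "size" && reduced_family == "simple") ||
        (full_family == "bounded_size" && reduced_family == "bounded")
  if (!ok) {
    stop("family '", reduced_family, "' is not nested in '",
         full_family, "'")
  }
  .n_params(full_family) - .n_params(reduced_family)
}

.lrt_from_loglik <- function(ll_full, ll_reduced, df) {
  raw <- 2 * (ll_full - ll_reduced)
  if (raw < -1e-6) {
    warning("full model has lower likelihood than reduced (", raw,
            "); check convergence")
  }
  stat <- max(0, raw)
  structure(list(statistic = stat, df = df,
                 p_value = pchisq(stat, df = df, lower.tail = FALSE),
                 loglik_full = ll_full, loglik_reduced = ll_reduced),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test: chisq = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Power-only fits on cell-size strata
#'
#' Refits the simple logistic model on subsets of the data filtered by
#' cell size, the direct way to see whether, say, smaller cells respond
#' at lower laser powers.  A stratum that retains fewer than `min_n`
#' records, or only one outcome level, is skipped with a reason rather
#' than failing the whole call.
#'
#' @param dataset a [trial_dataset()].
#' @param endpoint endpoint to model.
#' @param strata named list of numeric ranges `c(lo, hi)` in µm²; a
#'   record enters a stratum when `lo <= size < hi` (`hi = Inf` allowed).
#' @param min_n minimum records per stratum (default 10).
#' @return named list, one element per stratum: either an `mle_fit` or a
#'   list `(skipped = TRUE, reason = ...)`.
#' @export
fit_by_size_strata <- function(dataset, endpoint, strata, min_n = 10L) {
  stopifnot(inherits(dataset, "trial_dataset"), is.list(strata))
  if (is.null(names(strata)) || any(names(strata) == "")) {
    names(strata) <- paste0("stratum", seq_along(strata))
  }
  sizes <- dataset$records$cell_size_um2
  out <- lapply(strata, function(rng) {
    stopifnot(is.numeric(rng), length(rng) == 2L, rng[1L] < rng[2L])
    keep <- !is.na(sizes) & sizes >= rng[1L] & sizes < rng[2L]
    if (sum(keep) < min_n) {
      return(list(skipped = TRUE,
                  reason = sprintf("only %d records (< %d)",
                                   sum(keep), min_n)))
    }
    sub <- trial_dataset(dataset$records[keep, , drop = FALSE],
                         size_stats = dataset$size_stats)
    y <- endpoint_outcomes(sub, endpoint)
    if (all(y == 0) || all(y == 1)) {
      return(list(skipped = TRUE, reason = "single outcome level"))
    }
    fit_logistic(sub, endpoint, family = "simple")
  })
  out
}
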