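#' Prior specification for the bounded logistic models
#'
#' Weakly informative defaults: the upper limit `lim` is uniform on
#' (0, 1); slope and intercept coefficients are normal with mean 0 on the
#' internally standardized power scale; the plateau modifier `a4` is
#' normal with mean 0, truncated jointly with `lim` so that the effective
#' limit `lim (1 + a4 c)` stays in (0, 1] over the observed range of
#' normalized sizes.
#'
#' @param slope_sd prior sd of slope coefficients (standardized power
#'   scale), default 10.
#' @param intercept_sd prior sd of the intercept, default 10.
#' @param a4_sd prior sd of the plateau modifier `a4`, default 2.
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(slope_sd = 10, intercept_sd = 10, a4_sd = 2) {
  stopifnot(slope_sd > 0, intercept_sd > 0, a4_sd > 0)
  structure(list(slope_sd = slope_sd, intercept_sd = intercept_sd,
                 a4_sd = a4_sd), class = "prior_spec")
}

#' Sampler configuration for MCMC fits
#'
#' @param chains number of chains (>= 2).
#' @param iterations post-warmup draws per chain.  At least 1000 per
#'   chain is recommended for reported fits; fewer draws trigger a
#'   warning.
#' @param warmup adaptation draws discarded per chain.
#' @param seed integer seed; identical (data, priors, config) give
#'   identical samples.
#' @param rhat_threshold largest acceptable split-R-hat (default 1.01).
#' @param ess_threshold smallest acceptable effective sample size per
#'   parameter (default 400).
#' @return object of class `sampler_config`.
#' @export
sampler_config <- function(chains = 4L, iterations = 5000L, warmup = 2500L,
                           seed = 1L, rhat_threshold = 1.01,
                           ess_threshold = 400) {
  stopifnot(chains >= 2L, iterations >= 100L, warmup >= 100L,
            rhat_threshold > 1)
  if (iterations < 1000L) {
    warning("fewer than 1000 post-warmup draws per chain; ",
            "use >= 1000 for reported fits")
  }
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 rhat_threshold = rhat_threshold,
                 ess_threshold = ess_threshold),
            class = "sampler_config")
}

# ---- internal machinery ----------------------------------------------------

# standardize power for sampling; returns list(z, mean, sd)
.std_power <- function(x) {
  m <- mean(x)
  s <- sd(x)
  if (!is.finite(s) || s == 0) s <- 1
  list(z = (x - m) / s, mean = m, sd = s)
}

# names of sampling-scale parameters per family
.theta_names <- function(family) {
  if (family == "bounded") c("q", "alpha", "beta")
  else c("q", "alpha1", "alpha2", "alpha3", "beta", "a4")
}

# back-transform one sampling-scale draw to natural parameters
.theta_to_natural <- function(theta, family, mx, sx) {
  if (family == "bounded") {
    c(lim = plogis(theta[[1L]]), a = theta[[2L]] / sx,
      b = theta[[3L]] - theta[[2L]] * mx / sx)
  } else {
    c(lim = plogis(theta[[1L]]),
      a1 = theta[[2L]] / sx,
      a2 = theta[[3L]] - theta[[4L]] * mx / sx,
      a3 = theta[[4L]] / sx,
      a4 = theta[[6L]],
      b = theta[[5L]] - theta[[2L]] * mx / sx)
  }
}

# Bernoulli/binomial log-likelihood on the standardized scale.
# For the size-free bounded model trials are aggregated to per-power
# binomial counts, which makes each evaluation O(#distinct powers).
.make_loglik_std <- function(family, mf_std) {
  eps <- 1e-12
  if (family == "bounded") {
    key <- match(mf_std$z, sort(unique(mf_std$z)))
    z <- sort(unique(mf_std$z))
    n <- as.numeric(tabulate(key, nbins = length(z)))
    k <- as.numeric(rowsum(mf_std$y, key))
    function(theta) {
      lim <- plogis(theta[1L])
      p <- lim * .sigmoid(theta[2L] * z + theta[3L])
      sum(k * log(pmax(p, eps)) + (n - k) * log(pmax(1 - p, eps)))
    }
  } else {
    z <- mf_std$z
    cc <- mf_std$c
    y <- mf_std$y
    crange <- range(cc)
    function(theta) {
      lim <- plogis(theta[1L])
      eff <- lim * (1 + theta[6L] * crange)
      if (any(eff <= 0 | eff > 1)) return(-Inf)
      p <- lim * (1 + theta[6L] * cc) *
        .sigmoid(theta[2L] * z + theta[3L] * cc + theta[4L] * z * cc +
                   theta[5L])
      sum(ifelse(y == 1, log(pmax(p, eps)), log(pmax(1 - p, eps))))
    }
  }
}

.make_logprior <- function(family, priors) {
  if (family == "bounded") {
    function(theta) {
      lim <- plogis(theta[1L])
      # uniform(0,1) on lim plus the logit-transform Jacobian
      log(lim * (1 - lim)) +
        dnorm(theta[2L], 0, priors$slope_sd, log = TRUE) +
        dnorm(theta[3L], 0, priors$intercept_sd, log = TRUE)
    }
  } else {
    function(theta) {
      lim <- plogis(theta[1L])
      log(lim * (1 - lim)) +
        sum(dnorm(theta[2L:4L], 0, priors$slope_sd, log = TRUE)) +
        dnorm(theta[5L], 0, priors$intercept_sd, log = TRUE) +
        dnorm(theta[6L], 0, priors$a4_sd, log = TRUE)
    }
  }
}

# one adaptive random-walk Metropolis chain: global scale tuned toward a
# 0.234 acceptance rate (Robbins-Monro) and proposal covariance re-estimated
# from the warmup history; both frozen after warmup so the sampled chain is
# a valid Markov chain
.run_chain <- function(logpost, init, warmup, iterations, S0 = NULL) {
  d <- length(init)
  theta <- init
  lp <- logpost(theta)
  if (!is.finite(lp)) stop("chain initialized outside the prior support")
  L <- if (is.null(S0)) diag(d) * 0.1 else
    tryCatch(chol((2.38^2 / d) * S0), error = function(e) diag(d) * 0.1)
  ls <- 0
  warm <- matrix(NA_real_, warmup, d)
  draws <- matrix(NA_real_, iterations, d)
  accepts <- 0L
  for (i in seq_len(warmup + iterations)) {
    prop <- theta + exp(ls) * drop(crossprod(L, rnorm(d)))
    lp_prop <- logpost(prop)
    log_acc <- lp_prop - lp
    acc_prob <- if (is.finite(log_acc)) min(1, exp(log_acc)) else 0
    if (log(runif(1L)) < log_acc) {
      theta <- prop
      lp <- lp_prop
      if (i > warmup) accepts <- accepts + 1L
    }
    if (i <= warmup) {
      ls <- ls + (acc_prob - 0.234) / i^0.6
      warm[i, ] <- theta
      if (i >= 200L && i %% 100L == 0L) {
        # estimate the proposal covariance from the later half of the
        # warmup history so the initial transient does not inflate it
        use <- warm[seq(floor(i / 2), i), , drop = FALSE]
        S <- cov(use) + diag(1e-8, d)
        L <- chol((2.38^2 / d) * S)
        ls <- 0
      }
    } else {
      draws[i - warmup, ] <- theta
    }
  }
  list(draws = draws, accept_rate = accepts / iterations)
}

#' Fit a bounded logistic model by MCMC
#'
#' Samples the posterior of the bounded (`lim`, `a`, `b`) or bounded
#' size-covariate (`lim`, `a1`-`a4`, `b`) logistic model under a
#' Bernoulli likelihood and the priors in [prior_spec()], using an
#' adaptive random-walk Metropolis sampler.  Laser power is standardized
#' internally for sampling and all reported draws are back-transformed to
#' the natural mW scale.  Chains are initialized by jittering the
#' constrained maximum-likelihood solution.
#'
#' Convergence is checked with split-R-hat and effective sample size
#' (via \pkg{coda}); a fit that fails either check raises an error
#' carrying the diagnostics.
#'
#' @param dataset a [trial_dataset()] (pass through
#'   [normalize_cell_size()] first for `family = "bounded_size"`).
#' @param endpoint endpoint to model.
#' @param family `"bounded"` or `"bounded_size"`.
#' @param priors a [prior_spec()].
#' @param config a [sampler_config()].
#' @return object of class `posterior_fit`: list with `samples` (data
#'   frame, one row per draw, `chain` column), `medians`, `rhat`, `ess`,
#'   `accept_rate`, `curve_at_medians`, `family`, `endpoint`, `priors`,
#'   `config`.
#' @export
fit_bounded_mcmc <- function(dataset, endpoint,
                             family = c("bounded", "bounded_size"),
                             priors = prior_spec(),
                             config = sampler_config()) {
  family <- match.arg(family)
  endpoint <- match.arg(endpoint, ENDPOINTS)
  stopifnot(inherits(priors, "prior_spec"), inherits(config, "sampler_config"))
  mf <- .model_frame(dataset, endpoint, family)
  if (all(mf$y == 1) || all(mf$y == 0)) {
    stop("degenerate outcome: endpoint '", endpoint, "' is constant")
  }
  st <- .std_power(mf$x)
  mf_std <- data.frame(z = st$z, c = mf$c, y = mf$y)
  loglik <- .make_loglik_std(family, mf_std)
  logprior <- .make_logprior(family, priors)
  logpost <- function(theta) {
    ll <- loglik(theta)
    if (!is.finite(ll)) return(-Inf)
    ll + logprior(theta)
  }
  d <- length(.theta_names(family))

  set.seed(config$seed)
  center <- .bounded_mle_theta(family, mf_std)
  # seed the proposal covariance with the inverse curvature at the mode;
  # warmup adaptation then only has to polish it
  S0 <- tryCatch({
    H <- stats::optimHess(as.numeric(center),
                          function(th) -logpost(th))
    V <- solve(H)
    if (all(is.finite(V)) && all(diag(V) > 0)) V else NULL
  }, error = function(e) NULL)
  chains <- vector("list", config$chains)
  L0 <- if (!is.null(S0)) tryCatch(chol(S0), error = function(e) NULL)
  for (ch in seq_len(config$chains)) {
    init <- NULL
    # overdispersed starts: a few posterior sds out, shrinking until the
    # candidate lands inside the prior support
    for (scale in c(2, 1, 0.5, 0.25, 0)) {
      jit <- if (!is.null(L0)) drop(crossprod(L0, rnorm(d))) * scale
             else rnorm(d, 0, 0.05 * scale)
      cand <- as.numeric(center) + jit
      if (is.finite(logpost(cand))) {
        init <- cand
        break
      }
    }
    if (is.null(init)) {
      stop("could not initialize chain ", ch, " inside the prior support")
    }
    chains[[ch]] <- .run_chain(logpost, init, config$warmup,
                               config$iterations, S0 = S0)
  }

  nat_names <- if (family == "bounded") c("lim", "a", "b") else
    c("lim", "a1", "a2", "a3", "a4", "b")
  nat_chains <- lapply(chains, function(chn) {
    nat <- t(apply(chn$draws, 1L, .theta_to_natural,
                   family = family, mx = st$mean, sx = st$sd))
    colnames(nat) <- nat_names
    nat
  })

  # split-R-hat: feed each half-chain to gelman.diag as its own chain
  halves <- unlist(lapply(nat_chains, function(m) {
    h <- nrow(m) %/% 2L
    list(coda::mcmc(m[seq_len(h), , drop = FALSE]),
         coda::mcmc(m[(h + 1L):(2L * h), , drop = FALSE]))
  }), recursive = FALSE)
  gd <- coda::gelman.diag(coda::mcmc.list(halves), autoburnin = FALSE,
                          multivariate = FALSE)
  rhat <- setNames(gd$psrf[, 1L], nat_names)
  ess <- coda::effectiveSize(
    coda::mcmc.list(lapply(nat_chains, coda::mcmc)))
  ess <- setNames(as.numeric(ess), nat_names)

  if (any(rhat > config$rhat_threshold) ||
      any(ess < config$ess_threshold)) {
    stop(structure(class = c("irdose_nonconvergence", "error", "condition"),
      list(message = paste0(
             "MCMC did not converge: max split-Rhat = ",
             signif(max(rhat), 5), ", min ESS = ", signif(min(ess), 5),
             " (thresholds ", config$rhat_threshold, " / ",
             config$ess_threshold, ")"),
           call = sys.call(-1L), rhat = rhat, ess = ess)))
  }

  all_draws <- do.call(rbind, nat_chains)
  samples <- as.data.frame(all_draws)
  samples$chain <- rep(seq_len(config$chains),
                       each = config$iterations)
  medians <- apply(all_draws, 2L, median)
  params <- if (family == "bounded") {
    bounded_params(medians[["lim"]], medians[["a"]], medians[["b"]])
  } else {
    bounded_size_params(medians[["lim"]], medians[["a1"]], medians[["a2"]],
                        medians[["a3"]], medians[["a4"]], medians[["b"]])
  }
  dur <- unique(dataset$records$duration_s)
  curve <- response_curve(
    family, params, endpoint = endpoint,
    duration = if (length(dur) == 1L) dur else NA_real_,
    size_stats = dataset$size_stats,
    c_range = if (family == "bounded_size") range(mf$c) else NULL
  )
  accept <- vapply(chains, `[[`, numeric(1L), "accept_rate")
  structure(list(samples = samples, medians = medians, rhat = rhat,
                 ess = ess, accept_rate = accept,
                 curve_at_medians = curve, family = family,
                 endpoint = endpoint, n_used = nrow(mf),
                 priors = priors, config = config),
            class = "posterior_fit")
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat("Posterior fit (", x$family, ", endpoint ", x$endpoint, "): ",
      nrow(x$samples), " draws over ", x$config$chains, " chains\n",
      sep = "")
  summ <- data.frame(median = signif(x$medians, 5),
                     rhat = round(x$rhat, 4), ess = round(x$ess))
  print(summ)
  invisible(x)
}

#' Posterior-median parameter set
#'
#' The per-parameter marginal medians of the posterior draws, as a
#' parameter list ready for the matching `predict_*` function — the
#' point estimate adopted for bounded-model response curves.
#'
#' @param fit a `posterior_fit`.
#' @return parameter list, see [model_params].
#' @export
posterior_median_params <- function(fit) {
  stopifnot(inherits(fit, "posterior_fit"))
  fit$curve_at_medians$params
}

# extract the point-estimate curve from any fit-like object
.as_curve <- function(x) {
  if (inherits(x, "response_curve")) return(x)
  if (inherits(x, "mle_fit")) return(x$curve)
  if (inherits(x, "posterior_fit")) return(x$curve_at_medians)
  stop("cannot extract a response curve from class ",
       paste(class(x), collapse = "/"))
}

#' Deviance-based likelihood-ratio test for MCMC-fitted models
#'
#' The manual counterpart of [lrt_nested()] for bounded models: the
#' deviance `-2 logLik` of each model, evaluated at its posterior-median
#' parameters, is computed directly from the Bernoulli likelihood, and
#' the deviance difference (reduced minus full, clipped at zero) is
#' referred to a chi-square distribution.  The degrees of freedom are
#' the parameter-count difference: 3 for bounded_size vs bounded
#' (`a2`, `a3`, `a4` added; `lim` and `b` exist in both).
#'
#' @param full_fit,reduced_fit `posterior_fit`, `mle_fit` or
#'   [response_curve()] objects; the reduced family must be nested in the
#'   full one.
#' @param data the shared dataset: a [trial_dataset()] or a data frame
#'   with `x`, `y` (and `c`).
#' @return an `lrt_result`, see [lrt_nested()].
#' @export
manual_lrt <- function(full_fit, reduced_fit, data) {
  full <- .as_curve(full_fit)
  reduced <- .as_curve(reduced_fit)
  df <- .nesting_df(full$family, reduced$family)
  if (!identical(full$endpoint, reduced$endpoint)) {
    stop("fits model different endpoints")
  }
  dev_full <- as.numeric(deviance_at(full, data))
  dev_reduced <- as.numeric(deviance_at(reduced, data))
  .lrt_from_loglik(-dev_full / 2, -dev_reduced / 2, df)
}

# constrained MLE on the standardized sampling scale; returns theta-hat
.bounded_mle_theta <- function(family, mf_std, fix_lim = NULL) {
  loglik <- .make_loglik_std(family, mf_std)
  d <- length(.theta_names(family))
  # slope/intercept starts from an unbounded logistic fit
  g <- suppressWarnings(coef(glm(y ~ z, data = mf_std, family = binomial())))
  phat <- min(0.98, max(0.05, max(tapply(mf_std$y, mf_std$z, mean))))
  base <- function(q, a, b) {
    th <- c(q, a, b)
    if (family == "bounded_size") th <- c(q, a, 0, 0, b, 0)
    th
  }
  starts <- list(
    base(qlogis(min(0.97, phat * 1.2)), unname(g[2L]), unname(g[1L])),
    base(qlogis(0.5), unname(g[2L]), unname(g[1L])),
    base(qlogis(0.9), 1, 0)
  )
  if (!is.null(fix_lim)) {
    qfix <- qlogis(min(fix_lim, 1 - 1e-12))
    obj <- function(th_free) -loglik(c(qfix, th_free))
    starts <- lapply(starts, function(s) s[-1L])
  } else {
    obj <- function(th) -loglik(th)
  }
  best <- NULL
  for (s in starts) {
    # Nelder-Mead first (tolerates the -Inf constraint barrier), then a
    # BFGS polish from inside the feasible region
    fit <- tryCatch(
      optim(s, obj, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      fit <- tryCatch(
        optim(fit$par, obj, method = "BFGS",
              control = list(maxit = 500, reltol = 1e-12)),
        error = function(e) fit)
    }
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("bounded MLE failed from all starts")
  theta <- if (is.null(fix_lim)) best$par else
    c(qlogis(min(fix_lim, 1 - 1e-12)), best$par)
  attr(theta, "value") <- -best$value
  attr(theta, "convergence") <- best$convergence
  theta
}

#' Constrained maximum-likelihood fit of a bounded logistic model
#'
#' Direct numerical maximization of the bounded-model likelihood with
#' `lim` constrained to (0, 1) through a logit transform (and the
#' effective limit constrained over the observed size range for
#' `bounded_size`), from multiple starts.  Serves as a frequentist
#' cross-check for [fit_bounded_mcmc()]: with weak priors the posterior
#' medians should approach these estimates.
#'
#' A solution with `lim` above 0.995 is flagged as a boundary solution
#' (the plateau is not identified by the data, e.g. when all tested
#' powers sit in the rising phase of the curve).
#'
#' @inheritParams fit_bounded_mcmc
#' @param fix_lim optional fixed value for `lim`; `fix_lim = 1` reduces
#'   the bounded model to the simple logistic model.
#' @return an `mle_fit` (see [fit_logistic()]) with an extra
#'   `boundary_flag` element.
#' @export
fit_bounded_mle <- function(dataset, endpoint,
                            family = c("bounded", "bounded_size"),
                            fix_lim = NULL) {
  family <- match.arg(family)
  endpoint <- match.arg(endpoint, ENDPOINTS)
  mf <- .model_frame(dataset, endpoint, family)
  if (all(mf$y == 1) || all(mf$y == 0)) {
    stop("degenerate outcome: endpoint '", endpoint, "' is constant")
  }
  st <- .std_power(mf$x)
  mf_std <- data.frame(z = st$z, c = mf$c, y = mf$y)
  theta <- .bounded_mle_theta(family, mf_std, fix_lim = fix_lim)
  nat <- .theta_to_natural(as.numeric(theta), family, st$mean, st$sd)
  params <- if (family == "bounded") {
    bounded_params(nat[["lim"]], nat[["a"]], nat[["b"]])
  } else {
    bounded_size_params(nat[["lim"]], nat[["a1"]], nat[["a2"]],
                        nat[["a3"]], nat[["a4"]], nat[["b"]])
  }
  dur <- unique(dataset$records$duration_s)
  curve <- response_curve(
    family, params, endpoint = endpoint,
    duration = if (length(dur) == 1L) dur else NA_real_,
    size_stats = dataset$size_stats,
    c_range = if (family == "bounded_size") range(mf$c) else NULL
  )
  ll <- as.numeric(log_likelihood(curve, mf))
  structure(list(curve = curve, loglik = ll,
                 converged = attr(theta, "convergence") == 0L,
                 n_used = nrow(mf), separation_flag = FALSE,
                 boundary_flag = is.null(fix_lim) && nat[["lim"]] > 0.995,
                 stderr = NULL, vcov = NULL),
            class = "mle_fit")
}
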