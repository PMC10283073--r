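#' Logistic-family dose-response curves
#'
#' Four nested model families describe an endpoint probability as a
#' function of laser power `x` (mW) and, optionally, normalized cell size
#' `c`:
#'
#' * `simple`:        `p = 1 / (1 + exp(-(a x + b)))`
#' * `bounded`:       `p = lim / (1 + exp(-(a x + b)))`, `0 < lim <= 1`
#' * `size`:          `p = 1 / (1 + exp(-(a1 x + a2 c + a3 x c + b)))`
#' * `bounded_size`:  `p = lim (1 + a4 c) / (1 + exp(-(a1 x + a2 c + a3 x c + b)))`
#'
#' The bounded families model endpoints that plateau below 100%
#' (recombination that saturates around an upper limit `lim`); in
#' `bounded_size` the plateau itself varies linearly with normalized size
#' and the effective limit `lim (1 + a4 c)` must stay in (0, 1] over the
#' observed size range.  Setting `c = 0` (a cell of average size) reduces
#' `size` to `simple` and `bounded_size` to `bounded`; setting `lim = 1`
#' reduces `bounded` to `simple`.
#'
#' @param a,b,a1,a2,a3,a4,lim model coefficients; slopes are per mW
#'   (`a, a1`), per unit normalized size (`a2`), or per mW x unit size
#'   (`a3`); `a4` scales the upper limit per unit normalized size.
#' @return a named parameter list of class `irdose_params` with a
#'   `family` attribute.
#' @name model_params
NULL

.params <- function(family, values) {
  stopifnot(all(vapply(values, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v), logical(1L))))
  structure(as.list(values), family = family,
            class = c(paste0(family, "_params"), "irdose_params"))
}

#' @rdname model_params
#' @export
simple_params <- function(a, b) .params("simple", list(a = a, b = b))

#' @rdname model_params
#' @export
bounded_params <- function(lim, a, b) {
  if (lim <= 0 || lim > 1) stop("lim must lie in (0, 1]")
  .params("bounded", list(lim = lim, a = a, b = b))
}

#' @rdname model_params
#' @export
size_params <- function(a1, a2, a3, b) {
  .params("size", list(a1 = a1, a2 = a2, a3 = a3, b = b))
}

#' @rdname model_params
#' @export
bounded_size_params <- function(lim, a1, a2, a3, a4, b) {
  if (lim <= 0 || lim > 1) stop("lim must lie in (0, 1]")
  .params("bounded_size",
          list(lim = lim, a1 = a1, a2 = a2, a3 = a3, a4 = a4, b = b))
}

# logistic response with the linear predictor clamped to +-750 (the double
# exp() overflow edge): exact to double precision in-range, saturates to an
# exact 0 or 1 instead of producing NaN beyond it
.sigmoid <- function(eta) plogis(pmin(pmax(eta, -750), 750))

#' Evaluate the four model families
#'
#' Pure prediction functions, vectorized over `x` (and `c`).  All return
#' probabilities in `[0, 1]`; the bounded families return values below
#' their (effective) upper limit.
#'
#' @param params the matching parameter list, see [model_params].
#' @param x laser power in mW.
#' @param c normalized cell size (0 = a cell of average size).
#' @return numeric vector of probabilities.
#' @name predict_family
NULL

#' @rdname predict_family
#' @export
predict_simple <- function(params, x) .sigmoid(params$a * x + params$b)

#' @rdname predict_family
#' @export
predict_bounded <- function(params, x) {
  params$lim * .sigmoid(params$a * x + params$b)
}

#' @rdname predict_family
#' @export
predict_size <- function(params, x, c) {
  .sigmoid(params$a1 * x + params$a2 * c + params$a3 * x * c + params$b)
}

#' @rdname predict_family
#' @export
predict_bounded_size <- function(params, x, c) {
  eff <- params$lim * (1 + params$a4 * c)
  # 1e-9 slack absorbs rounding when a fitted limit sits on the boundary
  bad <- eff <= 0 | eff > 1 + 1e-9
  if (any(bad)) {
    stop("effective upper limit lim*(1 + a4*c) outside (0, 1] at c = ",
         c[which(bad)[1L]])
  }
  eff <- pmin(eff, 1)
  eff * .sigmoid(params$a1 * x + params$a2 * c + params$a3 * x * c + params$b)
}

#' Construct a fitted response curve
#'
#' Bundles a model family, its parameters, the endpoint it describes and
#' the irradiation duration it was fitted for.  When `size_stats` is
#' supplied, predictions can be made from raw cell areas in µm².
#'
#' @param family one of `"simple"`, `"bounded"`, `"size"`, `"bounded_size"`.
#' @param params matching parameter list from [model_params].
#' @param endpoint endpoint the curve models (`"target"`, `"neighboring"`,
#'   `"local"` or `"death"`), or `NA`.
#' @param duration irradiation duration in seconds the curve was fitted
#'   for, or `NA`.
#' @param size_stats optional `list(mean, sd)` of the size normalization.
#' @param c_range optional range of normalized sizes seen at fit time.
#' @return object of class `response_curve`.
#' @export
response_curve <- function(family, params, endpoint = NA_character_,
                           duration = NA_real_, size_stats = NULL,
                           c_range = NULL) {
  family <- match.arg(family, CURVE_FAMILIES)
  if (!identical(attr(params, "family"), family)) {
    stop("params are for family '", attr(params, "family"),
         "', not '", family, "'")
  }
  if (!is.na(endpoint)) endpoint <- match.arg(endpoint, ENDPOINTS)
  structure(list(family = family, params = params, endpoint = endpoint,
                 duration = duration, size_stats = size_stats,
                 c_range = c_range),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat("Response curve [", x$family, "]",
      if (!is.na(x$endpoint)) paste0(" endpoint=", x$endpoint),
      if (!is.na(x$duration)) paste0(" duration=", x$duration, "s"),
      "\n  ", paste(names(x$params), signif(unlist(x$params), 5),
                    sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

.uses_size <- function(family) family %in% c("size", "bounded_size")

#' Predict endpoint probability from a fitted curve
#'
#' @param object a [response_curve()].
#' @param power laser power in mW.
#' @param c normalized cell size; ignored by size-free families.
#' @param size raw cell area in µm²; converted to `c` via the curve's
#'   stored `size_stats` (overrides `c` when given).
#' @param ... unused.
#' @return vector of probabilities.
#' @export
predict.response_curve <- function(object, power, c = 0, size = NULL, ...) {
  if (!is.null(size)) {
    if (is.null(object$size_stats)) {
      stop("curve carries no size_stats; supply normalized c instead")
    }
    c <- (size - object$size_stats$mean) / object$size_stats$sd
  }
  switch(object$family,
    simple = predict_simple(object$params, power),
    bounded = predict_bounded(object$params, power),
    size = predict_size(object$params, power, c),
    bounded_size = predict_bounded_size(object$params, power, c)
  )
}

# assemble (x, c, y) model data for an endpoint; size-aware families drop
# records without a measured size
.model_frame <- function(dataset, endpoint, family) {
  y <- endpoint_outcomes(dataset, endpoint)
  x <- dataset$records$power_mw
  if (.uses_size(family)) {
    if (is.null(dataset$records$c_size)) {
      stop("size-covariate family requires normalize_cell_size() first")
    }
    c <- dataset$records$c_size
    keep <- !is.na(c)
    data.frame(x = x[keep], c = c[keep], y = y[keep])
  } else {
    data.frame(x = x, c = 0, y = y)
  }
}

#' Bernoulli log-likelihood of a curve on observed trials
#'
#' Sums `y log p + (1 - y) log(1 - p)` over trials.  Probabilities are
#' floored/ceiled at `1e-12` / `1 - 1e-12` inside the sum only (never in
#' predictions) so optimizers always see a finite value; a prediction that
#' is certain (`p` exactly 0 or 1) yet contradicted by the data is
#' reported through the `"contradiction"` attribute, the unclamped value
#' being `-Inf`.
#'
#' @param curve a [response_curve()].
#' @param data data frame with columns `x` (power, mW), `y` (0/1) and,
#'   for size-aware families, `c` (normalized size); alternatively a
#'   [trial_dataset()] together with `endpoint`.
#' @param endpoint endpoint to extract when `data` is a `trial_dataset`.
#' @return total log-likelihood (numeric scalar), with attribute
#'   `contradiction` (logical).
#' @export
log_likelihood <- function(curve, data, endpoint = curve$endpoint) {
  if (inherits(data, "trial_dataset")) {
    data <- .model_frame(data, endpoint, curve$family)
  }
  stopifnot(all(c("x", "y") %in% names(data)), all(data$y %in% c(0, 1)))
  cc <- if (.uses_size(curve$family)) data$c else 0
  p <- predict(curve, data$x, c = cc)
  eps <- 1e-12
  term <- ifelse(data$y == 1, log(pmax(p, eps)), log(pmax(1 - p, eps)))
  flag <- any((data$y == 1 & p == 0) | (data$y == 0 & p == 1))
  structure(sum(term), contradiction = flag)
}

#' Deviance of a curve on observed trials
#'
#' `-2` times the Bernoulli log-likelihood; always non-negative.  This is
#' the quantity differenced in the deviance-based likelihood-ratio test
#' for MCMC-fitted models.
#'
#' @inheritParams log_likelihood
#' @return deviance (numeric scalar), `contradiction` attribute preserved.
#' @export
deviance_at <- function(curve, data, endpoint = curve$endpoint) {
  ll <- log_likelihood(curve, data, endpoint)
  structure(-2 * as.numeric(ll), contradiction = attr(ll, "contradiction"))
}

#' Serialize a response curve to JSON
#'
#' The document records family, endpoint, duration, parameters and, when
#' present, the size normalization, so that predictions are reproducible
#' from raw µm² inputs.
#'
#' @param curve a [response_curve()].
#' @param path destination file; when `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
curve_to_json <- function(curve, path = NULL) {
  doc <- list(family = curve$family, endpoint = curve$endpoint,
              duration = curve$duration,
              params = curve$params[names(curve$params)],
              size_stats = curve$size_stats, c_range = curve$c_range)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(path)
}

#' Deserialize a response curve from JSON
#'
#' @param path file or JSON string produced by [curve_to_json()].
#' @return a [response_curve()].
#' @export
curve_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  maker <- switch(doc$family,
    simple = function(p) simple_params(p$a, p$b),
    bounded = function(p) bounded_params(p$lim, p$a, p$b),
    size = function(p) size_params(p$a1, p$a2, p$a3, p$b),
    bounded_size = function(p)
      bounded_size_params(p$lim, p$a1, p$a2, p$a3, p$a4, p$b),
    stop("unknown family: ", doc$family)
  )
  response_curve(
    doc$family, maker(doc$params),
    endpoint = if (is.null(doc$endpoint)) NA_character_ else doc$endpoint,
    duration = if (is.null(doc$duration)) NA_real_ else doc$duration,
    size_stats = doc$size_stats,
    c_range = doc$c_range
  )
}
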