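#' Bundle the four endpoint curves for dose optimization
#'
#' @param target,neighboring,death fitted [response_curve()] objects for
#'   the respective endpoints, all for the same irradiation duration.
#' @param local optional directly fitted curve for the local endpoint;
#'   when absent it is composed from `target` and `neighboring` on
#'   demand via [compose_local()].
#' @return object of class `curve_set`.
#' @export
curve_set <- function(target, neighboring, death, local = NULL) {
  curves <- list(target = target, neighboring = neighboring,
                 death = death, local = local)
  for (nm in names(curves)) {
    cv <- curves[[nm]]
    if (is.null(cv)) next
    stopifnot(inherits(cv, "response_curve"))
    if (!is.na(cv$endpoint) && cv$endpoint != nm) {
      stop("curve in slot '", nm, "' models endpoint '", cv$endpoint, "'")
    }
  }
  durs <- unlist(lapply(curves, function(cv) if (is.null(cv)) NULL else
    cv$duration))
  durs <- durs[!is.na(durs)]
  if (length(unique(durs)) > 1L) {
    stop("curves were fitted for different irradiation durations: ",
         paste(unique(durs), collapse = ", "))
  }
  structure(curves, class = "curve_set")
}

#' Local-recombination probability from the target and neighboring ones
#'
#' Union of the two recombination events under independence
#' (inclusion-exclusion): `p_t + p_n - p_t p_n`.
#'
#' @param p_t,p_n probabilities in `[0, 1]` (vectorized).
#' @return probability of recombination in the target and/or a
#'   neighboring cell.
#' @export
compose_local <- function(p_t, p_n) {
  stopifnot(all(p_t >= 0 & p_t <= 1), all(p_n >= 0 & p_n <= 1))
  p_t + p_n - p_t * p_n
}

#' Composite objective probability at a laser power
#'
#' Condition 1 is the probability of inducing recombination in the
#' single target cell but not in any other cell,
#' `p_target (1 - p_neighboring)`.  Condition 2 is the probability of
#' inducing recombination in at least one cell locally without any cell
#' death, `p_local (1 - p_death)`, where `p_local` is composed from the
#' target and neighboring curves when no direct local curve is present.
#' Both treat the endpoint events as independent.
#'
#' @param curves a [curve_set()].
#' @param condition 1 or 2.
#' @param x laser power in mW (vectorized).
#' @param c normalized cell size at which to evaluate (0 = average cell).
#' @return probability vector.
#' @export
condition_score <- function(curves, condition, x, c = 0) {
  stopifnot(inherits(curves, "curve_set"), condition %in% c(1, 2))
  if (condition == 1) {
    if (is.null(curves$target) || is.null(curves$neighboring)) {
      stop("condition 1 needs target and neighboring curves")
    }
    predict(curves$target, x, c = c) *
      (1 - predict(curves$neighboring, x, c = c))
  } else {
    if (is.null(curves$death)) stop("condition 2 needs a death curve")
    p_local <- if (!is.null(curves$local)) {
      predict(curves$local, x, c = c)
    } else {
      if (is.null(curves$target) || is.null(curves$neighboring)) {
        stop("condition 2 needs a local curve or target + neighboring")
      }
      compose_local(predict(curves$target, x, c = c),
                    predict(curves$neighboring, x, c = c))
    }
    p_local * (1 - predict(curves$death, x, c = c))
  }
}

#' Optimal laser power for a composite objective
#'
#' Maximizes [condition_score()] over a power range by scanning a
#' 0.01-mW grid and refining the best grid cell by golden-section search
#' ([stats::optimize()]).  Ties are broken toward the lowest power (less
#' heat, less damage).  Summaries round the power to 0.1 mW; the full
#' precision value is retained in the result.
#'
#' @param curves a [curve_set()].
#' @param condition 1 or 2, see [condition_score()].
#' @param power_range numeric `c(lo, hi)` in mW.
#' @param c normalized cell size at which to optimize.
#' @param grid_step scan step in mW (default 0.01).
#' @return object of class `dose_recommendation`: list with `condition`,
#'   `optimal_power`, `achieved_score`, `grid_step`, `c`, `power_range`,
#'   `degenerate` (TRUE when the score is identically zero and the range
#'   low end is returned).
#' @export
optimize_condition <- function(curves, condition, power_range, c = 0,
                               grid_step = 0.01) {
  stopifnot(is.numeric(power_range), length(power_range) == 2L,
            power_range[1L] < power_range[2L])
  lo <- power_range[1L]
  hi <- power_range[2L]
  grid <- unique(c(seq(lo, hi, by = grid_step), hi))
  f <- function(x) condition_score(curves, condition, x, c = c)
  scores <- f(grid)
  if (max(scores) <= 0) {
    return(structure(list(condition = condition, optimal_power = lo,
                          achieved_score = 0, grid_step = grid_step,
                          c = c, power_range = power_range,
                          degenerate = TRUE),
                     class = "dose_recommendation"))
  }
  i <- which.max(scores)  # first maximum = lowest power on ties
  lo_i <- grid[max(1L, i - 1L)]
  hi_i <- grid[min(length(grid), i + 1L)]
  best_x <- grid[i]
  best_s <- scores[i]
  if (hi_i > lo_i) {
    ref <- optimize(f, interval = c(lo_i, hi_i), maximum = TRUE,
                    tol = 1e-8)
    if (ref$objective > best_s) {
      best_x <- ref$maximum
      best_s <- ref$objective
    }
  }
  structure(list(condition = condition, optimal_power = best_x,
                 achieved_score = best_s, grid_step = grid_step, c = c,
                 power_range = power_range, degenerate = FALSE),
            class = "dose_recommendation")
}

#' @export
print.dose_recommendation <- function(x, ...) {
  cat(sprintf(
    "Condition %d: optimal power %.1f mW (score %.4f) over [%g, %g] mW%s\n",
    x$condition, x$optimal_power, x$achieved_score, x$power_range[1L],
    x$power_range[2L],
    if (x$c != 0) sprintf(" at c = %g", x$c) else ""))
  if (x$degenerate) cat("  (score identically zero over the range)\n")
  invisible(x)
}

#' Laser power at which a probability curve reaches a threshold
#'
#' The raising point of an endpoint curve: the power where the fitted
#' probability first reaches the threshold (10% by default), located by
#' bisection ([stats::uniroot()]) to within 1e-6 in probability.  The
#' curve must be increasing in power over the range.  When even the top
#' of the range stays below the threshold (e.g. a bounded curve whose
#' effective limit is below it) the point is flagged unreachable; when
#' the curve is already above the threshold at the low end, the low end
#' is returned flagged `"below_range"`.
#'
#' @param curve a [response_curve()].
#' @param threshold probability threshold, default 0.10.
#' @param power_range numeric `c(lo, hi)` in mW to search.
#' @param c normalized cell size at which to evaluate.
#' @return object of class `raising_point`: list with `endpoint`,
#'   `threshold`, `power` (`NA` when unreachable) and `status`
#'   (`"ok"`, `"unreachable"` or `"below_range"`).
#' @export
raising_point <- function(curve, threshold = 0.10, power_range, c = 0) {
  stopifnot(inherits(curve, "response_curve"), threshold > 0,
            threshold < 1, is.numeric(power_range),
            length(power_range) == 2L, power_range[1L] < power_range[2L])
  slope <- switch(curve$family,
    simple = curve$params$a,
    bounded = curve$params$a,
    size = curve$params$a1 + curve$params$a3 * c,
    bounded_size = curve$params$a1 + curve$params$a3 * c
  )
  if (slope <= 0) {
    stop("curve is not increasing in power at c = ", c,
         " (effective slope ", signif(slope, 4), ")")
  }
  f <- function(x) predict(curve, x, c = c)
  lo <- power_range[1L]
  hi <- power_range[2L]
  rp <- function(power, status) {
    structure(list(endpoint = curve$endpoint, threshold = threshold,
                   power = power, status = status),
              class = "raising_point")
  }
  if (f(hi) < threshold) return(rp(NA_real_, "unreachable"))
  if (f(lo) > threshold) return(rp(lo, "below_range"))
  root <- uniroot(function(x) f(x) - threshold, lower = lo, upper = hi,
                  tol = 1e-12)
  rp(root$root, "ok")
}

#' @export
print.raising_point <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("Raising point (%s, %g%%): %.2f mW\n",
                x$endpoint, 100 * x$threshold, x$power))
  } else {
    cat(sprintf("Raising point (%s, %g%%): %s\n",
                x$endpoint, 100 * x$threshold, x$status))
  }
  invisible(x)
}

#' Direct versus composed local-probability discrepancy
#'
#' The local endpoint can be fitted directly or composed from the target
#' and neighboring curves under independence.  This reports the maximum
#' absolute gap between the two over a power grid — a check of the
#' independence approximation behind [compose_local()].
#'
#' @param direct_local a [response_curve()] fitted on the local endpoint.
#' @param curves a [curve_set()] providing target and neighboring curves.
#' @param power_range numeric `c(lo, hi)` in mW.
#' @param c normalized cell size.
#' @param grid_step grid step in mW (default 0.1).
#' @return maximum absolute discrepancy (numeric scalar) with attribute
#'   `at` (the power where it occurs).
#' @export
local_consistency_check <- function(direct_local, curves, power_range,
                                    c = 0, grid_step = 0.1) {
  stopifnot(inherits(direct_local, "response_curve"),
            inherits(curves, "curve_set"))
  grid <- unique(c(seq(power_range[1L], power_range[2L], by = grid_step),
                   power_range[2L]))
  composed <- compose_local(predict(curves$target, grid, c = c),
                            predict(curves$neighboring, grid, c = c))
  gap <- abs(predict(direct_local, grid, c = c) - composed)
  structure(max(gap), at = grid[which.max(gap)])
}

#' Optimal power as a function of cell size
#'
#' Runs [optimize_condition()] at each requested normalized cell size
#' using size-aware curves, predicting how the recommended laser power
#' shifts for smaller or larger cells.  A requested size more than 2
#' units of normalized size outside the range seen at fit time is
#' flagged as extrapolation.
#'
#' @param curves a [curve_set()] whose curves are all of size-aware
#'   families (`size` or `bounded_size`).
#' @param condition 1 or 2.
#' @param power_range numeric `c(lo, hi)` in mW.
#' @param c_values numeric vector of normalized sizes.
#' @param grid_step scan step in mW.
#' @return list of `dose_recommendation` objects, one per `c`, each with
#'   an `extrapolation` element.
#' @export
size_conditional_recommendation <- function(curves, condition, power_range,
                                            c_values, grid_step = 0.01) {
  stopifnot(inherits(curves, "curve_set"), is.numeric(c_values))
  fams <- unlist(lapply(curves[!vapply(curves, is.null, logical(1L))],
                        function(cv) cv$family))
  if (!all(.uses_size(fams))) {
    stop("size-conditional recommendations need size-aware curves; got ",
         paste(unique(fams), collapse = ", "))
  }
  cr <- do.call(rbind, lapply(curves[!vapply(curves, is.null, logical(1L))],
                              function(cv) cv$c_range))
  c_lo <- if (is.null(cr)) -Inf else min(cr[, 1L])
  c_hi <- if (is.null(cr)) Inf else max(cr[, 2L])
  lapply(c_values, function(cc) {
    rec <- optimize_condition(curves, condition, power_range, c = cc,
                              grid_step = grid_step)
    rec$extrapolation <- cc < c_lo - 2 || cc > c_hi + 2
    if (rec$extrapolation) {
      warning("c = ", cc, " is more than 2 units outside the fitted ",
              "size range [", signif(c_lo, 4), ", ", signif(c_hi, 4), "]")
    }
    rec
  })
}
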