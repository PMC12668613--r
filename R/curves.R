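# Survival and incidence curve containers and the restricted-mean life
# expectancy operations built on them. Curves are step/linear functions on a
# common monthly grid; life expectancy is the area under the survival curve up
# to the horizon (restricted mean survival time), the estimator used for every
# "expected life years" quantity in the package.

#' Survival curve
#'
#' A discretised survival function S(t): probability of being event-free at
#' each grid time. Invariants: `S(0) = 1`, non-increasing, values in `[0, 1]`,
#' strictly increasing times.
#'
#' @param times numeric grid in years, starting at 0, strictly increasing.
#' @param probabilities survival probabilities on the grid.
#' @param horizon horizon in years; defaults to the last grid point.
#' @return an object of class `survival_curve`.
#' @export
survival_curve <- function(times, probabilities, horizon = max(times)) {
  check_curve_arrays(times, probabilities)
  if (abs(probabilities[1] - 1) > 1e-8) {
    stop("survival curve must start at S(0) = 1", call. = FALSE)
  }
  if (any(diff(probabilities) > 1e-8)) {
    stop("survival probabilities must be non-increasing", call. = FALSE)
  }
  structure(
    list(times = times, probabilities = pmin(pmax(probabilities, 0), 1),
         horizon = horizon),
    class = "survival_curve"
  )
}

#' Cumulative incidence curve
#'
#' Cumulative probability of the event of interest (here: receiving a
#' transplant) by each grid time. Starts at 0, non-decreasing, bounded by 1.
#'
#' @param times numeric grid in years starting at 0.
#' @param cumulative_probability cumulative event probabilities.
#' @param horizon horizon in years.
#' @return an object of class `incidence_curve`.
#' @export
incidence_curve <- function(times, cumulative_probability, horizon = max(times)) {
  check_curve_arrays(times, cumulative_probability)
  if (abs(cumulative_probability[1]) > 1e-8) {
    stop("incidence curve must start at 0", call. = FALSE)
  }
  if (any(diff(cumulative_probability) < -1e-8)) {
    stop("cumulative incidence must be non-decreasing", call. = FALSE)
  }
  structure(
    list(times = times,
         cumulative_probability = pmin(pmax(cumulative_probability, 0), 1),
         horizon = horizon),
    class = "incidence_curve"
  )
}

check_curve_arrays <- function(times, values) {
  if (length(times) < 2L) stop("empty grid: need at least two time points", call. = FALSE)
  if (length(times) != length(values)) stop("times and values differ in length", call. = FALSE)
  if (abs(times[1]) > 1e-12) stop("time grid must start at 0", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(values < -1e-8 | values > 1 + 1e-8)) {
    stop("curve values must lie in [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Convert between a survival curve and its incidence complement
#'
#' For a single-event process, the cumulative incidence is `1 - S(t)`. Used to
#' turn an event-free ("transplant-free") survival curve into the
#' time-to-transplant curve.
#'
#' @param curve a `survival_curve`.
#' @return an `incidence_curve`.
#' @export
as_incidence <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  incidence_curve(curve$times, 1 - curve$probabilities, curve$horizon)
}

#' Restricted-mean life expectancy from a survival curve
#'
#' Trapezoidal integral of S(t) over `[0, horizon]`, in years. This is the
#' restricted mean survival time; every life-expectancy quantity downstream
#' (status quo, after relisting, post-transplant) is computed this way.
#'
#' @param curve a `survival_curve`.
#' @return expected life years in `[0, horizon]`.
#' @export
life_expectancy <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  trapz(curve$times, curve$probabilities)
}

#' Condition a curve on elapsed waiting time
#'
#' Left-truncates the curve at `elapsed` years and renormalises:
#' `S'(t) = S(elapsed + t) / S(elapsed)` for a survival curve, and
#' `F'(t) = (F(elapsed + t) - F(elapsed)) / (1 - F(elapsed))` for an incidence
#' curve. The result is re-gridded from 0 with the same step and horizon
#' reduced by `elapsed`.
#'
#' @param curve a `survival_curve` or `incidence_curve`.
#' @param elapsed years already survived/waited; must satisfy
#'   `S(elapsed) > 0` (resp. `F(elapsed) < 1`).
#' @return curve of the same class on `[0, horizon - elapsed]`.
#' @export
conditional_curve <- function(curve, elapsed) {
  UseMethod("conditional_curve")
}

#' @export
conditional_curve.survival_curve <- function(curve, elapsed) {
  shifted <- shift_curve_values(curve$times, curve$probabilities, elapsed)
  s0 <- shifted$value_at_elapsed
  if (s0 <= 0) stop("degenerate conditioning: S(elapsed) = 0", call. = FALSE)
  survival_curve(shifted$times, pmin(shifted$values / s0, 1),
                 horizon = curve$horizon - elapsed)
}

#' @export
conditional_curve.incidence_curve <- function(curve, elapsed) {
  shifted <- shift_curve_values(curve$times, curve$cumulative_probability, elapsed)
  f0 <- shifted$value_at_elapsed
  if (f0 >= 1) stop("degenerate conditioning: F(elapsed) = 1", call. = FALSE)
  incidence_curve(shifted$times, pmin((shifted$values - f0) / (1 - f0), 1),
                  horizon = curve$horizon - elapsed)
}

# Shift a gridded function left by `elapsed`. When elapsed falls on the grid
# (the usual case: elapsed a multiple of the step) this is pure indexing and
# exact; otherwise values are linearly interpolated.
shift_curve_values <- function(times, values, elapsed) {
  if (elapsed < 0) stop("elapsed must be non-negative", call. = FALSE)
  if (elapsed == 0) {
    return(list(times = times, values = values, value_at_elapsed = values[1]))
  }
  if (elapsed >= max(times)) stop("elapsed exceeds the curve horizon", call. = FALSE)
  step <- times[2] - times[1]
  k <- round(elapsed / step)
  if (abs(k * step - elapsed) < 1e-8 && k < length(times)) {
    idx <- (k + 1L):length(times)
    return(list(times = times[idx] - times[k + 1L], values = values[idx],
                value_at_elapsed = values[k + 1L]))
  }
  new_times <- times[times <= max(times) - elapsed + 1e-12]
  vals <- stats::approx(times, values, xout = new_times + elapsed, rule = 2)$y
  list(times = new_times, values = vals,
       value_at_elapsed = stats::approx(times, values, xout = elapsed)$y)
}
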