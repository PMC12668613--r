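# Internal helpers shared across modules.

#' Monthly time grid
#'
#' Grid of time points in years from 0 to `horizon`, used everywhere a curve is
#' discretised. The step must divide the horizon evenly.
#'
#' @param horizon horizon in years.
#' @param step grid step in years (default one month, 1/12).
#' @return numeric vector `0, step, 2*step, ..., horizon`.
#' @export
time_grid <- function(horizon, step = 1 / 12) {
  stopifnot(horizon > 0, step > 0)
  n <- round(horizon / step)
  if (abs(n * step - horizon) > 1e-8) {
    stop("time_step must divide the horizon evenly", call. = FALSE)
  }
  seq(0, by = step, length.out = n + 1)
}

# trapezoidal integral of y over x
trapz <- function(x, y) {
  if (length(x) < 2L) stop("empty grid: need at least two time points", call. = FALSE)
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

# row-wise trapezoidal integral for a matrix of curves on a common grid
trapz_rows <- function(x, Y) {
  w <- diff(x)
  drop((Y[, -ncol(Y), drop = FALSE] + Y[, -1, drop = FALSE]) %*% w) / 2
}

# Deterministic per-stream sub-seed so enlarging one table does not perturb the
# draws of another. Always < 2^31.
subseed <- function(seed, stream) {
  offsets <- c(
    patients = 11L, donors = 23L, centers = 31L, offers = 37L,
    posttx = 53L, relist = 61L, model = 71L, misc = 89L
  )
  if (!stream %in% names(offsets)) stop("unknown random stream: ", stream)
  (abs(as.integer(seed)) %% 1000003L) * 1009L + offsets[[stream]]
}

# exponential draw that tolerates rate 0 (no events ever)
rexp_safe <- function(n, rate) {
  if (rate <= 0) rep(Inf, n) else stats::rexp(n, rate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
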