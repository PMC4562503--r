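#' Three-stage impulse-response parameters
#'
#' Parameters of the impulse response of a cascade of three leaky
#' integrators with distinct decay rates `a`, `b`, `c` (per second):
#' `f(t) = K * ((c-b) e^{-a t} + (b-a) e^{-c t} - (c-a) e^{-b t})`,
#' where `K` is a norming constant chosen so that the peak equals 1.  The
#' function starts at `f(0) = 0`, rises to a single peak, and decays to 0;
#' it is the package's model of the time course of a fading percept and of
#' the contrast reduction of the physically decaying proxy stimulus.
#'
#' @param a_rate,b_rate,c_rate Decay rates, s^-1; positive and pairwise
#'   distinct (the closed form degenerates when two coincide).
#' @param norm_const Dimensionless scale applied to the bracketed sum.
#' @param offset_threshold Criterion level defining the perceptual offset
#'   time (set by [calibrate_offset()]).
#' @param t_off Target offset time in seconds (set by [calibrate_offset()]).
#' @return Object of class `decay_params`.
#' @export
decay_params <- function(a_rate, b_rate, c_rate, norm_const = 1,
                         offset_threshold = NA_real_, t_off = NA_real_) {
  rates <- c(a_rate, b_rate, c_rate)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("decay rates must be finite and positive")
  if (min(dist(rates)) < 1e-9 * max(rates))
    stop("decay rates must be pairwise distinct (formula degenerates)")
  structure(
    list(a_rate = a_rate, b_rate = b_rate, c_rate = c_rate,
         norm_const = norm_const, offset_threshold = offset_threshold,
         t_off = t_off, t_peak = NA_real_, calibrated = FALSE),
    class = "decay_params")
}

#' @export
print.decay_params <- function(x, ...) {
  cat(sprintf("decay params: a = %.6g, b = %.6g, c = %.6g s^-1; K = %.6g\n",
              x$a_rate, x$b_rate, x$c_rate, x$norm_const))
  if (isTRUE(x$calibrated))
    cat(sprintf("  calibrated: f(%.4g s) = %.3g, peak at %.4g s\n",
                x$t_off, x$offset_threshold, x$t_peak))
  invisible(x)
}

#' Evaluate the three-stage impulse response
#'
#' @param t Time in seconds (vectorised, non-negative).
#' @param p A [decay_params()] object.
#' @return `norm_const * ((c-b) e^{-a t} + (b-a) e^{-c t} - (c-a) e^{-b t})`.
#' @export
impulse_response <- function(t, p) {
  stopifnot(inherits(p, "decay_params"))
  if (any(t < 0)) stop("t must be non-negative")
  a <- p$a_rate; b <- p$b_rate; c <- p$c_rate
  p$norm_const * ((c - b) * exp(-a * t) + (b - a) * exp(-c * t) -
                    (c - a) * exp(-b * t))
}

# Peak location/height: dense 1-ms grid over a rate-adapted window, then
# local refinement with optimize().  Very slow rates (peak beyond a few
# seconds) use a log-spaced coarse grid instead, to keep the grid bounded.
decay_peak <- function(p) {
  slow <- min(p$a_rate, p$b_rate, p$c_rate)
  t_hi <- min(max(1, 10 / slow), 1e4)
  grid <- if (t_hi <= 5) seq(0, t_hi, by = 1e-3)
          else c(0, exp(seq(log(1e-4), log(t_hi), length.out = 5000L)))
  v <- impulse_response(grid, p)
  i <- which.max(abs(v))
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(t) abs(impulse_response(t, p)),
                         c(lo, hi), maximum = TRUE, tol = 1e-12)
  list(t_peak = opt$maximum, peak = impulse_response(opt$maximum, p))
}

#' Normalise a decay curve to unit peak
#'
#' Sets `norm_const` so that the maximum of the response equals 1 (the sign
#' of the raw bracketed sum is absorbed, so swapping `b` and `c` leaves the
#' normalised curve unchanged).
#'
#' @param p A [decay_params()] object.
#' @return `p` with `norm_const` and `t_peak` set.
#' @export
normalize_peak <- function(p) {
  stopifnot(inherits(p, "decay_params"))
  p$norm_const <- 1
  pk <- decay_peak(p)
  p$norm_const <- 1 / pk$peak
  p$t_peak <- pk$t_peak
  p
}

# First time after the peak at which the normalised curve crosses `level`
# downwards.  The tail is a sum of decaying exponentials, so the crossing
# exists for any 0 < level < 1.
crossing_after_peak <- function(p, level) {
  f <- function(t) impulse_response(t, p) - level
  lo <- p$t_peak
  hi <- p$t_peak + 1 / min(p$a_rate, p$b_rate, p$c_rate)
  while (f(hi) > 0 && hi < 1e6) hi <- hi * 2
  if (f(hi) > 0) stop("no downward crossing found (level too small?)")
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Calibrate decay rates to a target perceptual-offset time
#'
#' With `a` fixed and `c = rate_ratio * b`, finds `b` by bisection such that
#' the peak-normalised response first falls through `threshold` exactly at
#' `t_off` seconds.  One constraint cannot fix two free rates, so the ratio
#' `c / b` is held fixed (default 1.2).  The crossing time is strictly
#' decreasing in `b` (faster stages decay sooner), which the bisection
#' exploits.
#'
#' @param a_rate First-stage decay rate, s^-1 (default 50).
#' @param t_off Target offset time, seconds (positive).
#' @param threshold Offset criterion in (0, 1); the curve only reaches 0
#'   asymptotically, so `threshold = 0` is rejected.  Default 0.01.
#' @param rate_ratio `c / b`, positive and != 1.  Default 1.2.
#' @param b_range Bisection bracket for `b`, s^-1.
#' @param tol Tolerance on the crossing time, seconds.
#' @return A calibrated [decay_params()] object (`calibrated = TRUE`,
#'   unit peak, `f(t_off) = threshold`).
#' @examples
#' p <- calibrate_offset(a_rate = 50, t_off = 0.6)
#' impulse_response(0.6, p)  # 0.01
#' @export
calibrate_offset <- function(a_rate = 50, t_off, threshold = 0.01,
                             rate_ratio = 1.2,
                             b_range = c(1e-3, 0.999 * a_rate),
                             tol = 1e-9) {
  stopifnot(a_rate > 0, t_off > 0, rate_ratio > 0, rate_ratio != 1)
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly between 0 and 1")
  make <- function(b) {
    # keep b and c away from a: the closed form degenerates at coincidence
    eps <- 1e-7 * a_rate
    if (abs(b - a_rate) < eps) b <- b + eps
    if (abs(rate_ratio * b - a_rate) < eps) b <- b + eps / rate_ratio
    normalize_peak(decay_params(a_rate, b, rate_ratio * b))
  }
  t_cross <- function(b) crossing_after_peak(make(b), threshold)
  lo <- b_range[1]; hi <- b_range[2]
  t_lo <- t_cross(lo); t_hi <- t_cross(hi)
  if (!(t_lo >= t_off && t_off >= t_hi))
    stop(sprintf(paste0("no solution in b-range [%g, %g] s^-1: crossing times",
                        " [%g, %g] s do not bracket t_off = %g s"),
                 lo, hi, t_hi, t_lo, t_off))
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    t_mid <- t_cross(mid)
    if (abs(t_mid - t_off) < tol || (hi - lo) < 1e-14 * hi) break
    if (t_mid > t_off) lo <- mid else hi <- mid
  }
  p <- make(mid)
  p$offset_threshold <- threshold
  p$t_off <- t_off
  p$calibrated <- TRUE
  p
}

#' Persistence duration read off a calibrated decay curve
#'
#' The first time after the peak at which the normalised response falls
#' below `criterion`.  At `criterion = 1` this is the peak time; at the
#' calibration threshold it is the calibrated `t_off` by construction.
#'
#' @param p A calibrated [decay_params()] object.
#' @param criterion Offset criterion in (0, 1].
#' @return Time in seconds.
#' @export
persistence_duration <- function(p, criterion) {
  stopifnot(inherits(p, "decay_params"))
  if (!isTRUE(p$calibrated)) stop("decay params must be calibrated first")
  if (!is.finite(criterion) || criterion <= 0 || criterion > 1)
    stop("criterion must lie in (0, 1]")
  if (criterion == 1) return(p$t_peak)
  crossing_after_peak(p, criterion)
}
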