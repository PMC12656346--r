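#' Uniformly sampled 1D trajectory
#'
#' One joint, one coordinate (or one derived angle), sampled on a uniform
#' time grid. All integral and warping arithmetic in the package runs on
#' these.
#'
#' @param values numeric vector of finite samples (length >= 2).
#' @param t0 start time in seconds.
#' @param dt sample spacing in seconds (> 0).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(values, t0 = 0, dt = 1) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("trajectory needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(values)))
    stop("trajectory samples must be finite", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a single positive number", call. = FALSE)
  structure(list(values = values, t0 = as.numeric(t0), dt = as.numeric(dt)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d samples, t0 = %g s, dt = %g s (%.3g Hz)\n",
              length(x$values), x$t0, x$dt, 1 / x$dt))
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$values)

traj_times <- function(traj) traj$t0 + (seq_along(traj$values) - 1) * traj$dt

traj_end <- function(traj) traj$t0 + (length(traj$values) - 1) * traj$dt

#' Centered moving-average smoothing
#'
#' Smooths a trajectory with a centered moving window. Edge frames average
#' over the samples actually available (shrunken windows), so the output has
#' the same length as the input and no padded values are invented; the signal
#' range is never expanded.
#'
#' @param traj a [trajectory()] (or bare numeric vector).
#' @param window odd window length in frames; `1` is the identity.
#' @return Smoothed object of the same type as the input.
#' @export
smooth_moving_average <- function(traj, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("smoothing window must be an odd count >= 1, got ", window,
         call. = FALSE)
  vals <- if (inherits(traj, "trajectory")) traj$values else as.numeric(traj)
  if (window > length(vals))
    stop("smoothing window exceeds trajectory length", call. = FALSE)
  out <- moving_average_vec(vals, window)
  if (inherits(traj, "trajectory")) trajectory(out, traj$t0, traj$dt) else out
}

# Shrunken-window moving average via cumulative sums: O(n).
moving_average_vec <- function(vals, window) {
  if (window == 1L) return(vals)
  n <- length(vals)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, vals))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Resample a trajectory onto a uniform grid
#'
#' Interpolates onto `n_samples` evenly spaced times spanning the original
#' support `[t0, t_end]`. The default interpolant is a monotone-preserving
#' piecewise cubic (Fritsch-Carlson Hermite spline), which reproduces the
#' endpoints exactly, introduces no overshoot on monotone segments, and is
#' markedly more accurate than linear interpolation on smooth motion.
#'
#' @param traj a [trajectory()].
#' @param n_samples number of output samples (>= 2).
#' @param method `"cubic"` (default) or `"linear"`.
#' @return A [trajectory()] with `n_samples` samples on the same support.
#' @export
resample_uniform <- function(traj, n_samples, method = c("cubic", "linear")) {
  method <- match.arg(method)
  n_samples <- as.integer(n_samples)
  if (n_samples < 2L)
    stop("n_samples must be >= 2", call. = FALSE)
  tt <- traj_times(traj)
  new_t <- seq(tt[1], tt[length(tt)], length.out = n_samples)
  vals <- interp_values(tt, traj$values, new_t, method)
  trajectory(vals, t0 = new_t[1], dt = new_t[2] - new_t[1])
}

# Shared interpolation core (also used on non-uniform source grids by the
# phase rescaling and the CSV dropout filler).
interp_values <- function(t_in, v_in, t_out, method = c("cubic", "linear")) {
  method <- match.arg(method)
  if (method == "linear" || length(t_in) < 3L) {
    stats::approx(t_in, v_in, xout = t_out, rule = 2)$y
  } else {
    f <- stats::splinefun(t_in, v_in, method = "monoH.FC")
    f(pmin(pmax(t_out, t_in[1]), t_in[length(t_in)]))
  }
}

#' Time-normalize a sampled signal to the unit interval
#'
#' Maps a signal observed at arbitrary strictly increasing times onto `M`
#' uniform samples over \[0, 1\], so phases of unequal duration become
#' comparable: the integral then measures path difference, not tempo.
#'
#' @param t sample times (strictly increasing, length >= 2).
#' @param v sample values.
#' @param M number of output samples.
#' @param method interpolation method, see [resample_uniform()].
#' @return A [trajectory()] on \[0, 1\] with `M` samples.
#' @export
time_normalize <- function(t, v, M = 100L, method = "cubic") {
  if (length(t) < 2L) stop("need at least 2 samples", call. = FALSE)
  u <- (t - t[1]) / (t[length(t)] - t[1])
  out_u <- seq(0, 1, length.out = M)
  trajectory(interp_values(u, v, out_u, method), t0 = 0,
             dt = 1 / (M - 1))
}
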