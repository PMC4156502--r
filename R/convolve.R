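#' Linear interpolation of a rate profile
#'
#' Piecewise-linear interpolant of the measured relative transcription rate,
#' exact at the sampling points. No extrapolation: queries outside the grid
#' span are an error (the kinetic models never need them).
#'
#' @param f Rate values at `time` (linear scale).
#' @param time Sampling grid (min), strictly increasing from 0.
#' @param t Query times within `[0, max(time)]`.
#' @return Interpolated rate values at `t`.
#' @export
interp_rate <- function(f, time, t) {
  check_time_grid(time)
  if (length(f) != length(time)) stop("f and time must have equal length")
  if (any(t < time[1L]) || any(t > time[length(time)]))
    stop("query times must lie within the time-grid span (no extrapolation)")
  approx(time, f, xout = t)$y
}

#' Decay convolution integral of a rate profile
#'
#' Evaluates `I(t) = int_0^t f(t') exp(k (t' - t)) dt'` for the
#' piecewise-linear interpolant of `f`, the building block of both kinetic
#' models. Two interchangeable evaluators are provided: an exact per-segment
#' closed form (default, used by the fitters) and adaptive quadrature over
#' the interpolant (the cross-checking route, mirroring `stats::integrate`
#' over `stats::approx`).
#'
#' @param f Rate values at `time` (linear scale).
#' @param time Sampling grid (min), strictly increasing from 0.
#' @param k Decay rate constant (1/min, > 0).
#' @param t Evaluation times within the grid span (default: the grid).
#' @param method `"closed"` (exact per-segment) or `"quadrature"`.
#' @param rel_tol Relative tolerance for the quadrature route.
#' @return Values of the convolution integral at `t`.
#' @examples
#' tt <- c(0, 5, 10)
#' convolve_decay(rep(1, 3), tt, k = 0.1, t = 10) # (1 - exp(-1)) / 0.1
#' @export
convolve_decay <- function(f, time, k, t = time,
                           method = c("closed", "quadrature"),
                           rel_tol = 1e-8) {
  method <- match.arg(method)
  check_time_grid(time)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stop("decay constant k must be a single positive number")
  if (any(t < 0) || any(t > max(time)))
    stop("evaluation times must lie within the time-grid span")
  if (method == "closed") {
    return(as.numeric(conv_decay_cpp(time, f, k, t)))
  }
  fi <- approxfun(time, f)
  # integrate piecewise between interpolation knots: the integrand has kinks
  # there, which adaptive quadrature over the full span handles poorly
  vapply(t, function(tt) {
    if (tt == 0) return(0)
    knots <- sort(unique(c(0, time[time < tt], tt)))
    total <- 0
    for (j in seq_len(length(knots) - 1L)) {
      total <- total +
        integrate(function(tp) fi(tp) * exp(k * (tp - tt)),
                  lower = knots[j], upper = knots[j + 1L],
                  rel.tol = rel_tol, subdivisions = 200L)$value
    }
    total
  }, numeric(1))
}

#' Predicted expression under the constant-decay model
#'
#' Forward-evaluates `y(t) = A I_k(t) + B + C exp(-k t)` where `I_k` is the
#' decay convolution of the rate profile ([convolve_decay()]). `A = 0`
#' reduces to the pure exponential-approach form `B + C exp(-k t)`.
#'
#' @param params Named vector or list with `A` (>= 0), `B`, `C`, `k` (> 0).
#' @param f Rate values at `time` (linear relative scale).
#' @param time Sampling grid (min).
#' @param t Evaluation times (default: the grid).
#' @return Predicted relative expression at `t` (linear scale).
#' @export
forward_constant <- function(params, f, time, t = time) {
  p <- as.list(params)
  if (p$A < 0) stop("A must be non-negative")
  if (p$k <= 0) stop("k must be positive")
  I <- convolve_decay(f, time, p$k, t)
  p$A * I + p$B + p$C * exp(-p$k * t)
}

#' Predicted expression under the switch-decay model
#'
#' Forward-evaluates the piecewise model with decay constant `k1` up to
#' `t_switch` and `k2` after it. The post-switch branch is
#' `A I_{k2}(t) + B k1/k2 + G exp(-k2 t)` with the continuity constant `G`
#' always recomputed internally so that the prediction is continuous at
#' `t_switch`; it is never user-supplied.
#'
#' @param params Named vector or list with `A` (>= 0), `B`, `C`,
#'   `k1`, `k2` (> 0), and `t_switch` strictly inside `(0, max(time))`.
#' @param f Rate values at `time` (linear relative scale).
#' @param time Sampling grid (min).
#' @param t Evaluation times (default: the grid).
#' @return Predicted relative expression at `t` (linear scale).
#' @export
forward_switch <- function(params, f, time, t = time) {
  p <- as.list(params)
  if (p$A < 0) stop("A must be non-negative")
  if (p$k1 <= 0 || p$k2 <= 0) stop("decay constants must be positive")
  ts <- p$t_switch
  if (is.null(ts) || ts <= 0 || ts >= max(time))
    stop("t_switch must lie strictly inside (0, max(time))")
  I1s <- convolve_decay(f, time, p$k1, ts)
  I2s <- convolve_decay(f, time, p$k2, ts)
  y1s <- p$A * I1s + p$B + p$C * exp(-p$k1 * ts)
  base2 <- y1s - p$A * I2s - p$B * p$k1 / p$k2  # G e^{-k2 t} = base2 e^{-k2 (t-ts)}
  out <- numeric(length(t))
  pre <- t <= ts
  if (any(pre)) {
    out[pre] <- p$A * convolve_decay(f, time, p$k1, t[pre]) + p$B +
      p$C * exp(-p$k1 * t[pre])
  }
  if (any(!pre)) {
    out[!pre] <- p$A * convolve_decay(f, time, p$k2, t[!pre]) +
      p$B * p$k1 / p$k2 + base2 * exp(-p$k2 * (t[!pre] - ts))
  }
  out
}
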