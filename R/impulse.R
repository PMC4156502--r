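#' Two-sigmoid impulse transcription-rate program
#'
#' Builds a smooth transcription-rate program of time shaped as an "impulse
#' and recovery": a baseline plateau `h0`, a transient plateau `h1` reached
#' around onset midpoint `t1`, and a recovery plateau `h2` approached around
#' recovery midpoint `t2`. The functional form is the product of two logistic
#' sigmoids scaled by `1/h1`, the standard parsimonious shape for transient
#' stress-response transcription programs.
#'
#' @param h0,h1,h2 Plateau levels before, during, and after the response
#'   (arbitrary rate units, all > 0).
#' @param t1 Onset midpoint (min).
#' @param t2 Recovery midpoint (min); must satisfy `0 <= t1 < t2`.
#' @param beta Sigmoid steepness (1/min, > 0). Large values approach a step.
#' @return A function of time `t` returning the rate, of class
#'   `"impulse_rate"`, with the parameters attached as attribute `"params"`.
#' @examples
#' r <- impulse_rate(h0 = 1, h1 = 4, h2 = 1, t1 = 5, t2 = 40, beta = 2)
#' r(c(0, 20, 120))
#' @export
impulse_rate <- function(h0, h1, h2, t1, t2, beta) {
  vals <- c(h0 = h0, h1 = h1, h2 = h2, t1 = t1, t2 = t2, beta = beta)
  if (any(!is.finite(vals)))
    stop("impulse parameters must all be finite")
  if (h0 <= 0 || h1 <= 0 || h2 <= 0)
    stop("impulse plateau levels must be positive")
  if (t1 < 0 || t1 >= t2)
    stop("impulse midpoints must satisfy 0 <= t1 < t2")
  if (beta <= 0)
    stop("impulse steepness beta must be positive")
  force(vals)
  f <- function(t) {
    s1 <- h0 + (h1 - h0) * plogis(beta * (t - t1))
    s2 <- h2 + (h1 - h2) * plogis(-beta * (t - t2))
    s1 * s2 / h1
  }
  attr(f, "params") <- vals
  class(f) <- c("impulse_rate", "function")
  f
}

#' @export
print.impulse_rate <- function(x, ...) {
  p <- attr(x, "params")
  cat("Impulse transcription-rate program\n")
  cat(sprintf("  plateaus: h0 = %.3g, h1 = %.3g, h2 = %.3g\n",
              p["h0"], p["h1"], p["h2"]))
  cat(sprintf("  midpoints: t1 = %.3g min, t2 = %.3g min; beta = %.3g /min\n",
              p["t1"], p["t2"], p["beta"]))
  invisible(x)
}
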