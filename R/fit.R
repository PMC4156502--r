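#' Paired transcription/expression time course for one gene
#'
#' Light container for the model inputs: the shared time grid and the
#' relative transcription-rate (`f`) and expression (`y`) profiles.
#'
#' @param time Sampling grid (min), strictly increasing from 0.
#' @param f,y Relative profiles at `time`; positive on the linear scale.
#' @param gene_id Gene identifier.
#' @param input `"linear"` if `f`/`y` are linear ratios, `"log2"` if they
#'   are log2 ratios (converted internally).
#' @return List of class `"time_course_pair"` with elements `gene_id`,
#'   `time`, `f`, `y` (linear scale), and `complete` (no missing values).
#' @export
time_course_pair <- function(time, f, y, gene_id = "gene",
                             input = c("linear", "log2")) {
  input <- match.arg(input)
  check_time_grid(time)
  if (length(f) != length(time) || length(y) != length(time))
    stop("f and y must have one value per time point")
  if (input == "log2") {
    f <- 2^f
    y <- 2^y
  }
  complete <- !anyNA(f) && !anyNA(y)
  if (any(f <= 0, na.rm = TRUE) || any(y <= 0, na.rm = TRUE))
    stop("relative profiles must be positive on the linear scale")
  structure(list(gene_id = as.character(gene_id), time = as.numeric(time),
                 f = as.numeric(f), y = as.numeric(y), complete = complete),
            class = "time_course_pair")
}

#' Fitting options for the kinetic models
#'
#' Initial values, bounds, and iteration budget for the derivative-free
#' least-squares fits. Defaults follow the published procedure: start at
#' `A = B = C = 1`, `k = k1 = k2 = 1/30` per min, cap each local fit at
#' 10,000 objective evaluations, and initialize the switch time on a 5-min
#' grid (here spanning 5-60 min) because the optimum is sensitive to its
#' starting value.
#'
#' @param init Named starting values `A`, `B`, `C`, `k` (shared by `k1`,
#'   `k2`).
#' @param k_bounds Box bounds (1/min) on all decay constants.
#' @param t_switch_init Range (min) spanned by the switch-time starting
#'   grid.
#' @param t_switch_spacing Spacing (min) of the switch-time starting grid.
#' @param max_iter Iteration (objective evaluation) cap per local fit.
#' @param tol Relative convergence tolerance on the objective.
#' @return List of class `"fit_options"`.
#' @export
fit_options <- function(init = c(A = 1, B = 1, C = 1, k = 1 / 30),
                       k_bounds = c(1e-6, 10),
                       t_switch_init = c(5, 60),
                       t_switch_spacing = 5,
                       max_iter = 10000L,
                       tol = 1e-10) {
  stopifnot(all(c("A", "B", "C", "k") %in% names(init)),
            length(k_bounds) == 2L, k_bounds[1] > 0,
            k_bounds[1] < k_bounds[2],
            t_switch_spacing > 0, max_iter >= 100L, tol > 0)
  structure(list(init = init[c("A", "B", "C", "k")], k_bounds = k_bounds,
                 t_switch_init = t_switch_init,
                 t_switch_spacing = t_switch_spacing,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "fit_options")
}

#' Adjusted R-squared goodness of fit
#'
#' `1 - (sse / sstot) * (n - 1) / (n - p - 1)`, where `n` is the number of
#' time points and `p + 1` the number of fitted parameters.
#'
#' @param sse Residual sum of squares.
#' @param sstot Total sum of squares (> 0).
#' @param n Number of observations.
#' @param p Number of parameters minus one.
#' @return The adjusted R-squared (<= 1; can be negative).
#' @examples
#' adjusted_r2(sse = 0.2, sstot = 1, n = 12, p = 3) # 0.725
#' @export
adjusted_r2 <- function(sse, sstot, n, p) {
  if (sstot <= 0) stop("sstot must be positive")
  if (n - p - 1 <= 0) stop("need n - p - 1 > 0 residual degrees of freedom")
  1 - (sse / sstot) * (n - 1) / (n - p - 1)
}

#' mRNA half-life from a decay rate constant
#'
#' @param k Decay rate constant(s) (1/min, > 0).
#' @return Half-life `ln(2) / k` in minutes.
#' @examples
#' half_life(log(2) / 20) # 20
#' @export
half_life <- function(k) {
  if (any(!is.finite(k)) || any(k <= 0))
    stop("decay constants must be positive")
  log(2) / k
}

make_fit <- function(model, a_zero, par, sse, sstot, n, feval, converged,
                     extra = NULL) {
  p <- switch(model, constant = if (a_zero) 2L else 3L,
              switch = if (a_zero) 4L else 5L)
  diag <- list(sse = sse, sstot = sstot, n = n, p = p,
               adj_r2 = adjusted_r2(sse, sstot, n, p),
               converged = converged, n_iter = feval)
  structure(c(list(model = model, a_zero = a_zero, params = par,
                   diagnostics = diag), extra),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Kinetic fit: '%s' model%s\n", x$model,
              if (x$a_zero) " (A = 0 variant)" else ""))
  print(signif(x$params, 4))
  d <- x$diagnostics
  cat(sprintf("  SSE %.4g, adj R^2 %.4f (n = %d, p = %d), %s in %d evals\n",
              d$sse, d$adj_r2, d$n, d$p,
              if (d$converged) "converged" else "not converged", d$n_iter))
  invisible(x)
}

check_fittable <- function(pair) {
  if (!inherits(pair, "time_course_pair"))
    stop("expected a time_course_pair")
  if (!pair$complete)
    return("incomplete")
  sstot <- sum((pair$y - mean(pair$y))^2)
  if (sstot < 1e-12)
    return("degenerate")
  "ok"
}

#' Fit the constant-decay model to one gene
#'
#' Derivative-free local minimization of the residual sum of squares of the
#' constant model from the stated starting values, within bounds and the
#' iteration cap. With `a_zero = TRUE` the pure exponential variant
#' `B + C exp(-k t)` is fitted (one fewer free parameter).
#'
#' @param pair A [time_course_pair()] with complete data.
#' @param options A [fit_options()] object.
#' @param a_zero Fit the `A = 0` special case?
#' @return A `"kinetic_fit"` with elements `params` (A, B, C, k) and
#'   `diagnostics` (sse, sstot, n, p, adj_r2, converged, n_iter).
#' @export
fit_constant <- function(pair, options = fit_options(), a_zero = FALSE) {
  status <- check_fittable(pair)
  if (status != "ok")
    stop("cannot fit: profile is ", status,
         " (missing values or no variation in y)")
  r <- fit_constant_cpp(pair$time, pair$f, pair$y, a_zero,
                        as.numeric(options$init), options$k_bounds[1],
                        options$k_bounds[2], options$max_iter, options$tol)
  sstot <- sum((pair$y - mean(pair$y))^2)
  make_fit("constant", a_zero, r$par, r$sse, sstot, length(pair$y),
           r$feval, r$converged)
}

ts_init_grid <- function(options, t_max) {
  g <- seq(options$t_switch_init[1],
           min(options$t_switch_init[2], t_max - 1),
           by = options$t_switch_spacing)
  g[g > 0 & g < t_max]
}

#' Fit the switch-decay model to one gene
#'
#' For each switch-time starting value on the 5-min grid, runs the local
#' derivative-free optimizer over all free parameters
#' (A, B, C, k1, k2, t_switch) and keeps the fit with the smallest residual
#' sum of squares over all starts.
#'
#' @inheritParams fit_constant
#' @return A `"kinetic_fit"` with `params` (A, B, C, k1, k2, t_switch); the
#'   continuity constant is implicit (recomputed by [forward_switch()]).
#' @export
fit_switch <- function(pair, options = fit_options(), a_zero = FALSE) {
  status <- check_fittable(pair)
  if (status != "ok")
    stop("cannot fit: profile is ", status,
         " (missing values or no variation in y)")
  t_max <- max(pair$time)
  init <- c(as.numeric(options$init)[1:3], options$init[["k"]],
            options$init[["k"]])
  r <- fit_switch_cpp(pair$time, pair$f, pair$y, a_zero, init,
                      ts_init_grid(options, t_max), options$k_bounds[1],
                      options$k_bounds[2], 1e-2, t_max - 1e-2,
                      options$max_iter, options$tol)
  sstot <- sum((pair$y - mean(pair$y))^2)
  make_fit("switch", a_zero, r$par, r$sse, sstot, length(pair$y),
           r$feval, r$converged, extra = list(ts_init = r$ts_init))
}
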