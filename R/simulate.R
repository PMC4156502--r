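#' Simulate absolute mRNA abundance under first-order decay
#'
#' Integrates `dE/dt = R(t) - k(t) E` exactly from `E(0) = E0`, where `R(t)`
#' is the piecewise-linear rate profile defined by sampling `rate` at the
#' time grid, and the decay rate is either constant (`decay = c(k = ...)`)
#' or piecewise constant with an instantaneous switch
#' (`decay = c(k1 = ..., k2 = ..., t_switch = ...)`). Integration is exact
#' per linear segment (no stepper error), with the switch time inserted into
#' the integration grid.
#'
#' @param rate A function of time (e.g., from [impulse_rate()]) or a numeric
#'   vector of rate values at `time`.
#' @param decay Named numeric vector: `c(k=)` or `c(k1=, k2=, t_switch=)`,
#'   all rates in 1/min and positive.
#' @param E0 Initial absolute abundance (>= 0, arbitrary units).
#' @param time Sampling grid (min), strictly increasing from 0.
#' @return Numeric vector of abundances `E(t)` at `time` (always >= 0 for
#'   non-negative rates).
#' @examples
#' tt <- c(0, 5, 10, 20, 40)
#' simulate_abundance(function(t) rep(0, length(t)),
#'                    c(k = log(2) / 10), E0 = 100, time = tt)
#' @export
simulate_abundance <- function(rate, decay, E0, time) {
  check_time_grid(time)
  if (!is.numeric(E0) || length(E0) != 1L || E0 < 0)
    stop("E0 must be a single non-negative number")
  R <- if (is.function(rate)) rate(time) else as.numeric(rate)
  if (length(R) != length(time) || any(!is.finite(R)) || any(R < 0))
    stop("rate must give a finite non-negative value at every time point")
  nm <- names(decay)
  if (setequal(nm, "k")) {
    k <- decay[["k"]]
    if (k <= 0) stop("decay constant must be positive")
    E <- conv_decay_cpp(time, R, k, time) + E0 * exp(-k * time)
  } else if (setequal(nm, c("k1", "k2", "t_switch"))) {
    k1 <- decay[["k1"]]; k2 <- decay[["k2"]]; ts <- decay[["t_switch"]]
    if (k1 <= 0 || k2 <= 0) stop("decay constants must be positive")
    if (ts <= 0 || ts >= max(time))
      stop("t_switch must lie strictly inside the time-grid span")
    u <- sort(unique(c(time, ts)))
    Ru <- approx(time, R, xout = u)$y
    pre <- u <= ts
    E_pre <- conv_decay_cpp(u, Ru, k1, u[pre]) + E0 * exp(-k1 * u[pre])
    E_ts <- conv_decay_cpp(u, Ru, k1, ts) + E0 * exp(-k1 * ts)
    u2 <- u[u >= ts]
    # integrate the post-switch branch from t_switch with its own origin
    E_post <- conv_decay_cpp(u2 - ts, Ru[u >= ts], k2, u2 - ts) +
      E_ts * exp(-k2 * (u2 - ts))
    Eu <- numeric(length(u))
    Eu[pre] <- E_pre
    Eu[u >= ts] <- E_post
    E <- Eu[match(time, u)]
  } else {
    stop("decay must be c(k=) or c(k1=, k2=, t_switch=)")
  }
  pmax(E, 0)
}

#' Convert absolute profiles to relative log2 ratios
#'
#' Rescales each profile against the mean over all its time points (emulating
#' hybridization against a pooled-timepoint reference) and returns log2
#' ratios. The linearized output of every profile therefore has mean 1.
#'
#' @param x Positive numeric vector, or matrix with genes in rows.
#' @return Object of the same shape containing log2 ratios.
#' @examples
#' to_relative(c(1, 3)) # log2(1/2), log2(3/2)
#' @export
to_relative <- function(x) {
  if (is.matrix(x)) {
    if (any(!is.finite(x)) || any(x <= 0))
      stop("all values must be positive and finite")
    return(log2(x / rowMeans(x)))
  }
  if (any(!is.finite(x)) || any(x <= 0))
    stop("all values must be positive and finite")
  log2(x / mean(x))
}

#' Add multiplicative measurement noise on the log2 scale
#'
#' Adds i.i.d. Gaussian noise to a log2-ratio profile (equivalently,
#' log-normal multiplicative noise on the linear scale), the standard
#' error model for two-color array ratios.
#'
#' @param x Numeric vector or matrix of log2 ratios.
#' @param sd Noise standard deviation in log2 units (>= 0; 0 returns `x`).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return `x` plus noise.
#' @export
add_measurement_noise <- function(x, sd, seed = NULL) {
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0)
    stop("sd must be a single non-negative number")
  if (sd == 0) return(x)
  with_seed(seed, function() x + rnorm(length(x), mean = 0, sd = sd))
}

#' Simulation configuration for synthetic cohorts
#'
#' Collects the stated world of the generator: cohort size, mixture of
#' kinetic classes, sampling grid, measurement noise, and parameter ranges.
#' Defaults emulate a stress-response time course: 12 samples over 120 min,
#' impulse-shaped transcription programs, baseline mRNA half-lives of
#' 10-60 min, and multiplicative log2 noise of sd 0.1 on both measured
#' channels.
#'
#' @param n_genes Number of genes to simulate.
#' @param class_proportions Fractions (summing to 1) over the classes
#'   `constant`, `exp_approach`, `switch_stab`, `switch_destab`.
#' @param time Sampling grid (min), strictly increasing from 0.
#' @param noise_sd_log2 Measurement noise sd (log2 units) applied
#'   independently to the rate and expression channels.
#' @param seed Integer seed for reproducibility.
#' @param half_life Range (min) for the baseline decay half-life.
#' @param amplitude_log2 Range of |log2 fold change| of the impulse plateau
#'   `h1` relative to baseline (sign drawn at random).
#' @param t1,t2 Ranges (min) of the impulse onset and recovery midpoints.
#' @param beta Range (1/min) of the impulse steepness.
#' @param recovery_log2 Range of the recovery plateau `h2` as log2 offset
#'   from baseline (drawn symmetrically around 0).
#' @param switch_ratio_log2 Range of |log2(k2/k1)| for switch-class genes
#'   (sign fixed by the class: stabilized k2 < k1, destabilized k2 > k1).
#' @param t_switch Range (min) for the true switch time.
#' @param t_switch_values Optional discrete set of switch times sampled
#'   uniformly instead of the `t_switch` range.
#' @param exp_half_life Range (min) of the *post-shift* half-life for
#'   exponential-approach genes (fast, so the new steady state is reached
#'   within the course).
#' @param exp_shift_log2 Range of |log2(k_F/k_I)| for exponential-approach
#'   genes (sign random).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 200,
                       class_proportions = c(constant = 0.5,
                                             exp_approach = 0.2,
                                             switch_stab = 0.15,
                                             switch_destab = 0.15),
                       time = c(0, 5, 10, 16, 25, 33, 41, 48, 60, 80, 100, 120),
                       noise_sd_log2 = 0.1,
                       seed = 1L,
                       half_life = c(10, 60),
                       amplitude_log2 = c(1, 3),
                       t1 = c(2, 10),
                       t2 = c(30, 80),
                       beta = c(0.2, 1),
                       recovery_log2 = c(-0.5, 0.5),
                       switch_ratio_log2 = c(1, 2),
                       t_switch = c(15, 55),
                       t_switch_values = NULL,
                       exp_half_life = c(5, 15),
                       exp_shift_log2 = c(0.7, 1.6)) {
  check_time_grid(time)
  cls <- c("constant", "exp_approach", "switch_stab", "switch_destab")
  if (is.null(names(class_proportions)))
    names(class_proportions) <- cls
  if (!setequal(names(class_proportions), cls))
    stop("class_proportions must be named over the four kinetic classes")
  class_proportions <- class_proportions[cls]
  if (any(class_proportions < 0) || any(class_proportions > 1) ||
      abs(sum(class_proportions) - 1) > 1e-8)
    stop("class_proportions must lie in [0, 1] and sum to 1")
  if (n_genes < 1) stop("n_genes must be at least 1")
  if (noise_sd_log2 < 0) stop("noise_sd_log2 must be non-negative")
  structure(list(n_genes = as.integer(n_genes),
                 class_proportions = class_proportions,
                 time = time, noise_sd_log2 = noise_sd_log2,
                 seed = seed, half_life = half_life,
                 amplitude_log2 = amplitude_log2, t1 = t1, t2 = t2,
                 beta = beta, recovery_log2 = recovery_log2,
                 switch_ratio_log2 = switch_ratio_log2,
                 t_switch = t_switch, t_switch_values = t_switch_values,
                 exp_half_life = exp_half_life,
                 exp_shift_log2 = exp_shift_log2),
            class = "sim_config")
}

# integer class counts by largest-remainder rounding
largest_remainder <- function(n, p) {
  raw <- n * p
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    frac <- raw - counts
    add <- order(frac, decreasing = TRUE)[seq_len(left)]
    counts[add] <- counts[add] + 1
  }
  as.integer(counts)
}

runif1 <- function(range) runif(1, range[1], range[2])

#' Simulate a cohort of paired transcription/expression time courses
#'
#' Generates `n_genes` paired relative profiles with known kinetic ground
#' truth. Four classes are emulated: `constant` (impulse-driven
#' transcription, fixed decay), `exp_approach` (flat transcription with an
#' instantaneous decay-rate change at t = 0, giving an exponential approach
#' to a new steady state), and `switch_stab` / `switch_destab`
#' (impulse-driven transcription with a piecewise decay-rate switch at
#' `t_switch`). Absolute abundances are integrated exactly over the
#' piecewise-linear rate program (see [simulate_abundance()]), rescaled
#' against the pooled-timepoint mean ([to_relative()]), and perturbed with
#' independent multiplicative noise on both channels.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"stress_cohort"` with elements `f` and `y`
#'   (gene-by-time matrices of log2 ratios), `time`, `truth` (one row per
#'   gene: class, decay constants, switch time, impulse parameters), and
#'   `config`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_genes = 10, seed = 42))
#' coh
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, function() simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_genes
  time <- cfg$time
  counts <- largest_remainder(n, cfg$class_proportions)
  classes <- rep(names(cfg$class_proportions), counts)
  ids <- sprintf("g%04d", seq_len(n))
  Tn <- length(time)
  f_log2 <- matrix(NA_real_, n, Tn, dimnames = list(ids, paste0("t", time)))
  y_log2 <- f_log2
  truth <- data.frame(gene_id = ids, class = classes,
                      k = NA_real_, k1 = NA_real_, k2 = NA_real_,
                      t_switch = NA_real_,
                      h0 = NA_real_, h1 = NA_real_, h2 = NA_real_,
                      t1 = NA_real_, t2 = NA_real_, beta = NA_real_,
                      E0 = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    cls <- classes[i]
    if (cls == "exp_approach") {
      k_post <- log(2) / runif1(cfg$exp_half_life)
      shift <- runif1(cfg$exp_shift_log2) * sample(c(-1, 1), 1)
      k_pre <- k_post / 2^shift  # shift = log2(k_F / k_I)
      R_level <- 1
      E0 <- R_level / k_pre    # pre-stress steady state
      E <- simulate_abundance(rep(R_level, Tn), c(k = k_post), E0, time)
      R <- rep(R_level, Tn)
      truth$k[i] <- k_post
      truth$k1[i] <- k_pre
      truth$k2[i] <- k_post
      truth$E0[i] <- E0
    } else {
      h0 <- 1
      amp <- runif1(cfg$amplitude_log2) * sample(c(-1, 1), 1)
      h1 <- h0 * 2^amp
      h2 <- h0 * 2^runif1(cfg$recovery_log2)
      tt1 <- runif1(cfg$t1)
      tt2 <- runif1(cfg$t2)
      bb <- runif1(cfg$beta)
      imp <- impulse_rate(h0, h1, h2, tt1, tt2, bb)
      R <- imp(time)
      k1 <- log(2) / runif1(cfg$half_life)
      E0 <- R[1] / k1
      if (cls == "constant") {
        E <- simulate_abundance(R, c(k = k1), E0, time)
        truth$k[i] <- k1
      } else {
        ratio <- 2^runif1(cfg$switch_ratio_log2)
        k2 <- if (cls == "switch_stab") k1 / ratio else k1 * ratio
        ts <- if (is.null(cfg$t_switch_values)) runif1(cfg$t_switch)
              else cfg$t_switch_values[sample.int(length(cfg$t_switch_values), 1)]
        E <- simulate_abundance(R, c(k1 = k1, k2 = k2, t_switch = ts),
                                E0, time)
        truth$k1[i] <- k1
        truth$k2[i] <- k2
        truth$t_switch[i] <- ts
      }
      truth[i, c("h0", "h1", "h2", "t1", "t2", "beta")] <-
        c(h0, h1, h2, tt1, tt2, bb)
      truth$E0[i] <- E0
    }
    f_log2[i, ] <- to_relative(R)
    y_log2[i, ] <- to_relative(E)
  }
  if (cfg$noise_sd_log2 > 0) {
    f_log2 <- f_log2 + matrix(rnorm(n * Tn, 0, cfg$noise_sd_log2), n, Tn)
    y_log2 <- y_log2 + matrix(rnorm(n * Tn, 0, cfg$noise_sd_log2), n, Tn)
  }
  structure(list(f = f_log2, y = y_log2, time = time, truth = truth,
                 config = cfg),
            class = "stress_cohort")
}

#' @export
print.stress_cohort <- function(x, ...) {
  cat(sprintf("Synthetic stress-response cohort: %d genes x %d time points (0-%g min)\n",
              nrow(x$f), length(x$time), max(x$time)))
  print(table(x$truth$class))
  cat(sprintf("measurement noise sd (log2): %g; seed: %s\n",
              x$config$noise_sd_log2, format(x$config$seed)))
  invisible(x)
}

#' Randomize the pairing between transcription and expression profiles
#'
#' Permutes the transcription-rate profiles across genes while leaving the
#' expression profiles untouched. Used as a negative control: the kinetic
#' models should explain matched pairs markedly better than shuffled ones.
#'
#' @param cohort A `"stress_cohort"` object (or any list with matrices `f`
#'   and `y` with matching rows).
#' @param seed Optional integer seed for the permutation.
#' @param permutation Optional explicit permutation of `1:n_genes`
#'   (overrides `seed`).
#' @return The cohort with `f` rows permuted; element `shuffle` records the
#'   permutation and the self-pairing rate (fraction of genes keeping their
#'   own rate profile; a derangement is not enforced).
#' @export
shuffle_pairing <- function(cohort, seed = NULL, permutation = NULL) {
  n <- nrow(cohort$f)
  if (is.null(n) || n < 2L)
    stop("shuffle_pairing needs a cohort of at least 2 genes")
  if (is.null(permutation)) {
    permutation <- with_seed(seed, function() sample.int(n))
  } else {
    if (length(permutation) != n || !setequal(permutation, seq_len(n)))
      stop("permutation must be a permutation of 1:n_genes")
  }
  ids <- rownames(cohort$f)
  newf <- cohort$f[permutation, , drop = FALSE]
  rownames(newf) <- ids
  cohort$f <- newf
  cohort$shuffle <- list(permutation = permutation,
                         self_pair_rate = mean(permutation == seq_len(n)))
  cohort
}
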