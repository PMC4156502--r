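# shared fixtures and independent oracles for the kinetic models

default_grid <- c(0, 5, 10, 16, 25, 33, 41, 48, 60, 80, 100, 120)

# generic fixed-step RK4 integration of dy/dt = A f(t) + B k1 - k(t) y,
# the ODE behind both kinetic models (k(t) switches from k1 to k2 at
# t_switch when one is given). Independent of the closed-form code path:
# segments are split at interpolation kinks and at the switch so the decay
# constant is chosen per segment, never by comparing drifting step times.
rk4_oracle <- function(pars, f, tt, h = 0.02) {
  fi <- approxfun(tt, f, rule = 2)
  A <- pars[["A"]]; B <- pars[["B"]]; C <- pars[["C"]]
  k1 <- pars[["k1"]]; k2 <- pars[["k2"]]
  ts <- if ("t_switch" %in% names(pars)) pars[["t_switch"]] else NA_real_
  y <- B + C
  out <- numeric(length(tt)); out[1] <- y; j <- 2
  brk <- sort(unique(c(tt, ts[!is.na(ts)])))
  for (seg in seq_len(length(brk) - 1)) {
    a0 <- brk[seg]; b0 <- brk[seg + 1]
    kseg <- if (is.na(ts) || b0 <= ts) k1 else k2
    deriv <- function(t, y) A * fi(t) + B * k1 - kseg * y
    n <- ceiling((b0 - a0) / h); hh <- (b0 - a0) / n
    for (s in seq_len(n)) {
      t0 <- a0 + (s - 1) * hh
      ka <- deriv(t0, y)
      kb <- deriv(t0 + hh / 2, y + hh / 2 * ka)
      kc <- deriv(t0 + hh / 2, y + hh / 2 * kb)
      kd <- deriv(t0 + hh, y + hh * kc)
      y <- y + hh / 6 * (ka + 2 * kb + 2 * kc + kd)
    }
    if (b0 %in% tt) { out[j] <- y; j <- j + 1 }
  }
  out
}

# exhaustive hypergeometric upper-tail probability by direct enumeration of
# all possible overlap counts (combinatorial identity, no phyper)
hyper_tail_oracle <- function(q, N, m, n_cl) {
  i <- q:min(m, n_cl)
  sum(choose(m, i) * choose(N - m, n_cl - i)) / choose(N, n_cl)
}

# noise-free pair with constant-model kinetics generated straight from the
# model equation (not via the cohort generator)
make_constant_pair <- function(pars = c(A = 1, B = 0.5, C = 0.2, k = 0.05),
                               tt = default_grid,
                               impulse = impulse_rate(1, 4, 1.2, 6, 45, 0.5),
                               gene_id = "gene") {
  f <- impulse(tt)
  y <- forward_constant(pars, f, tt)
  time_course_pair(tt, f, y, gene_id = gene_id)
}

make_switch_pair <- function(pars = c(A = 0.05, B = 0.2, C = 0.8, k1 = 0.02,
                                      k2 = 0.06, t_switch = 30),
                             tt = default_grid,
                             impulse = impulse_rate(1, 4, 1.2, 6, 45, 0.5),
                             gene_id = "gene") {
  f <- impulse(tt)
  y <- forward_switch(pars, f, tt)
  time_course_pair(tt, f, y, gene_id = gene_id)
}

# hand-built kinetic_fit stand-ins for exercising the selection rules
fake_fit <- function(model, adj_r2, a_zero = FALSE, k = 1 / 30, k1 = 0.02,
                     k2 = 0.04, t_switch = 30) {
  params <- if (model == "constant") {
    c(A = if (a_zero) 0 else 1, B = 0, C = 1, k = k)
  } else {
    c(A = if (a_zero) 0 else 1, B = 0, C = 1, k1 = k1, k2 = k2,
      t_switch = t_switch)
  }
  structure(list(model = model, a_zero = a_zero, params = params,
                 diagnostics = list(adj_r2 = adj_r2, converged = TRUE)),
            class = "kinetic_fit")
}
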