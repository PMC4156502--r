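test_that("rate interpolation is exact and bounded", {
  expect_equal(interp_rate(c(1, 3), c(0, 10), 5), 2)
  expect_equal(interp_rate(c(1, 3, 2), c(0, 10, 20), c(0, 10, 20)),
               c(1, 3, 2))
  expect_equal(interp_rate(rep(4, 3), c(0, 10, 20), c(3, 17)), c(4, 4))
  expect_error(interp_rate(c(1, 3), c(0, 10), 11), "span")
})

test_that("decay convolution matches closed forms", {
  tt <- c(0, 5, 10)
  expect_equal(convolve_decay(rep(0, 3), tt, 0.2, c(3, 10)), c(0, 0))
  expect_equal(convolve_decay(rep(1, 3), tt, 0.1, 10),
               (1 - exp(-1)) / 0.1, tolerance = 1e-10)
  expect_equal(convolve_decay(c(2, 1, 3), tt, 0.3, 0), 0)
  expect_error(convolve_decay(rep(1, 3), tt, -0.1, 5), "positive")
  expect_error(convolve_decay(rep(1, 3), tt, 0.1, 12), "span")
})

test_that("closed-form and quadrature evaluators are interchangeable", {
  tt <- default_grid
  set.seed(6)
  worst <- 0
  for (r in 1:40) {
    f <- 2^runif(length(tt), -2, 2)
    k <- exp(runif(1, log(1e-3), log(0.5)))
    tq <- runif(3, 0, 120)
    worst <- max(worst, max(abs(
      convolve_decay(f, tt, k, tq) -
        convolve_decay(f, tt, k, tq, method = "quadrature"))))
  }
  expect_lt(worst, 1e-6)
})

test_that("constant-model forward evaluation", {
  tt <- default_grid
  # steady state: production A f balancing decay with C = A/k stays flat
  k <- 0.05
  expect_equal(forward_constant(c(A = k, B = 0, C = 1, k = k),
                                rep(1, length(tt)), tt),
               rep(1, length(tt)), tolerance = 1e-12)
  # pure exponential approach at one half-life
  expect_equal(forward_constant(c(A = 0, B = 2, C = -1, k = log(2) / 10),
                                rep(1, length(tt)), tt, t = 10), 1.5)
  # A = 1, B = C = 0 reduces to the convolution itself
  expect_equal(forward_constant(c(A = 1, B = 0, C = 0, k = 0.1),
                                rep(1, length(tt)), tt, t = 10),
               (1 - exp(-1)) / 0.1, tolerance = 1e-10)
  expect_error(forward_constant(c(A = -1, B = 0, C = 0, k = 0.1),
                                rep(1, length(tt)), tt), "non-negative")
})

test_that("switch-model forward evaluation", {
  tt <- default_grid
  imp <- impulse_rate(1, 3, 1.2, 6, 50, 0.4)
  f <- imp(tt)
  # degenerate switch equals the constant model
  expect_equal(forward_switch(c(A = 0.1, B = 0.3, C = 0.7, k1 = 0.04,
                                k2 = 0.04, t_switch = 30), f, tt),
               forward_constant(c(A = 0.1, B = 0.3, C = 0.7, k = 0.04),
                                f, tt), tolerance = 1e-12)
  # continuity at the switch, by construction of G
  set.seed(8)
  for (r in 1:20) {
    pars <- c(A = runif(1, 0, 0.3), B = runif(1, -0.5, 1),
              C = runif(1, -0.5, 1.5),
              k1 = exp(runif(1, log(0.005), log(0.3))),
              k2 = exp(runif(1, log(0.005), log(0.3))),
              t_switch = runif(1, 5, 110))
    eps <- 1e-9
    lr <- forward_switch(pars, f, tt,
                         t = pars[["t_switch"]] + c(-eps, eps))
    expect_lt(abs(diff(lr)), 1e-8)
  }
  # independent ODE-integrator oracle
  set.seed(9)
  for (r in 1:5) {
    fr <- 2^runif(length(tt), -2, 2)
    pars <- c(A = runif(1, 0, 0.2), B = runif(1, -0.5, 1),
              C = runif(1, -0.5, 1.5),
              k1 = exp(runif(1, log(0.005), log(0.3))),
              k2 = exp(runif(1, log(0.005), log(0.3))),
              t_switch = runif(1, 10, 70))
    expect_equal(forward_switch(pars, fr, tt), rk4_oracle(pars, fr, tt),
                 tolerance = 1e-6)
  }
  expect_error(forward_switch(c(A = 1, B = 0, C = 0, k1 = 0.1, k2 = 0.2,
                                t_switch = 130), f, tt), "t_switch")
})
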