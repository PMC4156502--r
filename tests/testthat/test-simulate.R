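test_that("abundance simulation solves the kinetic equation", {
  tt <- default_grid
  # production balancing decay holds the steady state
  k <- 0.04
  E <- simulate_abundance(rep(k * 100, length(tt)), c(k = k), E0 = 100,
                          time = tt)
  expect_equal(E, rep(100, length(tt)))

  # no production: one half-life halves the pool
  E <- simulate_abundance(rep(0, 5), c(k = log(2) / 10), E0 = 100,
                          time = c(0, 2, 5, 10, 20))
  expect_equal(E[4], 50)

  # constant production from a displaced start: closed-form relaxation
  E <- simulate_abundance(rep(2, length(tt)), c(k = 0.1), E0 = 10, time = tt)
  expect_equal(E, 20 - 10 * exp(-0.1 * tt), tolerance = 1e-10)

  # piecewise decay agrees with the RK4 oracle
  imp <- impulse_rate(1, 4, 1.5, 6, 45, 0.5)
  R <- imp(tt)
  E <- simulate_abundance(R, c(k1 = 0.02, k2 = 0.06, t_switch = 30),
                          E0 = R[1] / 0.02, time = tt)
  oracle <- rk4_oracle(c(A = 1, B = 0, C = R[1] / 0.02, k1 = 0.02,
                         k2 = 0.06, t_switch = 30), R, tt)
  expect_equal(E, oracle, tolerance = 1e-7)

  expect_error(simulate_abundance(rep(1, 3), c(k = -1), 1, c(0, 5, 10)),
               "positive")
  expect_error(simulate_abundance(rep(1, 3), c(k1 = 1, k2 = 1,
                                               t_switch = 99), 1,
                                  c(0, 5, 10)), "t_switch")
})

test_that("relative rescaling against the pooled mean", {
  expect_equal(to_relative(rep(5, 8)), rep(0, 8))
  expect_equal(to_relative(c(1, 3)), log2(c(1 / 2, 3 / 2)))
  # normalization identity: the linearized profile has mean 1
  set.seed(1)
  for (i in 1:5) {
    x <- exp(rnorm(12))
    expect_equal(mean(2^to_relative(x)), 1)
  }
  m <- matrix(c(1, 3, 2, 2), nrow = 2, byrow = TRUE)
  expect_equal(to_relative(m)[1, ], log2(c(1 / 2, 3 / 2)),
               ignore_attr = TRUE)
  expect_error(to_relative(c(1, 0, 2)), "positive")
})

test_that("measurement noise is calibrated and reproducible", {
  x <- rep(0, 10000)
  expect_identical(add_measurement_noise(x, 0), x)
  out <- add_measurement_noise(x, 0.1, seed = 7)
  expect_equal(sd(out - x), 0.1, tolerance = 0.05)
  expect_identical(out, add_measurement_noise(x, 0.1, seed = 7))
  expect_false(identical(out, add_measurement_noise(x, 0.1, seed = 8)))
  expect_error(add_measurement_noise(x, -0.1), "non-negative")
})

test_that("pairing shuffle permutes rate profiles only", {
  coh <- simulate_cohort(sim_config(n_genes = 6, seed = 3))
  sh <- shuffle_pairing(coh, permutation = c(2, 1, 4, 3, 6, 5))
  expect_identical(sh$y, coh$y)
  expect_identical(unname(sh$f[1, ]), unname(coh$f[2, ]))
  expect_equal(sh$shuffle$self_pair_rate, 0)
  # multiset of rate profiles preserved under a seeded shuffle
  sh2 <- shuffle_pairing(coh, seed = 9)
  expect_equal(sort(as.vector(sh2$f)), sort(as.vector(coh$f)))
  one <- list(f = coh$f[1, , drop = FALSE], y = coh$y[1, , drop = FALSE])
  expect_error(shuffle_pairing(one), "at least 2")
})

test_that("cohort generation respects the configured mixture and seed", {
  cfg <- sim_config(n_genes = 100,
                    class_proportions = c(constant = 1, exp_approach = 0,
                                          switch_stab = 0,
                                          switch_destab = 0),
                    seed = 5)
  coh <- simulate_cohort(cfg)
  expect_equal(unname(table(coh$truth$class)[["constant"]]), 100)

  cfg2 <- sim_config(n_genes = 200,
                     class_proportions = c(constant = 0.5,
                                           exp_approach = 0.2,
                                           switch_stab = 0.15,
                                           switch_destab = 0.15),
                     seed = 1)
  a <- simulate_cohort(cfg2)
  b <- simulate_cohort(cfg2)
  expect_identical(a, b)
  counts <- table(a$truth$class)
  expect_equal(unname(counts[c("constant", "exp_approach", "switch_stab",
                               "switch_destab")]),
               c(100L, 40L, 30L, 30L), ignore_attr = TRUE)
  expect_error(sim_config(class_proportions = c(constant = 0.9,
                                                exp_approach = 0.9,
                                                switch_stab = 0,
                                                switch_destab = 0)),
               "sum to 1")
})

test_that("noise-free cohorts reproduce the forward kinetic models", {
  # every generated gene must match the fitting model evaluated with the
  # parameters implied by the ground truth, after relative rescaling
  cfg <- sim_config(n_genes = 20, noise_sd_log2 = 0, seed = 17)
  coh <- simulate_cohort(cfg)
  tt <- coh$time
  worst <- 0
  for (i in seq_len(nrow(coh$f))) {
    tr <- coh$truth[i, ]
    if (tr$class == "exp_approach") {
      R <- rep(1, length(tt))
      E <- simulate_abundance(R, c(k = tr$k), tr$E0, tt)
      pars <- c(A = 0, B = (1 / tr$k) / mean(E),
                C = (tr$E0 - 1 / tr$k) / mean(E), k = tr$k)
      yhat <- forward_constant(pars, R / mean(R), tt)
    } else {
      imp <- impulse_rate(tr$h0, tr$h1, tr$h2, tr$t1, tr$t2, tr$beta)
      R <- imp(tt)
      if (tr$class == "constant") {
        E <- simulate_abundance(R, c(k = tr$k), tr$E0, tt)
        pars <- c(A = mean(R) / mean(E), B = 0, C = tr$E0 / mean(E),
                  k = tr$k)
        yhat <- forward_constant(pars, R / mean(R), tt)
      } else {
        E <- simulate_abundance(R, c(k1 = tr$k1, k2 = tr$k2,
                                     t_switch = tr$t_switch), tr$E0, tt)
        pars <- c(A = mean(R) / mean(E), B = 0, C = tr$E0 / mean(E),
                  k1 = tr$k1, k2 = tr$k2, t_switch = tr$t_switch)
        yhat <- forward_switch(pars, R / mean(R), tt)
      }
    }
    expect_equal(2^coh$f[i, ], R / mean(R), tolerance = 1e-12,
                 ignore_attr = TRUE)
    worst <- max(worst, max(abs(coh$y[i, ] - log2(yhat))))
  }
  expect_lt(worst, 1e-8)
})

test_that("exponential-approach genes reach the new steady state", {
  cfg <- sim_config(n_genes = 30, noise_sd_log2 = 0, seed = 23,
                    class_proportions = c(constant = 0, exp_approach = 1,
                                          switch_stab = 0,
                                          switch_destab = 0))
  coh <- simulate_cohort(cfg)
  tt <- coh$time
  for (i in seq_len(nrow(coh$y))) {
    tr <- coh$truth[i, ]
    EF <- 1 / tr$k # R = 1, post-shift decay k
    E_last <- 2^coh$y[i, length(tt)] *
      mean(simulate_abundance(rep(1, length(tt)), c(k = tr$k), tr$E0, tt))
    bound <- abs(tr$E0 - EF) * exp(-tr$k * max(tt))
    expect_lt(abs(E_last - EF), bound + 1e-9)
  }
})
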