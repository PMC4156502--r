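test_that("five-criteria selection assigns switch, constant, and poor fit", {
  crit <- selection_criteria()
  base <- function(adjc, adjc0 = adjc - 0.2, adjs, adjs0 = adjs - 0.2,
                   k1 = 0.02, k2 = 0.04, ts = 30) {
    list(constant = fake_fit("constant", adjc),
         constant_a0 = fake_fit("constant", adjc0, a_zero = TRUE),
         switch = fake_fit("switch", adjs, k1 = k1, k2 = k2, t_switch = ts),
         switch_a0 = fake_fit("switch", adjs0, a_zero = TRUE, k1 = k1,
                              k2 = k2, t_switch = ts))
  }
  # all five criteria met
  a <- select_model(base(adjc = 0.50, adjs = 0.70, k1 = 0.02, k2 = 0.04),
                    crit)
  expect_equal(a$assigned, "switch")
  expect_false(a$used_a_zero)
  expect_equal(a$decay_shift, "destabilized")
  # blocked by a near-perfect constant fit
  expect_equal(select_model(base(adjc = 0.95, adjs = 0.80), crit)$assigned,
               "constant")
  # neither model fits
  expect_equal(select_model(base(adjc = 0.40, adjs = 0.50), crit)$assigned,
               "poor_fit")
  # decay-rate change too small
  expect_equal(select_model(base(adjc = 0.65, adjs = 0.70, k1 = 0.02,
                                 k2 = 0.024), crit)$assigned, "constant")
  # switch time outside the window
  expect_equal(select_model(base(adjc = 0.65, adjs = 0.70, ts = 80),
                            crit)$assigned, "constant")
  # A = 0 switch variant rescues a failed full switch fit
  fits <- base(adjc = 0.5, adjs = 0.45, adjs0 = 0.75)
  a <- select_model(fits, crit)
  expect_equal(a$assigned, "switch")
  expect_true(a$used_a_zero)
  # exact tie goes to the constant model (parsimony)
  expect_equal(select_model(base(adjc = 0.70, adjc0 = 0.3, adjs = 0.70),
                            crit)$assigned, "constant")
  expect_error(select_model(fits[1:2], crit), "must contain")
})

test_that("stabilization direction follows the decay constants", {
  crit <- selection_criteria()
  fits <- list(constant = fake_fit("constant", 0.5),
               constant_a0 = fake_fit("constant", 0.3, a_zero = TRUE),
               switch = fake_fit("switch", 0.8, k1 = 0.06, k2 = 0.02),
               switch_a0 = fake_fit("switch", 0.4, a_zero = TRUE))
  a <- select_model(fits, crit)
  expect_equal(a$assigned, "switch")
  expect_equal(a$decay_shift, "stabilized")
  expect_equal(unname(a$half_lives), log(2) / c(0.06, 0.02))
})

test_that("exponential-approach flag needs the A = 0 fit to win", {
  expect_true(flag_exponential_approach(fake_fit("constant", 0.88),
                                        fake_fit("constant", 0.92,
                                                 a_zero = TRUE)))
  expect_false(flag_exponential_approach(fake_fit("constant", 0.95),
                                         fake_fit("constant", 0.70,
                                                  a_zero = TRUE)))
  # quality floor applies regardless of the comparison
  expect_false(flag_exponential_approach(fake_fit("constant", 0.40),
                                         fake_fit("constant", 0.55,
                                                  a_zero = TRUE)))
})

test_that("steady-state decay-shift inference", {
  expect_equal(infer_decay_shift(1, 0.5, 1, 0.5)$label, "none")
  expect_equal(infer_decay_shift(1, 0.5, 1, 0.5)$ratio, 1)
  r <- infer_decay_shift(1, 0.25, 1, 0.5)
  expect_equal(r$ratio, 0.5)
  expect_equal(r$label, "destabilized")
  r <- infer_decay_shift(1, 2, 1, 1)
  expect_equal(r$ratio, 2)
  expect_equal(r$label, "stabilized")
  expect_error(infer_decay_shift(0, 1, 1, 1), "positive")
})
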