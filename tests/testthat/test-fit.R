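test_that("adjusted R-squared follows the printed formula", {
  expect_equal(adjusted_r2(0.2, 1, 12, 3), 1 - 0.2 * 11 / 8)
  expect_equal(adjusted_r2(0.25, 1, 12, 5), 1 - 0.25 * 11 / 6)
  expect_equal(adjusted_r2(0, 1, 12, 5), 1)
  # monotone decreasing in sse and in p at fixed sse
  sses <- seq(0, 1, by = 0.1)
  vals <- vapply(sses, adjusted_r2, numeric(1), sstot = 2, n = 12, p = 3)
  expect_true(all(diff(vals) < 0))
  byp <- vapply(2:5, function(p) adjusted_r2(0.3, 1, 12, p), numeric(1))
  expect_true(all(diff(byp) < 0))
  expect_error(adjusted_r2(0.1, 0, 12, 3), "positive")
  expect_error(adjusted_r2(0.1, 1, 12, 11), "degrees of freedom")
})

test_that("half-life conversion", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(half_life(1 / 30), log(2) * 30)
  expect_equal(half_life(log(2) / 20), 20)
  expect_error(half_life(0), "positive")
})

test_that("constant-model fitting recovers noise-free kinetics", {
  pair <- make_constant_pair(c(A = 1, B = 0.5, C = 0.2, k = 0.05))
  fit <- fit_constant(pair)
  expect_equal(fit$params[["k"]], 0.05, tolerance = 0.01)
  expect_gt(fit$diagnostics$adj_r2, 0.999)
  expect_lt(fit$diagnostics$sse, 1e-6)
  expect_equal(fit$diagnostics$p, 3)
  # A = 0 variant has one fewer parameter
  expect_equal(fit_constant(pair, a_zero = TRUE)$diagnostics$p, 2)
})

test_that("degenerate profiles are rejected as uninformative", {
  tt <- default_grid
  flat <- time_course_pair(tt, rep(1, length(tt)), rep(2, length(tt)))
  expect_error(fit_constant(flat), "degenerate")
  fit <- decay_fit(flat)
  expect_equal(fit$assignment$assigned, "uninformative")
  withna <- suppressWarnings(
    time_course_pair(tt, rep(1, length(tt)),
                     c(NA, 2^rnorm(length(tt) - 1))))
  expect_false(withna$complete)
  expect_equal(decay_fit(withna)$assignment$assigned, "uninformative")
})

test_that("switch-model fitting recovers the decay change", {
  pair <- make_switch_pair(c(A = 0.05, B = 0.2, C = 0.8, k1 = 0.02,
                             k2 = 0.06, t_switch = 30))
  fit <- fit_switch(pair)
  expect_equal(fit$params[["t_switch"]], 30, tolerance = 2.5 / 30)
  expect_equal(fit$params[["k2"]] / fit$params[["k1"]], 3, tolerance = 0.1)
  expect_equal(fit$diagnostics$p, 5)
  # determinism: identical inputs give identical fits
  fit2 <- fit_switch(pair)
  expect_identical(fit$params, fit2$params)
})

test_that("the switch model nests the constant model", {
  # on any data the best switch SSE cannot exceed the best constant SSE
  set.seed(12)
  tt <- default_grid
  for (r in 1:4) {
    f <- 2^(rnorm(length(tt), 0, 0.8))
    y <- 2^(rnorm(length(tt), 0, 0.8))
    pair <- time_course_pair(tt, f, y)
    sc <- fit_constant(pair)$diagnostics$sse
    ss <- fit_switch(pair)$diagnostics$sse
    expect_lte(ss, sc + 1e-6)
  }
})

test_that("cohort-level fitting tabulates assignments", {
  coh <- simulate_cohort(sim_config(n_genes = 12, seed = 33))
  tab <- fit_decay_models(coh)
  expect_s3_class(tab, "decay_fit_table")
  expect_equal(nrow(tab), 12)
  expect_true(all(c("gene_id", "assigned", "adj_r2_const", "t_switch",
                    "half_life_pre", "decay_shift") %in% names(tab)))
  expect_true(all(tab$assigned %in%
                    c("switch", "constant", "poor_fit", "uninformative")))
  # a missing value marks the gene uninformative, others unaffected
  coh$y[3, 5] <- NA
  tab2 <- fit_decay_models(coh)
  expect_equal(tab2$assigned[3], "uninformative")
  expect_equal(tab2$assigned[-3], tab$assigned[-3])
})
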