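test_that("maximum fold change", {
  expect_equal(max_fold_change(c(1, 2, 4, 2)), 4)
  expect_equal(max_fold_change(rep(3, 5)), 1)
  expect_equal(max_fold_change(c(1, NA, 5)), 5)
  expect_error(max_fold_change(c(2, NA, NA)), "at least 2")
  expect_error(max_fold_change(c(1, -2)), "positive")
  # invariance under time permutation and positive scaling; always >= 1
  set.seed(4)
  for (r in 1:10) {
    x <- 2^rnorm(12)
    m <- max_fold_change(x)
    expect_gte(m, 1)
    expect_equal(max_fold_change(sample(x)), m)
    expect_equal(max_fold_change(x * runif(1, 0.1, 10)), m)
  }
})

test_that("profile correlation on the log2 scale", {
  x <- rnorm(12)
  expect_equal(profile_correlation(x, x), 1)
  expect_equal(profile_correlation(x, -x), -1)
  expect_equal(profile_correlation(0:11, 2 * (0:11) + 3), 1)
  expect_true(is.na(profile_correlation(rep(1, 12), x)))
  expect_error(profile_correlation(x, x[-1]), "equal length")
})

test_that("response timing picks out the most variable interval", {
  tt <- c(0, 5, 10, 20)
  # all regulation happens across the first interval
  set.seed(2)
  f <- cbind(rnorm(30, 0, 0.01), rnorm(30, 0, 2), rnorm(30, 0, 2) / 2,
             rnorm(30, 0, 0.01))
  f[, 3] <- f[, 2] + rnorm(30, 0, 0.05)
  f[, 4] <- f[, 3] + rnorm(30, 0, 0.05)
  tv <- transition_variance(f, tt)
  expect_equal(attr(tv, "argmax_interval"), 1L)
  expect_equal(tv$t_from, c(0, 5, 10))
  # gene order is irrelevant
  tv2 <- transition_variance(f[sample(30), ], tt)
  expect_equal(tv2$variance, tv$variance)
  # a flat cohort has no variance anywhere
  expect_equal(transition_variance(matrix(1, 5, 4), tt)$variance, rep(0, 3))
  expect_error(transition_variance(matrix(1, 5, 1)), "2 time points")
})

test_that("per-gene and per-cluster summary statistics", {
  coh <- simulate_cohort(sim_config(n_genes = 8, seed = 19))
  st <- profile_stats(coh)
  expect_equal(nrow(st), 8)
  expect_true(all(st$mfc_exp >= 1 & st$mfc_pol >= 1))
  expect_true(all(abs(st$corr_fy) <= 1, na.rm = TRUE))
  # known MFC through the full path
  f <- matrix(log2(c(1, 2, 4, 2)), 1)
  y <- matrix(log2(c(1, 8, 2, 1)), 1)
  rownames(f) <- rownames(y) <- "gA"
  expect_equal(profile_stats(f, y)$mfc_pol, 4)
  expect_equal(profile_stats(f, y)$mfc_exp, 8)

  stats <- data.frame(gene_id = paste0("g", 1:4),
                      mfc_exp = c(1.5, 2.0, 4.0, 3.0),
                      mfc_pol = c(1, 2, 3, 4))
  expect_equal(median_mfc(paste0("g", 1:3), stats)$medmfc_exp, 2.0)
  expect_equal(median_mfc("g2", stats)$medmfc_exp, 2.0)
  expect_equal(median_mfc(paste0("g", 1:4), stats)$medmfc_pol, 2.5)
  expect_error(median_mfc(character(0), stats), "non-empty")
  expect_error(median_mfc("nope", stats), "missing")
})

test_that("matched pairs correlate better than shuffled ones", {
  cfg <- sim_config(n_genes = 30, seed = 29,
                    class_proportions = c(constant = 1, exp_approach = 0,
                                          switch_stab = 0,
                                          switch_destab = 0))
  coh <- simulate_cohort(cfg)
  sh <- shuffle_pairing(coh, seed = 30)
  med <- function(co) median(profile_stats(co)$corr_fy, na.rm = TRUE)
  expect_gt(med(coh), med(sh))
})
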