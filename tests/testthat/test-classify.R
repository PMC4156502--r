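test_that("cluster strategy labels follow the amplitude cut-offs", {
  expect_equal(label_cluster_strategy(2.5, 2.0), "strong_both")
  expect_equal(label_cluster_strategy(2.0, 1.1), "post_transcriptional")
  expect_equal(label_cluster_strategy(1.5, 1.5), "unassigned")
  # boundary: 1.7 itself is not "above 1.7"
  expect_equal(label_cluster_strategy(1.7, 1.7), "unassigned")
  # vectorized and a partition: exactly one label each
  lab <- label_cluster_strategy(c(2.5, 2.0, 1.5, 3), c(2.0, 1.1, 1.5, 1.4))
  expect_equal(lab, c("strong_both", "post_transcriptional", "unassigned",
                      "unassigned"))
})

test_that("return-to-baseline detection", {
  up <- c(0, 1, 2, 1.8, 1, 0.5, 0.5)
  r <- returns_to_baseline(up)
  expect_true(r$flag)
  expect_equal(r$direction, "up")
  expect_equal(r$recession[2], 0.75)
  mono <- returns_to_baseline(c(0, 0.5, 1, 1.5, 2, 2.5))
  expect_false(mono$flag)
  v <- returns_to_baseline(c(0, -2, -1.5, -0.6, -0.1, 0.05))
  expect_true(v$flag)
  expect_equal(v$direction, "down")
  flat <- returns_to_baseline(rep(0, 6))
  expect_false(flat$flag)
})

test_that("hypergeometric enrichment equals exhaustive enumeration", {
  uni <- paste0("g", 1:20)
  set5 <- uni[1:5]
  clus <- uni[c(1:4, 10, 11)]
  r <- enrichment_test(clus, set5, uni)
  expect_equal(r$overlap, 4)
  expect_equal(r$p_value, hyper_tail_oracle(4, 20, 5, 6))
  expect_equal(r$p_value, 540 / 38760) # 5*C(15,2) + C(15,1) over C(20,6)
  # disjoint overlap is certain at >= 0
  expect_equal(enrichment_test(uni[6:10], set5, uni)$p_value, 1)
  # fully overlapping degenerate case
  expect_equal(enrichment_test(uni, uni, uni)$p_value, 1)
  expect_error(enrichment_test(clus, set5, character(0)), "non-empty")
  expect_error(enrichment_test(c(clus, "zz"), set5, uni), "subsets")
  # random instances across small universes
  set.seed(14)
  for (r in 1:25) {
    N <- sample(5:25, 1)
    u <- paste0("g", 1:N)
    s <- sample(u, sample.int(N, 1))
    cl <- sample(u, sample.int(N, 1))
    got <- enrichment_test(cl, s, u)
    expect_equal(got$p_value,
                 hyper_tail_oracle(got$overlap, N, length(s), length(cl)))
  }
})

test_that("regulator dependence is recovered from a mutant contrast", {
  uni <- paste0("g", 1:100)
  regulated <- uni[1:30]
  not_regulated <- uni[61:100]
  clusters <- list(dep = uni[1:15],      # inside the regulated list
                   indep = uni[61:75],   # inside the not-regulated list
                   other = uni[31:45])   # overlaps neither
  wt <- c(dep = 3.0, indep = 2.4, other = 2.6)
  mut <- c(dep = 1.2, indep = 2.3, other = 1.5)
  out <- regulator_dependence(clusters, wt, mut, regulated, not_regulated,
                              uni)
  expect_equal(out$dependence[out$cluster_id == "dep"], "dependent")
  expect_equal(out$dependence[out$cluster_id == "indep"], "independent")
  expect_equal(out$dependence[out$cluster_id == "other"], "unassigned")
  # a large amplitude ratio without overlap stays unassigned
  expect_equal(out$medmfc_ratio[out$cluster_id == "other"], 2.6 / 1.5)
  # missing mutant data cannot be classified
  mut2 <- c(dep = NA, indep = 2.3, other = 1.5)
  out2 <- regulator_dependence(clusters, wt, mut2, regulated,
                               not_regulated, uni)
  expect_equal(out2$dependence[out2$cluster_id == "dep"], "unassigned")
})
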