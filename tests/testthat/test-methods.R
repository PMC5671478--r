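test_that("delta-Ct stability matches hand computation", {
  # A and B parallel -> SD of their difference is 0
  ab <- tibble::tibble(gene = c("A", "B"),
                       s1 = c(20, 25), s2 = c(21, 26), s3 = c(22, 27))
  d <- delta_ct(ab)
  expect_equal(d$stability, c(0, 0))

  d3 <- delta_ct(abc_cq())
  expect_equal(d3$stability[d3$gene == "A"],
               mean(c(0, sd(c(5, 3, 6, 2)))), tolerance = 1e-12)
  expect_equal(round(d3$stability[d3$gene == "A"], 4), 0.9129)
})

test_that("delta-Ct is invariant to a constant shift of one gene", {
  panel <- random_cq_panel(7, k = 5, s = 8)
  shifted <- panel
  shifted[2, -1] <- shifted[2, -1] + 5
  expect_equal(delta_ct(panel)$stability, delta_ct(shifted)$stability,
               tolerance = 1e-9)
})

test_that("BestKeeper dispersion, index and correlation behave as defined", {
  cq2 <- tibble::tibble(gene = c("g", "h"), s1 = c(20, 30), s2 = c(22, 30))
  bk2 <- bestkeeper(cq2)
  expect_equal(bk2$stability[bk2$gene == "g"], 1)   # mean |20,22 - 21|

  cq3 <- tibble::tibble(gene = c("g", "h"),
                        s1 = c(20, 10), s2 = c(22, 10), s3 = c(21, 10))
  bk3 <- bestkeeper(cq3)
  expect_equal(bk3$stability[bk3$gene == "g"], 2 / 3, tolerance = 1e-12)
  expect_equal(round(bk3$stability[bk3$gene == "g"], 4), 0.6667)

  # a gene equal to the index up to shift correlates perfectly
  base <- c(20, 21, 23, 26)
  cq4 <- tibble::tibble(gene = c("x", "y"),
                        s1 = c(base[1], base[1] + 4), s2 = c(base[2], base[2] + 4),
                        s3 = c(base[3], base[3] + 4), s4 = c(base[4], base[4] + 4))
  bk4 <- bestkeeper(cq4)
  # the geometric-mean index is not exactly affine in Cq, so correlation with
  # a shifted copy of the panel profile is near-perfect, not identically 1
  expect_equal(bk4$corr_index, c(1, 1), tolerance = 1e-6)

  # classic SD mode and the inconsistency flag
  bk_sd <- bestkeeper(cq3, dispersion = "sd")
  expect_equal(bk_sd$stability[bk_sd$gene == "g"], 1)
  wob <- tibble::tibble(gene = c("w", "v"), s1 = c(18, 20), s2 = c(22, 20.5))
  expect_true(bestkeeper(wob)$inconsistent[1])
})

test_that("consensus geometric mean reproduces worked rank sets", {
  ranks <- tibble::tibble(
    gene = rep(c("top", "mixed", "mid"), each = 4),
    method = rep(c("bestkeeper", "delta_ct", "genorm", "normfinder"), 3),
    rank = c(1, 1, 1, 1,  2, 1, 7, 1,  3, 4, 5, 4)
  )
  cc <- consensus_rank(ranks)
  expect_equal(cc$geomean[cc$gene == "top"], 1)
  expect_equal(cc$geomean[cc$gene == "mixed"], 14^0.25, tolerance = 1e-12)
  expect_equal(round(cc$geomean[cc$gene == "mixed"], 2), 1.93)
  expect_equal(round(cc$geomean[cc$gene == "mid"], 4), 3.9360)
  expect_equal(cc$gene[cc$final_rank == 1], "top")
})

test_that("consensus validates its input", {
  bad <- tibble::tibble(gene = c("a", "b", "a"),
                        method = c("m1", "m1", "m2"),
                        rank = c(1, 2, 1))
  expect_error(consensus_rank(bad), "same gene set")
  na_rank <- tibble::tibble(gene = "a", method = "m1", rank = NA_real_)
  expect_error(consensus_rank(na_rank), "positive")
})

test_that("consensus geomean lies in [1, k] and tracks unanimity", {
  sim <- simulate_cq(seed = 99)
  panel <- rank_stability(sim$cq, sim$design)
  k <- nrow(panel)
  expect_true(all(panel$geomean >= 1 & panel$geomean <= k))
  unanimous <- panel$bestkeeper_rank == 1 & panel$deltact_rank == 1 &
    panel$genorm_rank == 1 & panel$normfinder_rank == 1
  expect_equal(panel$geomean == 1, unanimous)
})

test_that("all four methods are invariant to sample permutation and share ranks 1..k", {
  sim <- simulate_cq(seed = 12, k_genes = 8)
  cq <- sim$cq
  perm_cols <- c("gene", rev(setdiff(names(cq), "gene")))
  perm <- cq[, perm_cols]
  perm_design <- sim$design[rev(seq_len(nrow(sim$design))), ]
  a <- rank_stability(cq, sim$design)
  b <- rank_stability(perm, perm_design)
  for (col in c("bestkeeper_value", "deltact_value", "genorm_value",
                "normfinder_value", "geomean")) {
    expect_equal(a[[col]], b[[col]], tolerance = 1e-9)
  }
  for (col in c("bestkeeper_rank", "deltact_rank", "genorm_rank",
                "normfinder_rank", "final_rank")) {
    expect_equal(sort(a[[col]]), seq_len(nrow(a)))
    expect_equal(a[[col]], b[[col]])
  }
})

test_that("stability panel tidy() returns the long method table", {
  sim <- simulate_cq(seed = 4, k_genes = 5)
  panel <- rank_stability(sim$cq, sim$design)
  td <- tidy(panel)
  expect_setequal(unique(td$method),
                  c("bestkeeper", "deltact", "genorm", "normfinder"))
  expect_equal(nrow(td), 4 * nrow(panel))
})
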