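test_that("geNorm reproduces the worked three-gene example", {
  q <- relative_quantities(abc_cq())
  fit <- genorm(q)
  # A and B are perfectly parallel: V_AB = 0; C is excluded first with
  # M_C = sd(5,3,6,2) = 1.8257
  expect_equal(fit$exclusion_order, "C")
  expect_equal(fit$stability$stability[fit$stability$gene == "C"],
               sd(c(5, 3, 6, 2)), tolerance = 1e-9)
  expect_equal(round(fit$stability$stability[fit$stability$gene == "C"], 4),
               1.8257)
  expect_equal(fit$final_pair, c("A", "B"))
  expect_equal(fit$stability$stability[fit$stability$gene %in% c("A", "B")],
               c(0, 0))
  expect_equal(fit$stability$rank, c(1L, 2L, 3L))
})

test_that("proportional quantity profiles have zero pairwise variation", {
  q <- tibble::tibble(gene = c("a", "b", "c"),
                      s1 = c(1, 0.5, 0.9), s2 = c(0.5, 0.25, 0.2),
                      s3 = c(0.25, 0.125, 1))
  fit <- genorm(q)
  expect_equal(fit$final_pair, c("a", "b"))
  expect_equal(fit$stability$stability[fit$stability$gene %in% c("a", "b")],
               c(0, 0), tolerance = 1e-12)
})

test_that("optimal reference number follows the pairwise-variation cutoff", {
  sim <- simulate_cq(seed = 21, k_genes = 6, stable_gene_count = 4,
                     noise_sd_stable = 0.05, noise_sd_unstable = 0.3,
                     group_shift_unstable = 0)
  fit <- genorm(relative_quantities(sim$cq))
  expect_true(all(fit$v_curve$v < 0.15))
  expect_equal(fit$optimal_n, 2L)
  expect_equal(fit$v_flag, "all_below")

  noisy <- simulate_cq(seed = 22, k_genes = 6, stable_gene_count = 2,
                       noise_sd_stable = 2, noise_sd_unstable = 4,
                       group_shift_unstable = 3)
  fit2 <- genorm(relative_quantities(noisy$cq))
  expect_true(all(fit2$v_curve$v >= 0.15))
  expect_equal(fit2$optimal_n, 2L)
  expect_equal(fit2$v_flag, "none_below")
})

test_that("degenerate and undersized panels are handled", {
  expect_error(genorm(tibble::tibble(gene = c("a", "b"),
                                     s1 = c(1, 1), s2 = c(0.5, 0.5))),
               "3 genes")
  # zero-variance panel: all M = 0 and ranking falls back to gene id
  q0 <- tibble::tibble(gene = c("b", "a", "c"),
                       s1 = c(1, 1, 1), s2 = c(1, 1, 1))
  fit <- genorm(q0)
  expect_equal(fit$stability$stability, c(0, 0, 0))
  expect_equal(fit$stability$gene[order(fit$stability$rank)],
               c("a", "b", "c"))
})

test_that("stepwise exclusion matches the brute-force oracle", {
  for (seed in 1:25) {
    k <- 3 + (seed %% 4)
    panel <- random_cq_panel(seed, k = k, s = 6)
    q <- relative_quantities(panel)
    fit <- genorm(q)
    orc <- oracle_genorm(q)
    expect_equal(fit$exclusion_order, orc$exclusion_order)
    expect_equal(stats::setNames(fit$stability$stability, fit$stability$gene),
                 orc$m_at_exclusion[fit$stability$gene], tolerance = 1e-12)
    expect_equal(stats::setNames(fit$stability$rank, fit$stability$gene),
                 orc$rank[fit$stability$gene])
  }
})

test_that("full-panel geNorm M equals delta-Ct stability at E = 2", {
  for (seed in 1:20) {
    panel <- random_cq_panel(seed + 100, k = 3 + (seed %% 6), s = 5 + (seed %% 4))
    m <- genorm_m(relative_quantities(panel))
    d <- delta_ct(panel)
    expect_equal(m$m, d$stability[match(m$gene, d$gene)], tolerance = 1e-9)
  }
})

test_that("genorm tidy/glance expose stability table and optimal number", {
  fit <- genorm(relative_quantities(abc_cq()))
  td <- tidy(fit)
  expect_named(td, c("gene", "method", "stability", "rank"))
  expect_equal(unique(td$method), "genorm")
  gl <- glance(fit)
  expect_equal(gl$n_genes, 3L)
  expect_true(gl$optimal_n >= 2)
})
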