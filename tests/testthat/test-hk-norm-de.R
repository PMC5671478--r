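test_that("normalization factors are per-sample geometric means of references", {
  mat <- tibble::tibble(transcript_id = c("r1", "r2", "g"),
                        s1 = c(1, 4, 10), s2 = c(2, 2, 10), s3 = c(3, 3, 10))
  nf1 <- normalization_factors(mat, "r1")
  expect_equal(nf1$factor, c(1, 2, 3))
  nf2 <- normalization_factors(mat, c("r1", "r2"))
  expect_equal(nf2$factor, c(2, 2, 3))
  # constant references give constant factors
  flat <- tibble::tibble(transcript_id = c("r", "g"),
                         s1 = c(5, 1), s2 = c(5, 2))
  expect_equal(unique(normalization_factors(flat, "r")$factor), 5)
})

test_that("zero or absent reference values are rejected by name", {
  mat <- tibble::tibble(transcript_id = c("r", "g"),
                        s1 = c(0, 1), s2 = c(2, 2))
  expect_error(normalization_factors(mat, "r"), "r.*s1")
  expect_error(normalization_factors(mat, "nope"), "not in matrix")
})

make_de_fixture <- function() {
  design <- tibble::tibble(sample = c("t1", "t2", "c1", "c2"),
                           group = c("T", "T", "C", "C"),
                           replicate = c(1L, 2L, 1L, 2L))
  mat <- tibble::tibble(
    transcript_id = c("hk1", "hk2", "doubles", "triples", "halves", "tracksHK"),
    t1 = c(2, 8, 20, 30, 3, 8),
    t2 = c(2, 8, 20, 30, 3, 8),
    c1 = c(2, 8, 10, 10, 10, 8),
    c2 = c(2, 8, 10, 10, 10, 8)
  )
  list(mat = mat, design = design)
}

test_that("fold-change calls use strict thresholds", {
  fx <- make_de_fixture()
  de <- relative_de(fx$mat, fx$design, c("hk1", "hk2"), treat = "T", control = "C")
  expect_equal(de$call[de$gene == "doubles"], "ns")   # fc == 2, strict >
  expect_equal(de$fc[de$gene == "doubles"], 2)
  expect_equal(de$call[de$gene == "triples"], "up")
  expect_equal(de$call[de$gene == "halves"], "down")
  expect_equal(de$fc[de$gene == "tracksHK"], 1)       # proportional to refs
  # a reference gene evaluated against itself is exactly 1
  expect_equal(de$fc[de$gene == "hk1"], 1)
})

test_that("calls are invariant to global and per-sample rescaling", {
  fx <- make_de_fixture()
  base <- relative_de(fx$mat, fx$design, c("hk1", "hk2"), "T", "C")

  global <- fx$mat
  for (s in setdiff(names(global), "transcript_id")) {
    global[[s]] <- global[[s]] * 100
  }
  g <- relative_de(global, fx$design, c("hk1", "hk2"), "T", "C")
  expect_equal(g$fc, base$fc, tolerance = 1e-12)
  expect_equal(g$call, base$call)

  percol <- fx$mat
  scale <- c(t1 = 0.5, t2 = 3, c1 = 10, c2 = 0.2)
  for (s in names(scale)) percol[[s]] <- percol[[s]] * scale[[s]]
  p <- relative_de(percol, fx$design, c("hk1", "hk2"), "T", "C")
  expect_equal(p$fc, base$fc, tolerance = 1e-12)
  expect_equal(p$call, base$call)
})

test_that("constant references reduce calls to the raw group-mean ratio", {
  fx <- make_de_fixture()
  de <- relative_de(fx$mat, fx$design, "hk1", "T", "C")
  raw_fc <- (fx$mat$t1 + fx$mat$t2) / (fx$mat$c1 + fx$mat$c2)
  expect_equal(de$fc, raw_fc, tolerance = 1e-12)
})

test_that("zero control means yield undefined fold change and ns call", {
  design <- tibble::tibble(sample = c("t1", "c1", "c2"),
                           group = c("T", "C", "C"),
                           replicate = c(1L, 1L, 2L))
  mat <- tibble::tibble(transcript_id = c("hk", "trace"),
                        t1 = c(2, 5), c1 = c(2, 0), c2 = c(2, 0))
  expect_warning(de <- relative_de(mat, design, "hk", "T", "C"), "undefined")
  expect_true(is.na(de$fc[de$gene == "trace"]))
  expect_equal(de$call[de$gene == "trace"], "ns")
})

test_that("concordance counts partition the gene universe", {
  calls <- function(genes, call, fc) {
    out <- tibble::tibble(gene = genes, mean_treat = NA_real_,
                          mean_control = NA_real_, fc = fc,
                          log2fc = log2(fc), call = call,
                          method_label = "x")
    class(out) <- c("de_calls", class(out))
    out
  }
  a <- calls(paste0("g", 1:20),
             c(rep("up", 10), rep("down", 6), rep("ns", 4)),
             c(rep(4, 10), rep(0.25, 6), rep(1.2, 4)))
  # 16 concordant by construction, 2 same-direction, 2 discordant
  b_call <- a$call
  b_fc <- a$fc
  b_call[1:2] <- "ns"; b_fc[1:2] <- 1.5          # same direction, weaker
  b_call[19:20] <- "down"; b_fc[19:20] <- 0.2    # direction flips
  b <- calls(a$gene, b_call, b_fc)
  cc <- concordance(a, b)
  expect_equal(cc$n_same_call, 16)
  expect_equal(cc$n_same_direction_diff_magnitude, 2)
  expect_equal(cc$n_discordant, 2)
  expect_equal(cc$n_same_call + cc$n_same_direction_diff_magnitude +
                 cc$n_discordant, 20)
  expect_equal(nrow(tidy(cc)), 20)
  expect_equal(glance(cc)$n_same_call, 16)

  # identical sets agree everywhere; opposite sets do not
  self <- concordance(a, a)
  expect_equal(self$n_same_call, 20)
  flip <- calls(a$gene, ifelse(a$call == "up", "down",
                               ifelse(a$call == "down", "up", "up")),
                1 / a$fc)
  opp <- concordance(a[1:16, ], flip[1:16, ])
  expect_equal(opp$n_same_call, 0)

  expect_error(concordance(a, b[1:10, ]), "universe")
})
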