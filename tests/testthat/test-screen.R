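test_that("transcript_stats reproduces hand-computed statistics", {
  mat <- tibble::tibble(transcript_id = c("flat", "pair", "zero"),
                        s1 = c(2, 2, 0), s2 = c(2, 4, 5),
                        s3 = c(2, 3, 5), s4 = c(2, 3, 5))
  st <- transcript_stats(mat)

  flat <- st[st$transcript_id == "flat", ]
  expect_equal(flat$cv, 0)
  expect_equal(flat$mfc, 1)
  expect_true(flat$constitutive)

  # two-sample check on its own matrix (n-1 SD)
  st2 <- transcript_stats(tibble::tibble(transcript_id = "t",
                                         a = 2, b = 4))
  expect_equal(st2$mean_expr, 3)
  expect_equal(st2$sd_expr, sqrt(2), tolerance = 1e-12)
  expect_equal(st2$cv, 100 * sqrt(2) / 3, tolerance = 1e-9)
  expect_equal(round(st2$cv, 2), 47.14)
  expect_equal(st2$mfc, 2)

  zero <- st[st$transcript_id == "zero", ]
  expect_false(zero$constitutive)
  expect_true(is.na(zero$mfc))
  expect_true(is.na(zero$log_cv_abs))
  expect_equal(zero$n_samples_expressed, 3L)
})

test_that("a single-sample matrix is rejected (SD undefined)", {
  expect_error(transcript_stats(tibble::tibble(transcript_id = "t", s1 = 1)),
               "two samples")
})

test_that("select_stable admits via the CV or the log-CV clause", {
  stats <- tibble::tibble(
    transcript_id = c("cv_ok", "log_ok", "both_fail", "mfc_fail", "not_ce"),
    mean_expr = 100, sd_expr = 10,
    cv = c(19, 21, 21, 19, 19),
    log_mean = 5,
    log_cv_abs = c(6, 4, 6, 4, 4),
    mfc = c(1.9, 1.5, 1.5, 2.0, 1.5),
    constitutive = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    n_samples_expressed = c(12L, 12L, 12L, 12L, 11L)
  )
  out <- select_stable(stats)
  expect_equal(out$passed,
               c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$pass_clause[1:2], c("cv", "log_cv"))
  expect_true(all(is.na(out$pass_clause[3:5])))
})

test_that("select_stable is monotone in its thresholds", {
  sim <- simulate_fpkm(seed = 42)
  st <- transcript_stats(sim$matrix)
  base <- select_stable(st)
  wider <- select_stable(st, cv_max = 30, mfc_max = 2.5, logcv_max = 8)
  expect_true(all(st$transcript_id[base$passed] %in%
                    st$transcript_id[wider$passed]))
})

test_that("cv, mfc, constitutive flag and selection are scale invariant", {
  sim <- simulate_fpkm(seed = 11)
  mat <- sim$matrix
  scaled <- mat
  for (s in setdiff(names(scaled), "transcript_id")) {
    scaled[[s]] <- scaled[[s]] * 7.3
  }
  a <- transcript_stats(mat)
  b <- transcript_stats(scaled)
  expect_equal(a$cv, b$cv, tolerance = 1e-9)
  expect_equal(a$mfc, b$mfc, tolerance = 1e-9)
  expect_equal(a$constitutive, b$constitutive)
  # the cv/mfc clauses of the filter are invariant too
  expect_equal(select_stable(a, logcv_max = 1e-12)$passed,
               select_stable(b, logcv_max = 1e-12)$passed)
})

test_that("stats are invariant to sample-column permutation", {
  sim <- simulate_fpkm(seed = 5)
  mat <- sim$matrix
  perm <- mat[, c("transcript_id",
                  rev(setdiff(names(mat), "transcript_id")))]
  expect_equal(transcript_stats(mat), transcript_stats(perm))
})

test_that("recommend_references applies window and isoform-uniqueness rules", {
  stats <- tibble::tibble(
    transcript_id = c("good", "low", "multi"),
    mean_expr = c(300, 5, 300), sd_expr = c(30, 0.5, 30),
    cv = c(10, 10, 10), log_mean = 5, log_cv_abs = c(2, 2, 2),
    mfc = 1.4, constitutive = TRUE, n_samples_expressed = 12L
  )
  index <- tibble::tibble(transcript_id = c("good", "low", "multi"),
                          gene_id = c("G1", "G2", "G3"),
                          isoform_count = c(1L, 1L, 13L))
  rec <- recommend_references(stats, index)
  expect_equal(rec$transcript_id, "good")
  # without the uniqueness rule the multi-isoform transcript is admitted
  rec2 <- recommend_references(stats, index, require_unique_isoform = FALSE)
  expect_setequal(rec2$transcript_id, c("good", "multi"))
  # results are sorted by cv then id
  expect_equal(rec2$recommendation_rank, seq_len(nrow(rec2)))
  expect_equal(rec2$transcript_id, sort(rec2$transcript_id))
})

test_that("recommend_references logs transcripts with unknown isoform status", {
  stats <- tibble::tibble(
    transcript_id = c("known", "unknown"),
    mean_expr = 300, sd_expr = 30, cv = 10, log_mean = 5,
    log_cv_abs = 2, mfc = 1.4, constitutive = TRUE,
    n_samples_expressed = 12L
  )
  index <- tibble::tibble(transcript_id = "known", gene_id = "G",
                          isoform_count = 1L)
  expect_warning(rec <- recommend_references(stats, index), "unknown")
  expect_equal(rec$transcript_id, "known")
})

test_that("top_overlap matches enumeration and its identities", {
  st <- tibble::tibble(transcript_id = paste0("t", 1:5),
                       a = c(1, 2, 3, 4, 5),
                       b = c(2, 4, 1, 5, 3))
  # top-2 by a: t1,t2; by b: t3,t1 -> overlap 1/2
  expect_equal(top_overlap(st, a, b, 2), 0.5)
  expect_equal(top_overlap(st, a, a, 3), 1)
  disjoint <- tibble::tibble(transcript_id = paste0("t", 1:4),
                             a = c(1, 2, 3, 4), b = c(4, 3, 1, 2))
  expect_equal(top_overlap(disjoint, a, b, 2), 0)
  expect_error(top_overlap(st, a, b, 6), "exceeds")
})

test_that("expression partition is a disjoint cover with a strict cutoff", {
  stats <- tibble::tibble(transcript_id = c("lo", "edge", "hi"),
                          mean_expr = c(0.5, 1.0, 10))
  p <- partition_by_expression(stats)
  expect_equal(as.character(p$expression_class), c("low", "high", "high"))
  sim <- simulate_fpkm(seed = 3)
  ps <- partition_by_expression(transcript_stats(sim$matrix))
  expect_equal(sum(ps$expression_class == "low") +
                 sum(ps$expression_class == "high"), nrow(ps))
})

test_that("screen_report computes counts and rounded percentages", {
  screened <- tibble::tibble(
    constitutive = c(TRUE, TRUE, FALSE, FALSE),
    passed = c(TRUE, FALSE, FALSE, FALSE)
  )
  rep <- screen_report(screened)
  expect_equal(rep$n_transcripts, 4)
  expect_equal(rep$pct_constitutive, 50)
  expect_equal(rep$pct_stable, 25)
})
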