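# Small in-code fixtures shared across tests.

tiny_expr <- function() {
  tibble::tibble(
    transcript_id = c("t1", "t2", "t3"),
    s1 = c(2, 10, 0),
    s2 = c(2, 20, 5),
    s3 = c(2, 15, 5),
    s4 = c(2, 12, 5)
  )
}

# three-gene Cq panel used in the worked geNorm/delta-Ct examples:
# A and B move in parallel (V_AB = 0), C wobbles
abc_cq <- function() {
  tibble::tibble(
    gene = c("A", "B", "C"),
    s1 = c(20, 22, 25),
    s2 = c(21, 23, 24),
    s3 = c(20, 22, 26),
    s4 = c(21, 23, 23)
  )
}

random_cq_panel <- function(seed, k = 5, s = 8, base = c(18, 30), sd_range = c(0.1, 1.5)) {
  withr::with_seed(seed, {
    genes <- sprintf("g%02d", seq_len(k))
    m <- t(vapply(seq_len(k), function(i) {
      runif(1, base[1], base[2]) + rnorm(s, 0, runif(1, sd_range[1], sd_range[2]))
    }, numeric(s)))
    dplyr::bind_cols(tibble::tibble(gene = genes),
                     tibble::as_tibble(stats::setNames(as.data.frame(m),
                                                       paste0("s", seq_len(s)))))
  })
}

two_group_design <- function(samples) {
  n <- length(samples)
  tibble::tibble(sample = samples,
                 group = rep(c("G1", "G2"), each = n / 2),
                 replicate = rep(seq_len(n / 2), 2))
}

write_gtf <- function(path, gene_tx) {
  # gene_tx: named integer vector, gene id -> number of transcripts
  lines <- unlist(lapply(names(gene_tx), function(g) {
    vapply(seq_len(gene_tx[[g]]), function(i) {
      sprintf(paste0("chr1\ttest\ttranscript\t%d\t%d\t.\t+\t.\t",
                     "gene_id \"%s\"; transcript_id \"%s.%d\";"),
              i * 100, i * 100 + 50, g, g, i)
    }, character(1))
  }))
  writeLines(lines, path)
  path
}
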