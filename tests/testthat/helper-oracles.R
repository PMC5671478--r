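# Independent brute-force oracles, written as direct loop-wise transcriptions
# of the methods' defining formulas. They share no code with the package
# implementations they check.

# stepwise geNorm: explicit O(k^2 * s) recomputation at every exclusion step
oracle_genorm <- function(q_tbl) {
  m <- as.matrix(q_tbl[setdiff(names(q_tbl), "gene")])
  rownames(m) <- q_tbl$gene
  L <- log2(m)
  pair_v <- function(a, b) stats::sd(L[a, ] - L[b, ])
  active <- sort(rownames(L))
  m_at <- stats::setNames(rep(NA_real_, nrow(L)), rownames(L))
  excluded <- character(0)
  step_m <- list()
  while (length(active) > 2) {
    M <- sapply(active, function(g) {
      vs <- c()
      for (h in active) if (h != g) vs <- c(vs, pair_v(g, h))
      mean(vs)
    })
    step_m[[length(step_m) + 1]] <- M
    worst <- names(M)[M == max(M)]
    drop <- sort(worst, decreasing = TRUE)[1]
    m_at[drop] <- M[[drop]]
    excluded <- c(excluded, drop)
    active <- setdiff(active, drop)
  }
  fm <- pair_v(active[1], active[2])
  m_at[active] <- fm
  ranked <- c(sort(active), rev(excluded))
  list(m_at_exclusion = m_at,
       exclusion_order = excluded,
       rank = stats::setNames(seq_along(ranked), ranked),
       step_m = step_m)
}

# NormFinder: per-formula evaluation with explicit loops
oracle_normfinder <- function(cq_tbl, design = NULL) {
  m <- as.matrix(cq_tbl[setdiff(names(cq_tbl), "gene")])
  rownames(m) <- cq_tbl$gene
  x <- -m
  k <- nrow(x)
  genes <- rownames(x)
  if (is.null(design)) {
    groups <- list(all = colnames(x))
  } else {
    groups <- split(design$sample, design$group)
  }
  G <- length(groups)
  sigma2 <- matrix(NA_real_, k, G)
  d <- matrix(NA_real_, k, G)
  for (g in seq_len(G)) {
    cols <- groups[[g]]
    z <- matrix(NA_real_, k, length(cols))
    for (j in seq_along(cols)) {
      sample_mean <- mean(x[, cols[j]])
      for (i in seq_len(k)) z[i, j] <- x[i, cols[j]] - sample_mean
    }
    v <- numeric(k)
    for (i in seq_len(k)) v[i] <- stats::var(z[i, ])
    for (i in seq_len(k)) {
      sigma2[i, g] <- max(0, (v[i] - sum(v) / (k * (k - 1))) * k / (k - 2))
      d[i, g] <- mean(z[i, ])
    }
  }
  if (G == 1) {
    rho <- sqrt(sigma2[, 1])
  } else {
    n_g <- sapply(groups, length)
    dbar <- numeric(k)
    for (i in seq_len(k)) dbar[i] <- mean(d[i, ])
    dd2 <- c(); se <- c()
    for (i in seq_len(k)) for (g in seq_len(G)) {
      dd2 <- c(dd2, (d[i, g] - dbar[i])^2)
      se <- c(se, sigma2[i, g] / n_g[g])
    }
    gamma2 <- max(0, mean(dd2) * G / (G - 1) - mean(se))
    rho <- numeric(k)
    for (i in seq_len(k)) {
      acc <- 0
      for (g in seq_len(G)) {
        se_ig <- sigma2[i, g] / n_g[g]
        denom <- gamma2 + se_ig
        b <- if (denom > 0) (d[i, g] - dbar[i]) * gamma2 / denom else 0
        acc <- acc + abs(b) + sqrt(se_ig)
      }
      rho[i] <- acc / G
    }
  }
  stats::setNames(rho, genes)
}
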