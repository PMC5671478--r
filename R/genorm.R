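# strict ordinal ranks: ascending stability value, ties broken by gene id
rank_by_value <- function(value, gene) {
  ord <- order(value, gene)
  r <- integer(length(value))
  r[ord] <- seq_along(value)
  r
}

#' geNorm stability analysis with stepwise exclusion and pairwise variation
#'
#' Implements the geNorm procedure on a relative-quantity table. For every
#' pair of genes the pairwise variation `V_jk` is the SD over samples of
#' `log2(q_j / q_k)`; a gene's expression stability `M` is its mean `V`
#' against all other genes in the current set. The least stable gene (largest
#' `M`, ties broken by removing the lexicographically larger id) is excluded
#' and `M` recomputed, down to the final pair, which shares the final `M`.
#'
#' The pairwise-variation curve asks how many reference genes are enough:
#' `NF_n` is the per-sample geometric mean of the `n` best-ranked genes'
#' quantities, and `V(n, n+1)` the SD over samples of `log2(NF_n / NF_{n+1})`.
#' The optimal number is the smallest `n >= 2` with `V < v_cutoff` (0.15 by
#' convention); when no `V` clears the cutoff the answer defaults to 2 and the
#' `v_flag` says so.
#'
#' @param q Relative-quantity table from [relative_quantities()] (a `gene`
#'   column plus numeric sample columns, values in `(0, 1]`). A raw Cq table
#'   can be converted first.
#' @param v_cutoff Pairwise-variation cutoff for the optimal gene number.
#' @return An object of class `genorm_fit`: a list with `stability` (tibble:
#'   `gene`, `stability` = `M` at exclusion, `rank`), `exclusion_order`,
#'   `final_pair`, `v_curve` (tibble `n`, `v`), `optimal_n`, `v_flag`
#'   (`"ok"`, `"all_below"` or `"none_below"`), `n_genes`, `n_samples`.
#'   Use [tidy()] / [glance()] / [autoplot()] on it.
#' @export
genorm <- function(q, v_cutoff = 0.15) {
  m <- cq_values(q)  # same layout as a Cq table: gene column + sample columns
  if (anyNA(m)) abort("relative-quantity table must be complete")
  if (any(m <= 0)) abort("relative quantities must be positive")
  k <- nrow(m)
  s <- ncol(m)
  if (k < 3) abort("geNorm needs at least 3 genes")
  if (s < 2) abort("geNorm needs at least 2 samples")

  L <- log2(m)
  genes <- rownames(L)
  # pairwise variation matrix V_jk = SD over samples of log2 ratios
  V <- matrix(0, k, k, dimnames = list(genes, genes))
  for (j in seq_len(k - 1)) {
    for (h in seq(j + 1, k)) {
      v <- sd(L[j, ] - L[h, ])
      V[j, h] <- v
      V[h, j] <- v
    }
  }

  active <- genes
  m_at_exclusion <- setNames(numeric(k), genes)
  exclusion_order <- character(0)
  while (length(active) > 2) {
    M <- vapply(active,
                function(g) mean(V[g, setdiff(active, g)]),
                numeric(1))
    worst <- max(M)
    # among ties, drop the lexicographically larger id (smaller ids rank better)
    cand <- sort(names(M)[M == worst], decreasing = TRUE)
    drop <- cand[[1]]
    m_at_exclusion[drop] <- M[[drop]]
    exclusion_order <- c(exclusion_order, drop)
    active <- setdiff(active, drop)
  }
  final_m <- V[active[1], active[2]]
  m_at_exclusion[active] <- final_m
  final_pair <- sort(active)

  # ranking: reverse exclusion order; the final pair takes ranks 1-2 by id
  ranked <- c(final_pair, rev(exclusion_order))
  rank_of <- setNames(seq_len(k), ranked)

  stability <- tibble(gene = genes,
                      stability = unname(m_at_exclusion[genes]),
                      rank = unname(rank_of[genes]))

  # pairwise-variation curve over the best-ranked genes
  v_curve <- tibble(n = integer(0), v = numeric(0))
  if (k >= 3) {
    nf_log <- function(n) colMeans(L[ranked[seq_len(n)], , drop = FALSE])
    v_curve <- purrr::map_dfr(2:(k - 1), function(n) {
      tibble(n = n, v = sd(nf_log(n) - nf_log(n + 1)))
    })
  }
  below <- v_curve$v < v_cutoff
  if (all(below)) {
    optimal_n <- 2L
    v_flag <- if (nrow(v_curve) > 0) "all_below" else "ok"
  } else if (!any(below)) {
    optimal_n <- 2L
    v_flag <- "none_below"
  } else {
    optimal_n <- as.integer(min(v_curve$n[below]))
    v_flag <- "ok"
  }

  structure(list(stability = stability,
                 exclusion_order = exclusion_order,
                 final_pair = final_pair,
                 v_curve = v_curve,
                 v_cutoff = v_cutoff,
                 optimal_n = optimal_n,
                 v_flag = v_flag,
                 n_genes = k,
                 n_samples = s),
            class = "genorm_fit")
}

#' Full-panel geNorm M values (no exclusion)
#'
#' The mean pairwise variation of each gene against the whole panel, i.e. the
#' `M` values of the first geNorm iteration before any gene is removed.
#'
#' @inheritParams genorm
#' @return A tibble `gene`, `m`.
#' @export
genorm_m <- function(q) {
  m <- cq_values(q)
  if (any(m <= 0) || anyNA(m)) abort("relative quantities must be positive and complete")
  L <- log2(m)
  genes <- rownames(L)
  purrr::map_dfr(genes, function(g) {
    others <- setdiff(genes, g)
    tibble(gene = g,
           m = mean(vapply(others, function(h) sd(L[g, ] - L[h, ]), numeric(1))))
  })
}

#' @export
print.genorm_fit <- function(x, ...) {
  cat("geNorm stability analysis:", x$n_genes, "genes,", x$n_samples, "samples\n")
  cat("most stable pair:", paste(x$final_pair, collapse = ", "),
      sprintf("(M = %.3f)", x$stability$stability[match(x$final_pair[1], x$stability$gene)]), "\n")
  cat("optimal number of reference genes:", x$optimal_n,
      sprintf("(V cutoff %.2f, %s)", x$v_cutoff, x$v_flag), "\n")
  invisible(x)
}

#' @rdname genorm
#' @param x A `genorm_fit` object.
#' @param ... Unused.
#' @export
tidy.genorm_fit <- function(x, ...) {
  x$stability |> mutate(method = "genorm") |>
    select(all_of(c("gene", "method", "stability", "rank")))
}

#' @rdname genorm
#' @export
glance.genorm_fit <- function(x, ...) {
  tibble(n_genes = x$n_genes, n_samples = x$n_samples,
         optimal_n = x$optimal_n, v_flag = x$v_flag,
         final_m = x$stability$stability[match(x$final_pair[1], x$stability$gene)])
}
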