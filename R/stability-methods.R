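#' Comparative delta-Ct stability analysis
#'
#' For every gene, the stability value is the mean — over all partner genes —
#' of the SD across samples of the pairwise Cq difference. A gene that moves
#' in parallel with the rest of the panel has small SDs of its delta-Ct values
#' and is deemed stable. Ranks ascend with the stability value (ties broken by
#' gene id).
#'
#' @param cq Cq table with complete rows (genes with missing cells are dropped
#'   with a warning).
#' @return A tibble `gene`, `method` (`"delta_ct"`), `stability`, `rank`.
#' @export
delta_ct <- function(cq) {
  cq <- drop_incomplete_genes(cq, "delta-Ct analysis")
  m <- cq_values(cq)
  if (nrow(m) < 2) abort("the comparative delta-Ct method needs at least 2 genes")
  genes <- rownames(m)
  stab <- vapply(genes, function(g) {
    others <- setdiff(genes, g)
    mean(vapply(others, function(h) sd(m[g, ] - m[h, ]), numeric(1)))
  }, numeric(1))
  tibble(gene = genes, method = "delta_ct", stability = unname(stab),
         rank = rank_by_value(unname(stab), genes))
}

#' BestKeeper stability analysis
#'
#' Ranks genes by the dispersion of their raw Cq values. The classic tool's
#' "SD [+/- CP]" is the mean absolute deviation of a gene's Cq from its
#' arithmetic mean (the default here); a textbook n-1 SD is available via
#' `dispersion = "sd"`. The BestKeeper index — the per-sample geometric mean
#' of Cq across all genes — and each gene's Pearson correlation with it are
#' reported for inspection but do not enter the ranking. Genes with dispersion
#' above 1 cycle are flagged inconsistent.
#'
#' @param cq Cq table with complete rows.
#' @param dispersion `"mad"` (mean absolute deviation, default) or `"sd"`.
#' @return A tibble `gene`, `method` (`"bestkeeper"`), `stability`, `rank`,
#'   `corr_index`, `inconsistent`; the per-sample index is attached as the
#'   `"index"` attribute (named numeric vector).
#' @export
bestkeeper <- function(cq, dispersion = c("mad", "sd")) {
  dispersion <- match.arg(dispersion)
  cq <- drop_incomplete_genes(cq, "BestKeeper analysis")
  m <- cq_values(cq)
  genes <- rownames(m)
  disp <- apply(m, 1, function(x) {
    if (dispersion == "mad") mean(abs(x - mean(x))) else sd(x)
  })
  if (nrow(m) >= 2) {
    index <- exp(colMeans(log(m)))
    corr <- apply(m, 1, function(x) {
      if (sd(x) == 0 || sd(index) == 0) NA_real_ else cor(x, index)
    })
  } else {
    index <- setNames(rep(NA_real_, ncol(m)), colnames(m))
    corr <- rep(NA_real_, nrow(m))
  }
  out <- tibble(gene = genes, method = "bestkeeper",
                stability = unname(disp),
                rank = rank_by_value(unname(disp), genes),
                corr_index = unname(corr),
                inconsistent = unname(disp) > 1)
  attr(out, "index") <- index
  out
}

#' NormFinder model-based stability analysis
#'
#' Decomposes each gene's expression (on the log2 scale; a Cq unit is one
#' doubling, so the analysis runs on `-Cq`) into intra-group variance and
#' inter-group bias. Within each sample the panel's gene mean is removed, the
#' residual variance per gene and group is estimated with the panel-size
#' correction `k/(k-2)` after subtracting the shared component, the per-group
#' gene effects are shrunk towards zero in proportion to how much of their
#' spread is attributable to sampling noise, and the stability value is the
#' mean over groups of (|shrunken bias| + SE of the group mean). Smaller is
#' more stable. Without grouping the stability reduces to the square root of
#' the single-group variance estimate.
#'
#' @param cq Cq table with complete rows; at least 3 genes (the `k/(k-2)`
#'   correction degenerates below that).
#' @param design Sample design; required when `use_groups = TRUE`, where every
#'   group needs at least 2 samples and there must be at least 2 groups.
#' @param use_groups Use the grouped (bias + variance) model? Defaults to
#'   `TRUE` when a design is supplied.
#' @return A tibble `gene`, `method` (`"normfinder"`), `stability`, `rank`.
#' @export
normfinder <- function(cq, design = NULL, use_groups = !is.null(design)) {
  cq <- drop_incomplete_genes(cq, "NormFinder analysis")
  m <- cq_values(cq)
  k <- nrow(m)
  if (k < 3) abort("NormFinder needs at least 3 genes")
  x <- -m  # log2-scale expression
  genes <- rownames(x)

  if (use_groups) {
    if (is.null(design)) abort("use_groups = TRUE requires a design")
    design <- validate_sample_design(design)
    if (!setequal(design$sample, colnames(x))) {
      abort("design samples do not match Cq samples")
    }
    grp <- split(design$sample, design$group)
    if (length(grp) < 2) abort("grouped NormFinder needs at least 2 groups")
    if (any(lengths(grp) < 2)) abort("every group needs at least 2 samples")
  } else {
    grp <- list(all = colnames(x))
  }
  G <- length(grp)

  sigma2 <- matrix(NA_real_, k, G, dimnames = list(genes, names(grp)))
  d <- matrix(NA_real_, k, G, dimnames = list(genes, names(grp)))
  n_g <- lengths(grp)

  for (g in seq_len(G)) {
    xg <- x[, grp[[g]], drop = FALSE]
    z <- sweep(xg, 2, colMeans(xg))        # remove per-sample panel mean
    v <- apply(z, 1, var)                  # n-1 variance over samples
    sigma2[, g] <- pmax(0, (v - sum(v) / (k * (k - 1))) * k / (k - 2))
    d[, g] <- rowMeans(z)
  }

  if (use_groups) {
    dbar <- rowMeans(d)
    dd <- d - dbar
    gamma2 <- max(0, mean(dd^2) * G / (G - 1) -
                    mean(sweep(sigma2, 2, n_g, "/")))
    se2 <- sweep(sigma2, 2, n_g, "/")
    denom <- gamma2 + se2
    b <- ifelse(denom > 0, dd * gamma2 / denom, 0)
    rho <- rowMeans(abs(b) + sqrt(se2))
  } else {
    rho <- sqrt(sigma2[, 1])
  }

  tibble(gene = genes, method = "normfinder", stability = unname(rho),
         rank = rank_by_value(unname(rho), genes))
}

#' Geometric-mean consensus of per-method stability ranks
#'
#' Aggregates the ordinal ranks assigned by several stability methods into a
#' single consensus: each gene's score is the geometric mean of its ranks, and
#' the final ranking ascends by that score (ties broken by gene id). A gene
#' ranked first by every method scores exactly 1.
#'
#' @param results A long tibble with columns `gene`, `method`, `rank` — e.g.
#'   row-bound outputs of [delta_ct()], [bestkeeper()], [normfinder()] and
#'   `tidy()` of [genorm()] — or a wide data frame with a `gene` column and
#'   one rank column per method.
#' @return A tibble `gene`, `geomean`, `final_rank`, sorted by `final_rank`.
#' @export
consensus_rank <- function(results) {
  results <- as_tibble(results)
  if (!"gene" %in% names(results)) abort("consensus_rank needs a 'gene' column")
  if (!all(c("method", "rank") %in% names(results))) {
    # wide layout: every non-gene column is a method's rank vector
    results <- results |>
      tidyr::pivot_longer(-"gene", names_to = "method", values_to = "rank")
  }
  if (anyNA(results$rank) || any(results$rank < 1)) {
    abort("ranks must be positive and present for every gene and method")
  }
  per_method <- split(results$gene, results$method)
  universe <- per_method[[1]]
  for (g in per_method) {
    if (!setequal(g, universe) || length(g) != length(universe)) {
      abort("all methods must cover the same gene set")
    }
  }
  results |>
    group_by(.data$gene) |>
    summarise(geomean = exp(mean(log(.data$rank))), .groups = "drop") |>
    mutate(final_rank = rank_by_value(.data$geomean, .data$gene)) |>
    arrange(.data$final_rank)
}

#' Run the full RT-qPCR stability panel
#'
#' One-stop evaluation of a candidate reference-gene panel: BestKeeper,
#' comparative delta-Ct, geNorm (on relative quantities) and NormFinder, plus
#' the geometric-mean consensus of their ranks — the standard comprehensive
#' stability report.
#'
#' @param cq Cq table (complete rows; genes with missing cells are dropped
#'   with a warning).
#' @param design Optional sample design; enables grouped NormFinder.
#' @param efficiencies Optional assay table or named vector of per-gene
#'   amplification efficiencies, used for the geNorm quantity transform when
#'   `genorm_use_efficiencies = TRUE`; the default transform assumes perfect
#'   doubling (E = 2).
#' @param use_groups Grouped NormFinder model? Defaults to `TRUE` when a
#'   design is supplied.
#' @param bestkeeper_dispersion Passed to [bestkeeper()].
#' @param genorm_use_efficiencies Use per-gene efficiencies in the geNorm
#'   transform (default `FALSE`).
#' @param v_cutoff Pairwise-variation cutoff for the optimal gene number.
#' @return A tibble of class `stability_panel` with one row per gene:
#'   `gene`, `<method>_value` and `<method>_rank` for the four methods,
#'   `geomean` and `final_rank`, sorted by consensus rank. The underlying
#'   `genorm_fit` (with the pairwise-variation curve and optimal gene number)
#'   is attached as the `"genorm_fit"` attribute and summarised by `glance()`.
#' @export
rank_stability <- function(cq, design = NULL, efficiencies = NULL,
                           use_groups = !is.null(design),
                           bestkeeper_dispersion = c("mad", "sd"),
                           genorm_use_efficiencies = FALSE,
                           v_cutoff = 0.15) {
  cq <- drop_incomplete_genes(cq, "stability panel")
  bk <- bestkeeper(cq, dispersion = bestkeeper_dispersion)
  dc <- delta_ct(cq)
  q <- relative_quantities(
    cq, efficiencies = if (genorm_use_efficiencies) efficiencies else NULL)
  gn <- genorm(q, v_cutoff = v_cutoff)
  nf <- normfinder(cq, design = design, use_groups = use_groups)

  long <- bind_rows(
    select(bk, all_of(c("gene", "method", "stability", "rank"))),
    dc,
    tidy(gn),
    nf
  )
  consensus <- consensus_rank(select(long, all_of(c("gene", "method", "rank"))))

  wide <- long |>
    tidyr::pivot_wider(names_from = "method",
                       values_from = c("stability", "rank"),
                       names_glue = "{method}_{.value}") |>
    rename(bestkeeper_value = "bestkeeper_stability",
           deltact_value = "delta_ct_stability",
           deltact_rank = "delta_ct_rank",
           genorm_value = "genorm_stability",
           normfinder_value = "normfinder_stability") |>
    left_join(consensus, by = "gene") |>
    arrange(.data$final_rank) |>
    select(all_of(c("gene",
                    "bestkeeper_value", "bestkeeper_rank",
                    "deltact_value", "deltact_rank",
                    "genorm_value", "genorm_rank",
                    "normfinder_value", "normfinder_rank",
                    "geomean", "final_rank")))
  attr(wide, "genorm_fit") <- gn
  class(wide) <- c("stability_panel", class(wide))
  wide
}

#' @export
glance.stability_panel <- function(x, ...) {
  glance(attr(x, "genorm_fit")) |>
    mutate(best_gene = x$gene[x$final_rank == 1],
           best_geomean = x$geomean[x$final_rank == 1])
}

#' @export
tidy.stability_panel <- function(x, ...) {
  x |>
    as_tibble() |>
    select(all_of(c("gene", "bestkeeper_value", "bestkeeper_rank",
                    "deltact_value", "deltact_rank",
                    "genorm_value", "genorm_rank",
                    "normfinder_value", "normfinder_rank"))) |>
    tidyr::pivot_longer(-"gene",
                        names_to = c("method", ".value"),
                        names_pattern = "(.*)_(value|rank)") |>
    rename(stability = "value")
}
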