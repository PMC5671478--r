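#' Quality-control filtering of RT-qPCR candidate assays
#'
#' Screens candidate primer assays against the standard acceptance rule before
#' any stability analysis: amplification efficiency strictly above
#' `min_efficiency` (1.8 by default; 2 is perfect per-cycle doubling),
#' calibration-curve R-squared strictly above `min_r2` (0.99), and — when a Cq
#' table is supplied — every observed Cq strictly below `max_cq` (40), which
#' guarantees a quantifiable expression level in all conditions.
#'
#' @param assays Tibble with columns `gene`, `efficiency` and `r2`
#'   (see [read_assay_table()]).
#' @param cq Optional Cq table; when given, the `max_cq` rule is applied and a
#'   missing Cq counts as a failure (the well never crossed threshold).
#' @param min_efficiency,min_r2,max_cq Rule thresholds.
#' @return A tibble with one row per assay: `gene`, `efficiency`, `r2`,
#'   `max_cq_observed` (`NA` without a Cq table), logical `passed`, and a
#'   `reason` string for rejected assays.
#' @export
qc_candidates <- function(assays, cq = NULL,
                          min_efficiency = 1.8, min_r2 = 0.99, max_cq = 40) {
  stopifnot(min_efficiency > 1, min_efficiency <= 2.2,
            min_r2 > 0, min_r2 <= 1)
  assays <- as_tibble(assays)
  if (!all(c("gene", "efficiency") %in% names(assays))) {
    abort("assays must have 'gene' and 'efficiency' columns")
  }
  if (!"r2" %in% names(assays)) assays$r2 <- NA_real_

  if (!is.null(cq)) {
    m <- cq_values(cq)
    maxcq <- apply(m, 1, function(x) if (anyNA(x)) NA_real_ else max(x))
    assays$max_cq_observed <- unname(maxcq[assays$gene])
    cq_ok <- !is.na(assays$max_cq_observed) & assays$max_cq_observed < max_cq
  } else {
    assays$max_cq_observed <- NA_real_
    cq_ok <- rep(TRUE, nrow(assays))
  }

  eff_ok <- !is.na(assays$efficiency) & assays$efficiency > min_efficiency
  r2_ok <- !is.na(assays$r2) & assays$r2 > min_r2

  reason <- purrr::pmap_chr(
    list(eff_ok, r2_ok, cq_ok,
         is.na(assays$efficiency) | is.na(assays$r2)),
    function(e, r, c, miss) {
      if (miss) return("missing efficiency or r2")
      fails <- c(if (!e) "efficiency", if (!r) "r2", if (!c) "max_cq")
      if (length(fails) == 0) NA_character_ else paste(fails, collapse = ",")
    })

  assays |>
    mutate(passed = eff_ok & r2_ok & cq_ok, reason = reason)
}

#' Descriptive statistics of Cq values per gene
#'
#' Per-gene mean, sample SD, range, quartiles (linear interpolation) and
#' interquartile range of quantification-cycle values — the box-plot view of
#' candidate variability. Genes with any missing Cq are skipped with a
#' warning.
#'
#' @param cq Cq table (see [read_cq_table()]).
#' @return A tibble with columns `gene`, `mean`, `sd`, `min`, `p25`, `p75`,
#'   `max`, `iqr`, ordered as in the input.
#' @export
cq_descriptives <- function(cq) {
  cq <- drop_incomplete_genes(cq, "Cq descriptives")
  m <- cq_values(cq)
  purrr::map_dfr(rownames(m), function(g) {
    x <- m[g, ]
    q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
    tibble(gene = g, mean = mean(x), sd = sd(x),
           min = min(x), p25 = q[1], p75 = q[2], max = max(x),
           iqr = q[2] - q[1])
  })
}

#' Transform Cq values to within-gene relative quantities
#'
#' The standard geNorm input transform: for each gene, the sample with the
#' lowest Cq (highest expression) is set to quantity 1 and every other sample
#' to `E^(Cq_min - Cq)`, where `E` is the per-cycle amplification efficiency
#' (2 = perfect doubling, the default when no efficiency is given).
#'
#' @param cq Cq table; genes with missing cells are dropped with a warning.
#' @param efficiencies Optional assay table (`gene`, `efficiency`) or a named
#'   numeric vector of efficiencies; genes absent from it get `default_e`.
#' @param default_e Efficiency used when none is supplied (default 2).
#' @return A tibble shaped like `cq` whose values are relative quantities in
#'   `(0, 1]`, with the per-gene efficiencies in the `"efficiency_used"`
#'   attribute (a named vector).
#' @export
relative_quantities <- function(cq, efficiencies = NULL, default_e = 2) {
  cq <- drop_incomplete_genes(cq, "relative quantities")
  m <- cq_values(cq)
  e <- setNames(rep(default_e, nrow(m)), rownames(m))
  if (!is.null(efficiencies)) {
    if (is.data.frame(efficiencies)) {
      ev <- setNames(efficiencies$efficiency, efficiencies$gene)
    } else {
      ev <- efficiencies
    }
    hit <- intersect(names(ev), names(e))
    e[hit] <- ev[hit]
  }
  if (any(is.na(e) | e <= 1)) {
    abort(paste0("amplification efficiency must be > 1; offending gene(s): ",
                 paste(names(e)[is.na(e) | e <= 1], collapse = ", ")))
  }
  q <- m
  for (g in rownames(m)) {
    q[g, ] <- e[g]^(min(m[g, ]) - m[g, ])
  }
  out <- dplyr::bind_cols(tibble(gene = rownames(q)), as_tibble(q))
  attr(out, "efficiency_used") <- e
  out
}
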