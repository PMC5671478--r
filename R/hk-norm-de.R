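#' Per-sample normalization factors from reference genes
#'
#' The classic internal-control normalizer: each sample's factor is the
#' geometric mean of the chosen reference genes' expression in that sample.
#' Dividing a sample's column by its factor removes between-sample technical
#' scale, on the assumption that the reference genes are truly stable.
#'
#' @param mat Expression matrix tibble.
#' @param hk_ids Character vector of reference transcript ids; every one must
#'   be present and strictly positive in every sample.
#' @return A tibble `sample`, `factor` with the reference ids in the
#'   `"hk_ids"` attribute.
#' @export
normalization_factors <- function(mat, hk_ids) {
  v <- expr_values(mat)
  missing <- setdiff(hk_ids, rownames(v))
  if (length(missing) > 0) {
    abort(paste0("reference gene(s) not in matrix: ", paste(missing, collapse = ", ")))
  }
  h <- v[hk_ids, , drop = FALSE]
  if (any(h <= 0)) {
    bad <- which(h <= 0, arr.ind = TRUE)[1, ]
    abort(paste0("reference gene '", hk_ids[bad[1]], "' is not expressed in sample '",
                 colnames(h)[bad[2]], "'"))
  }
  out <- tibble(sample = colnames(h),
                factor = unname(exp(colMeans(log(h)))))
  attr(out, "hk_ids") <- hk_ids
  out
}

#' Reference-gene-normalized fold-change differential expression calls
#'
#' Re-evaluates differential expression with reference-gene normalization:
#' every sample's expression is divided by its normalization factor (the
#' geometric mean of the reference genes, see [normalization_factors()]), the
#' normalized values are averaged per condition group, and the fold change
#' `treat / control` is called `up` when strictly above `fc_threshold`, `down`
#' when strictly below its reciprocal, and `ns` otherwise. Genes whose control
#' mean is zero get an undefined fold change and an `ns` call (trace
#' expression cannot support a ratio), with a warning.
#'
#' @param mat Expression matrix tibble.
#' @param design Sample design covering the matrix samples.
#' @param hk_ids Reference transcript ids used for normalization.
#' @param treat,control Group labels to contrast.
#' @param fc_threshold Fold-change call threshold (default 2; strict
#'   comparisons).
#' @param group_mean `"arithmetic"` (default) or `"geometric"` mean of the
#'   normalized values within each group.
#' @return A tibble of class `de_calls`: `gene`, `mean_treat`, `mean_control`
#'   (normalized group means), `fc`, `log2fc`, `call` (`up`/`down`/`ns`),
#'   `method_label`.
#' @export
relative_de <- function(mat, design, hk_ids, treat, control,
                        fc_threshold = 2.0,
                        group_mean = c("arithmetic", "geometric")) {
  group_mean <- match.arg(group_mean)
  stopifnot(fc_threshold > 1)
  v <- expr_values(mat)
  design <- validate_sample_design(design)
  if (!all(colnames(v) %in% design$sample)) {
    abort("design does not cover all matrix samples")
  }
  grp <- setNames(design$group, design$sample)[colnames(v)]
  t_cols <- colnames(v)[grp == treat]
  c_cols <- colnames(v)[grp == control]
  if (length(t_cols) == 0) abort(paste0("no samples in treatment group '", treat, "'"))
  if (length(c_cols) == 0) abort(paste0("no samples in control group '", control, "'"))

  nf <- normalization_factors(mat, hk_ids)
  fac <- setNames(nf$factor, nf$sample)[colnames(v)]
  norm <- sweep(v, 2, fac, "/")

  gmean <- function(x) if (any(x <= 0)) NA_real_ else exp(mean(log(x)))
  mfun <- if (group_mean == "arithmetic") mean else gmean

  mt <- apply(norm[, t_cols, drop = FALSE], 1, mfun)
  mc <- apply(norm[, c_cols, drop = FALSE], 1, mfun)

  fc <- ifelse(!is.na(mc) & mc > 0, mt / mc, NA_real_)
  undef <- is.na(fc)
  if (any(undef)) {
    warn(paste0("fold change undefined (zero/degenerate control mean) for: ",
                paste(rownames(v)[undef], collapse = ", ")))
  }
  call <- dplyr::case_when(
    is.na(fc) ~ "ns",
    fc > fc_threshold ~ "up",
    fc < 1 / fc_threshold ~ "down",
    TRUE ~ "ns"
  )
  out <- tibble(gene = rownames(v),
                mean_treat = unname(mt),
                mean_control = unname(mc),
                fc = unname(fc),
                log2fc = log2(unname(fc)),
                call = call,
                method_label = paste0("hk:", paste(hk_ids, collapse = "+")))
  class(out) <- c("de_calls", class(out))
  out
}

#' Read an external differential-expression table
#'
#' Plain TSV/CSV with a gene column and either `fc` or `log2fc`; an optional
#' `significant` flag column restricts non-`ns` calls to flagged genes.
#'
#' @param path Path to the table.
#' @param fc_threshold Fold-change call threshold (strict, default 2).
#' @param method_label Label recorded on the calls (default `"external"`).
#' @return A `de_calls` tibble comparable with [relative_de()] output.
#' @export
read_de_table <- function(path, fc_threshold = 2.0, method_label = "external") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, comment = "#",
                           show_col_types = FALSE, progress = FALSE)
  idcol <- id_column(raw, c("gene", "gene_id", "transcript_id"))
  names(raw)[names(raw) == idcol] <- "gene"
  if ("fc" %in% names(raw)) {
    fc <- as.numeric(raw$fc)
  } else if ("log2fc" %in% names(raw)) {
    fc <- 2^as.numeric(raw$log2fc)
  } else {
    abort("external DE table needs an 'fc' or 'log2fc' column")
  }
  sig <- if ("significant" %in% names(raw)) as.logical(raw$significant) else TRUE
  call <- dplyr::case_when(
    is.na(fc) | !sig ~ "ns",
    fc > fc_threshold ~ "up",
    fc < 1 / fc_threshold ~ "down",
    TRUE ~ "ns"
  )
  out <- tibble(gene = as.character(raw$gene),
                mean_treat = NA_real_, mean_control = NA_real_,
                fc = fc, log2fc = log2(fc), call = call,
                method_label = method_label)
  class(out) <- c("de_calls", class(out))
  out
}

#' Concordance between two sets of differential-expression calls
#'
#' Gene-by-gene comparison of two `de_calls` tables over the same gene
#' universe. Genes agreeing on the call (`up`/`down`/`ns`) are concordant;
#' genes with different calls but the same fold-change direction count as
#' same-direction/different-magnitude; the rest are discordant.
#'
#' @param a,b `de_calls` tibbles covering the same genes (e.g. reference-gene
#'   normalized calls vs an external pipeline's calls).
#' @return An object of class `de_concordance`: a list with `per_gene` (tibble
#'   `gene`, `call_a`, `call_b`, `fc_a`, `fc_b`, `agreement`) and the counts
#'   `n_same_call`, `n_same_direction_diff_magnitude`, `n_discordant`.
#'   `tidy()` returns the per-gene table, `glance()` the counts.
#' @export
concordance <- function(a, b) {
  if (!setequal(a$gene, b$gene) || nrow(a) != nrow(b)) {
    abort("the two call sets must cover the same gene universe")
  }
  b <- b[match(a$gene, b$gene), ]
  agreement <- dplyr::case_when(
    a$call == b$call ~ "same_call",
    sign(a$log2fc) == sign(b$log2fc) &
      !is.na(a$log2fc) & !is.na(b$log2fc) ~ "same_direction_diff_magnitude",
    TRUE ~ "discordant"
  )
  per_gene <- tibble(gene = a$gene,
                     call_a = a$call, call_b = b$call,
                     fc_a = a$fc, fc_b = b$fc,
                     agreement = agreement)
  structure(list(per_gene = per_gene,
                 n_same_call = sum(agreement == "same_call"),
                 n_same_direction_diff_magnitude =
                   sum(agreement == "same_direction_diff_magnitude"),
                 n_discordant = sum(agreement == "discordant")),
            class = "de_concordance")
}

#' @export
print.de_concordance <- function(x, ...) {
  cat("DE call concordance over", nrow(x$per_gene), "genes:\n")
  cat("  same call:                      ", x$n_same_call, "\n")
  cat("  same direction, diff magnitude: ", x$n_same_direction_diff_magnitude, "\n")
  cat("  discordant:                     ", x$n_discordant, "\n")
  invisible(x)
}

#' @rdname concordance
#' @param x A `de_concordance` object.
#' @param ... Unused.
#' @export
tidy.de_concordance <- function(x, ...) x$per_gene

#' @rdname concordance
#' @export
glance.de_concordance <- function(x, ...) {
  tibble(n_genes = nrow(x$per_gene),
         n_same_call = x$n_same_call,
         n_same_direction_diff_magnitude = x$n_same_direction_diff_magnitude,
         n_discordant = x$n_discordant)
}
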