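# Internal validators for the package's tabular containers.
#
# Containers are ordinary tibbles so they compose with dplyr:
#   * expression matrix: `transcript_id` + one numeric column per sample
#   * Cq table:          `gene` + one numeric column per sample (NA = missing)
#   * sample design:     `sample`, `group`, `replicate`
#   * assay table:       `gene`, `efficiency`, `r2`
#   * isoform index:     `transcript_id`, `gene_id`, `isoform_count`

id_column <- function(x, candidates) {
  hit <- intersect(candidates, names(x))
  if (length(hit) == 0) {
    abort(paste0("expected an id column named one of: ",
                 paste(candidates, collapse = ", ")))
  }
  hit[[1]]
}

#' Validate a transcript-by-sample expression matrix
#'
#' Checks the tibble layout used throughout the package: a `transcript_id`
#' character column followed by one numeric column per sample, with unique
#' transcript and sample identifiers and no negative values.
#'
#' @param x A data frame with a `transcript_id` column and numeric sample
#'   columns.
#' @return `x` as a tibble, invisibly usable downstream.
#' @export
validate_expression_matrix <- function(x) {
  x <- as_tibble(x)
  if (!"transcript_id" %in% names(x)) {
    abort("expression matrix must have a 'transcript_id' column")
  }
  samples <- setdiff(names(x), "transcript_id")
  if (length(samples) == 0) abort("expression matrix has no sample columns")
  if (anyDuplicated(x$transcript_id)) {
    dup <- unique(x$transcript_id[duplicated(x$transcript_id)])
    abort(paste0("duplicate transcript id(s): ", paste(head(dup, 5), collapse = ", ")))
  }
  if (anyDuplicated(samples)) abort("duplicate sample column names")
  for (s in samples) {
    v <- x[[s]]
    if (!is.numeric(v)) abort(paste0("sample column '", s, "' is not numeric"))
    if (anyNA(v)) abort(paste0("sample column '", s, "' contains missing values"))
    if (any(v < 0)) {
      i <- which(v < 0)[1]
      abort(paste0("negative expression value at transcript '",
                   x$transcript_id[i], "', sample '", s, "'"))
    }
  }
  x
}

#' Validate a gene-by-sample Cq table
#'
#' A Cq table holds quantification-cycle values: a `gene` character column and
#' one numeric column per sample. `NA` marks a missing Cq (e.g. a well that
#' never crossed threshold); all present values must be finite.
#'
#' @param x A data frame with a `gene` column and numeric sample columns.
#' @return `x` as a tibble.
#' @export
validate_cq_table <- function(x) {
  x <- as_tibble(x)
  if (!"gene" %in% names(x)) abort("Cq table must have a 'gene' column")
  samples <- setdiff(names(x), "gene")
  if (length(samples) == 0) abort("Cq table has no sample columns")
  if (anyDuplicated(x$gene)) {
    abort(paste0("duplicate gene id(s): ",
                 paste(unique(x$gene[duplicated(x$gene)]), collapse = ", ")))
  }
  for (s in samples) {
    v <- x[[s]]
    if (!is.numeric(v)) abort(paste0("sample column '", s, "' is not numeric"))
    if (any(!is.na(v) & !is.finite(v))) {
      abort(paste0("non-finite Cq in sample column '", s, "'"))
    }
  }
  x
}

#' Validate a sample design sheet
#'
#' @param x A data frame with columns `sample`, `group` and optionally
#'   `replicate` (defaulting to within-group order).
#' @return A tibble with columns `sample`, `group`, `replicate`.
#' @export
validate_sample_design <- function(x) {
  x <- as_tibble(x)
  need <- c("sample", "group")
  if (!all(need %in% names(x))) {
    abort("sample design must have columns 'sample' and 'group'")
  }
  if (anyDuplicated(x$sample)) abort("duplicate sample ids in design")
  if (anyNA(x$group) || any(x$group == "")) abort("every sample needs a group label")
  if (!"replicate" %in% names(x)) {
    x <- x |> group_by(.data$group) |> mutate(replicate = row_number()) |> ungroup()
  }
  if (any(x$replicate < 1)) abort("replicate numbers must be positive")
  x |>
    mutate(sample = as.character(.data$sample),
           group = as.character(.data$group),
           replicate = as.integer(.data$replicate)) |>
    select(all_of(c("sample", "group", "replicate")))
}

# gene-by-sample values as a plain numeric matrix (rownames = gene ids)
cq_values <- function(cq) {
  cq <- validate_cq_table(cq)
  m <- as.matrix(cq[setdiff(names(cq), "gene")])
  storage.mode(m) <- "double"
  rownames(m) <- cq$gene
  m
}

expr_values <- function(mat) {
  mat <- validate_expression_matrix(mat)
  m <- as.matrix(mat[setdiff(names(mat), "transcript_id")])
  storage.mode(m) <- "double"
  rownames(m) <- mat$transcript_id
  m
}

# drop genes with any missing Cq, warning with a reason; complete matrices are
# what the stability algorithms require
drop_incomplete_genes <- function(cq, context = "stability analysis") {
  cq <- validate_cq_table(cq)
  samples <- setdiff(names(cq), "gene")
  incomplete <- cq$gene[apply(is.na(as.matrix(cq[samples])), 1, any)]
  if (length(incomplete) > 0) {
    warn(paste0("excluding gene(s) with missing Cq from ", context, ": ",
                paste(incomplete, collapse = ", ")))
    cq <- cq[!cq$gene %in% incomplete, , drop = FALSE]
  }
  cq
}
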