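#' Read a transcript-by-sample expression table
#'
#' Reads either a plain TSV/CSV whose first column is the transcript id and
#' whose remaining columns are numeric per-sample expression values (FPKM or
#' counts), or a Cufflinks-style `*.fpkm_tracking` file whose FPKM columns are
#' auto-detected by the `_FPKM` suffix convention.
#'
#' @param path Path to the table. Comment lines starting with `#` are skipped.
#' @param dialect `"tsv"` (also handles comma-separated files by extension) or
#'   `"cufflinks_fpkm_tracking"`.
#' @param unit Label recorded on the result: `"FPKM"` or `"count"`.
#' @return A tibble with a `transcript_id` column and one numeric column per
#'   sample, row order preserved; the unit label is stored in the
#'   `"unit_label"` attribute.
#' @export
read_expression_matrix <- function(path,
                                   dialect = c("tsv", "cufflinks_fpkm_tracking"),
                                   unit = "FPKM") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, comment = "#",
                           show_col_types = FALSE, progress = FALSE,
                           trim_ws = TRUE)
  if (dialect == "cufflinks_fpkm_tracking") {
    idcol <- id_column(raw, c("tracking_id", "transcript_id"))
    fpkm_cols <- grep("_FPKM$", names(raw), value = TRUE)
    if (length(fpkm_cols) == 0) abort("no '_FPKM' columns found in tracking file")
    out <- raw[c(idcol, fpkm_cols)]
    names(out) <- c("transcript_id", sub("_FPKM$", "", fpkm_cols))
  } else {
    out <- raw
    names(out)[1] <- "transcript_id"
  }
  out$transcript_id <- as.character(out$transcript_id)
  for (s in setdiff(names(out), "transcript_id")) {
    if (!is.numeric(out[[s]])) {
      bad <- suppressWarnings(as.numeric(out[[s]]))
      if (anyNA(bad)) {
        i <- which(is.na(bad))[1]
        abort(paste0("malformed numeric value '", out[[s]][i], "' at row ", i,
                     ", column '", s, "'"))
      }
      out[[s]] <- bad
    }
  }
  out <- validate_expression_matrix(out)
  attr(out, "unit_label") <- unit
  out
}

#' Read a sample design sheet
#'
#' Expects a TSV/CSV with header `sample,group,replicate` (replicate optional).
#'
#' @param path Path to the design sheet.
#' @return A tibble with columns `sample`, `group`, `replicate`.
#' @export
read_sample_design <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, comment = "#",
                           show_col_types = FALSE, progress = FALSE,
                           trim_ws = TRUE)
  validate_sample_design(raw)
}

#' Read a table of quantification-cycle (Cq) values
#'
#' The wide layout is a gene-by-sample grid (first column the gene id). The
#' long layout has one row per well with columns `gene`, `sample`,
#' `replicate`, `cq`; replicate wells are averaged arithmetically on the Cq
#' scale to one value per gene and sample (or combined as the
#' geometric mean of relative quantities with `aggregate = "geomean_quantity"`,
#' which at a common efficiency is again the arithmetic Cq mean).
#' Non-numeric Cq entries such as `"ND"` are treated as missing; a gene-sample
#' cell with no usable replicate is marked missing with a warning.
#'
#' @param path Path to the Cq table.
#' @param layout `"wide"` or `"long"`.
#' @param aggregate Replicate aggregation for the long layout: `"mean_cq"`
#'   (default, field convention) or `"geomean_quantity"`.
#' @return A tibble with a `gene` column and one numeric sample column per
#'   sample; `NA` marks missing cells.
#' @export
read_cq_table <- function(path, layout = c("wide", "long"),
                          aggregate = c("mean_cq", "geomean_quantity")) {
  layout <- match.arg(layout)
  aggregate <- match.arg(aggregate)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, comment = "#",
                           show_col_types = FALSE, progress = FALSE,
                           trim_ws = TRUE,
                           col_types = readr::cols(.default = readr::col_character()))
  as_cq_num <- function(v) suppressWarnings(as.numeric(v))
  if (layout == "wide") {
    names(raw)[1] <- "gene"
    out <- raw
    for (s in setdiff(names(out), "gene")) out[[s]] <- as_cq_num(out[[s]])
    return(validate_cq_table(out))
  }
  idcol <- id_column(raw, c("gene", "gene_id"))
  names(raw)[names(raw) == idcol] <- "gene"
  if (!all(c("sample", "cq") %in% names(raw))) {
    abort("long Cq layout needs columns gene, sample, cq (replicate optional)")
  }
  raw$cq <- as_cq_num(raw$cq)
  agg <- raw |>
    group_by(.data$gene, .data$sample) |>
    summarise(cq = {
      v <- .data$cq[!is.na(.data$cq)]
      if (length(v) == 0) NA_real_
      # geometric mean of E^-Cq quantities back-converted to the Cq scale is
      # the arithmetic Cq mean for any fixed efficiency; both modes therefore
      # reduce to mean(v), kept distinct to make the intent explicit
      else mean(v)
    }, .groups = "drop")
  empty <- agg |> filter(is.na(.data$cq))
  if (nrow(empty) > 0) {
    warn(paste0("Cq cell(s) with no usable replicate marked missing: ",
                paste(paste0(empty$gene, "/", empty$sample), collapse = ", ")))
  }
  out <- agg |>
    tidyr::pivot_wider(names_from = "sample", values_from = "cq") |>
    arrange(match(.data$gene, unique(raw$gene)))
  validate_cq_table(out)
}

#' Read a primer assay table (efficiencies and calibration R-squared)
#'
#' @param path TSV/CSV with columns `gene`, `efficiency` and optionally `r2`.
#' @return A tibble with columns `gene`, `efficiency`, `r2` (`NA` when absent).
#' @export
read_assay_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, comment = "#",
                           show_col_types = FALSE, progress = FALSE,
                           trim_ws = TRUE)
  idcol <- id_column(raw, c("gene", "gene_id"))
  names(raw)[names(raw) == idcol] <- "gene"
  if (!"efficiency" %in% names(raw)) abort("assay table needs an 'efficiency' column")
  if (!"r2" %in% names(raw)) raw$r2 <- NA_real_
  raw |>
    mutate(gene = as.character(.data$gene),
           efficiency = as.numeric(.data$efficiency),
           r2 = as.numeric(.data$r2)) |>
    select(all_of(c("gene", "efficiency", "r2")))
}

#' Write a tibble as TSV with a provenance comment header
#'
#' All package writers emit a first line `#stableref <version> <command>` so
#' outputs are self-describing; the package readers skip `#` comments.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param command Free-text provenance note recorded in the header.
#' @return `path`, invisibly.
#' @export
write_stableref_tsv <- function(x, path, command = "write") {
  ver <- as.character(utils::packageVersion("stableref"))
  writeLines(paste("#stableref", ver, command), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Write an expression matrix as TSV
#'
#' @param mat Expression matrix tibble (see [read_expression_matrix()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  mat <- validate_expression_matrix(mat)
  write_stableref_tsv(mat, path, command = "expression-matrix")
}
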