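#' Build a transcript-to-gene isoform index from a GTF annotation
#'
#' Counts, for every gene, how many distinct transcript isoforms the
#' annotation declares. Multi-isoform genes are problematic reference-gene
#' candidates: isoforms of one gene can differ wildly in expression level and
#' stability, and primers often cannot distinguish them. Only the `gene_id`
#' and `transcript_id` attributes are used; coordinates and strand are
#' irrelevant here.
#'
#' @param gtf_path Path to a GTF file with `gene_id` and `transcript_id`
#'   attributes on transcript or exon features.
#' @return A tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `isoform_count` (number of distinct transcripts of that gene).
#' @export
build_isoform_index <- function(gtf_path) {
  if (!file.exists(gtf_path)) abort(paste0("file not found: ", gtf_path))
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("build_isoform_index needs the 'rtracklayer' package")
  }
  gr <- tryCatch(rtracklayer::import(gtf_path, format = "gtf"),
                 error = function(e) {
                   abort(paste0("empty or malformed GTF '", gtf_path, "': ",
                                conditionMessage(e)))
                 })
  if (length(gr) == 0) abort("empty GTF: no features parsed")
  meta <- as.data.frame(gr@elementMetadata)
  if (!all(c("gene_id", "transcript_id") %in% names(meta))) {
    abort("GTF lacks gene_id/transcript_id attributes")
  }
  tbl <- tibble(gene_id = as.character(meta$gene_id),
                transcript_id = as.character(meta$transcript_id))
  bad <- is.na(tbl$gene_id) | is.na(tbl$transcript_id) |
    tbl$gene_id == "" | tbl$transcript_id == ""
  if (any(bad)) {
    warn(paste0("skipping ", sum(bad), " feature(s) lacking gene_id or transcript_id"))
    tbl <- tbl[!bad, , drop = FALSE]
  }
  if (nrow(tbl) == 0) abort("GTF has no features with both gene_id and transcript_id")
  tbl <- dplyr::distinct(tbl, .data$transcript_id, .data$gene_id)
  if (anyDuplicated(tbl$transcript_id)) {
    abort("a transcript_id maps to more than one gene_id in the GTF")
  }
  tbl |>
    group_by(.data$gene_id) |>
    mutate(isoform_count = dplyr::n_distinct(.data$transcript_id)) |>
    ungroup() |>
    arrange(.data$gene_id, .data$transcript_id) |>
    select(all_of(c("transcript_id", "gene_id", "isoform_count")))
}
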