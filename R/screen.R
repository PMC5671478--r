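#' Per-transcript expression stability statistics
#'
#' Computes, for every transcript of an expression matrix, the descriptive
#' statistics on which genome-wide reference-gene screening rests: mean and SD
#' of expression, coefficient of variation (CV, percent), maximum fold change
#' (MFC, max/min across samples), the CV of log-transformed expression, and a
#' constitutive-expression flag (detected above `detect_threshold` in every
#' sample).
#'
#' MFC and the log-scale statistics are only defined for constitutive
#' transcripts (a zero in any sample makes the ratio and the log undefined);
#' they are `NA` otherwise. By default MFC is taken across individual samples,
#' the stricter convention; `mfc_scope = "group_mean"` takes it across
#' condition means instead (requires `design`).
#'
#' @param mat Expression matrix tibble: `transcript_id` plus numeric sample
#'   columns (see [read_expression_matrix()]).
#' @param detect_threshold Detection threshold: a transcript counts as
#'   expressed in a sample when its value is strictly greater. Default 0.
#' @param sd_denom `"n-1"` (sample SD, default) or `"n"` (population SD).
#' @param log_base Base of the log transform for the log-CV statistic: 2
#'   (default), 10 or `exp(1)`.
#' @param pseudocount Added before the log transform; 0 by default because the
#'   constitutive flag already guarantees positive values where the log is
#'   taken. Useful for count matrices.
#' @param mfc_scope `"sample"` (default) or `"group_mean"`.
#' @param design Sample design tibble, required for `mfc_scope = "group_mean"`.
#' @param isoforms Optional isoform index from [build_isoform_index()]; when
#'   supplied, an `isoform_count` column is joined on transcript id.
#' @return A tibble with one row per transcript: `transcript_id`, `mean_expr`,
#'   `sd_expr`, `cv`, `log_mean`, `log_cv_abs`, `mfc`, `constitutive`,
#'   `n_samples_expressed` and (optionally) `isoform_count`. CV fields are in
#'   percent.
#' @export
transcript_stats <- function(mat, detect_threshold = 0,
                             sd_denom = c("n-1", "n"),
                             log_base = 2, pseudocount = 0,
                             mfc_scope = c("sample", "group_mean"),
                             design = NULL, isoforms = NULL) {
  sd_denom <- match.arg(sd_denom)
  mfc_scope <- match.arg(mfc_scope)
  v <- expr_values(mat)
  n <- ncol(v)
  if (n < 2) abort("at least two samples are required (SD undefined for one)")

  sd_fun <- if (sd_denom == "n-1") {
    function(x) sd(x)
  } else {
    function(x) sqrt(mean((x - mean(x))^2))
  }

  if (mfc_scope == "group_mean") {
    if (is.null(design)) abort("mfc_scope = 'group_mean' requires a design")
    design <- validate_sample_design(design)
    if (!setequal(design$sample, colnames(v))) {
      abort("design samples do not match matrix samples")
    }
    grp <- design$group[match(colnames(v), design$sample)]
    mfc_basis <- t(apply(v, 1, function(x) tapply(x, grp, mean)))
  } else {
    mfc_basis <- v
  }

  one <- function(i) {
    x <- v[i, ]
    m <- mean(x)
    s <- sd_fun(x)
    expressed <- x > detect_threshold
    const <- all(expressed)
    b <- mfc_basis[i, ]
    mfc <- if (const && all(b > detect_threshold)) max(b) / min(b) else NA_real_
    if (const) {
      lx <- log(x + pseudocount, base = log_base)
      lm <- mean(lx)
      lcv <- if (lm != 0) 100 * abs(sd_fun(lx) / lm) else NA_real_
    } else {
      lm <- NA_real_
      lcv <- NA_real_
    }
    tibble(mean_expr = m, sd_expr = s,
           cv = if (m > 0) 100 * s / m else NA_real_,
           log_mean = lm, log_cv_abs = lcv, mfc = mfc,
           constitutive = const,
           n_samples_expressed = sum(expressed))
  }

  out <- dplyr::bind_cols(tibble(transcript_id = rownames(v)),
                          purrr::map_dfr(seq_len(nrow(v)), one))
  if (!is.null(isoforms)) {
    out <- left_join(out,
                     select(as_tibble(isoforms),
                            all_of(c("transcript_id", "isoform_count"))),
                     by = "transcript_id")
  }
  out
}

#' Select stably expressed transcripts
#'
#' Applies the stable-expression filter cascade to the output of
#' [transcript_stats()]: a transcript is kept when it is constitutively
#' expressed, its maximum fold change is below `mfc_max`, and either its
#' expression CV is below `cv_max` or the absolute CV of its log-transformed
#' expression is below `logcv_max`. The per-filter ledger records which clause
#' admitted each transcript.
#'
#' @param stats Tibble from [transcript_stats()].
#' @param cv_max CV threshold in percent (default 20; a relaxed screen uses 30).
#' @param mfc_max Maximum fold change threshold (default 2).
#' @param logcv_max Log-CV threshold in percent (default 5).
#' @return `stats` with logical ledger columns `pass_constitutive`,
#'   `pass_mfc`, `pass_cv`, `pass_logcv`, the overall `passed`, and
#'   `pass_clause` (`"cv"`, `"log_cv"`, `"both"` or `NA` when not kept).
#' @export
select_stable <- function(stats, cv_max = 20, mfc_max = 2, logcv_max = 5) {
  stopifnot(cv_max > 0, mfc_max > 0, logcv_max > 0)
  stats |>
    mutate(
      pass_constitutive = .data$constitutive,
      pass_mfc = !is.na(.data$mfc) & .data$mfc < mfc_max,
      pass_cv = !is.na(.data$cv) & .data$cv < cv_max,
      pass_logcv = !is.na(.data$log_cv_abs) & .data$log_cv_abs < logcv_max,
      passed = .data$pass_constitutive & .data$pass_mfc &
        (.data$pass_cv | .data$pass_logcv),
      pass_clause = dplyr::case_when(
        !.data$passed ~ NA_character_,
        .data$pass_cv & .data$pass_logcv ~ "both",
        .data$pass_cv ~ "cv",
        TRUE ~ "log_cv"
      )
    )
}

#' Rank recommended reference-gene candidates
#'
#' The full recommendation rule for picking reference genes off a
#' transcriptome screen: stable expression (see [select_stable()]), a mean
#' expression level inside a practical window (high enough to quantify
#' reliably, low enough not to exhaust reagents; default 50-1000 expression
#' units, with 100-1000 a common stricter choice), and — because isoforms of
#' one gene can behave very differently and confound primer design — a unique
#' transcript isoform. The result is ranked by ascending CV, ties broken by
#' transcript id.
#'
#' @param stats Tibble from [transcript_stats()].
#' @param index Optional isoform index from [build_isoform_index()]; required
#'   when `require_unique_isoform = TRUE` unless `stats` already carries an
#'   `isoform_count` column. Transcripts with unknown isoform status are
#'   excluded (with a warning) while uniqueness is required.
#' @param expr_min,expr_max Mean-expression window (defaults 50 and 1000).
#' @param require_unique_isoform Keep only single-isoform genes (default TRUE).
#' @inheritParams select_stable
#' @return A tibble of recommended transcripts sorted by ascending `cv`, with
#'   the stats columns and a `recommendation_rank` column.
#' @export
recommend_references <- function(stats, index = NULL,
                                 cv_max = 20, mfc_max = 2, logcv_max = 5,
                                 expr_min = 50, expr_max = 1000,
                                 require_unique_isoform = TRUE) {
  stopifnot(expr_min > 0, expr_min < expr_max)
  if (!is.null(index) && !"isoform_count" %in% names(stats)) {
    stats <- left_join(stats,
                       select(as_tibble(index),
                              all_of(c("transcript_id", "isoform_count"))),
                       by = "transcript_id")
  }
  out <- select_stable(stats, cv_max = cv_max, mfc_max = mfc_max,
                       logcv_max = logcv_max) |>
    filter(.data$passed,
           .data$mean_expr >= expr_min, .data$mean_expr <= expr_max)
  if (require_unique_isoform) {
    if (!"isoform_count" %in% names(out)) {
      abort("isoform uniqueness required but no isoform index supplied")
    }
    unknown <- out$transcript_id[is.na(out$isoform_count)]
    if (length(unknown) > 0) {
      warn(paste0("excluding transcript(s) with unknown isoform status: ",
                  paste(unknown, collapse = ", ")))
    }
    out <- filter(out, !is.na(.data$isoform_count), .data$isoform_count == 1)
  }
  out |>
    arrange(.data$cv, .data$transcript_id) |>
    mutate(recommendation_rank = row_number())
}

#' Overlap of the top-n most stable transcripts under two metrics
#'
#' Measures method consistency: how many of the `n` transcripts with the
#' smallest values of one stability metric are also in the top `n` of
#' another (e.g. CV of FPKM vs CV of read counts vs CV of log FPKM). Ties are
#' broken by transcript id so the selection is deterministic.
#'
#' @param stats Tibble with a `transcript_id` column and the two metric
#'   columns.
#' @param metric_a,metric_b Names (unquoted or character) of the two metric
#'   columns; smaller = more stable.
#' @param n Size of the top lists; must not exceed the number of transcripts.
#' @return The overlap fraction in `[0, 1]`.
#' @export
top_overlap <- function(stats, metric_a, metric_b, n) {
  a <- rlang::as_name(rlang::enquo(metric_a))
  b <- rlang::as_name(rlang::enquo(metric_b))
  stats <- as_tibble(stats)
  if (n > nrow(stats)) abort("n exceeds the number of transcripts")
  if (n < 1) abort("n must be positive")
  top_ids <- function(metric) {
    stats |>
      arrange(.data[[metric]], .data$transcript_id) |>
      dplyr::slice_head(n = n) |>
      pull("transcript_id")
  }
  length(intersect(top_ids(a), top_ids(b))) / n
}

#' Partition transcripts into low- and high-expression classes
#'
#' @param stats Tibble from [transcript_stats()].
#' @param cutoff Mean-expression cutoff; `mean_expr < cutoff` is "low"
#'   (default 1, the conventional FPKM floor below which expression is
#'   considered negligible).
#' @return `stats` with an added `expression_class` factor (`"low"`/`"high"`).
#' @export
partition_by_expression <- function(stats, cutoff = 1.0) {
  stats |>
    mutate(expression_class = factor(
      ifelse(.data$mean_expr < cutoff, "low", "high"),
      levels = c("low", "high")))
}

#' Summarise a genome-wide screen
#'
#' Collapses a screened stats table (output of [select_stable()]) into the
#' headline numbers of a reference-gene screen: how many transcripts were
#' measured, how many are constitutive, how many pass the stability filter,
#' and the corresponding percentages (rounded to two decimals, as
#' conventionally reported).
#'
#' @param screened Tibble from [select_stable()] (needs `constitutive` and
#'   `passed` columns).
#' @return A one-row tibble: `n_transcripts`, `n_constitutive`,
#'   `pct_constitutive`, `n_stable`, `pct_stable`.
#' @export
screen_report <- function(screened) {
  if (!all(c("constitutive", "passed") %in% names(screened))) {
    abort("screen_report needs the output of select_stable()")
  }
  n <- nrow(screened)
  if (n == 0) abort("empty screen")
  nc <- sum(screened$constitutive, na.rm = TRUE)
  ns <- sum(screened$passed, na.rm = TRUE)
  tibble(
    n_transcripts = n,
    n_constitutive = nc,
    pct_constitutive = round(100 * nc / n, 2),
    n_stable = ns,
    pct_stable = round(100 * ns / n, 2)
  )
}
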