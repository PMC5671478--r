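#' Run the reference-gene workflow from a configuration file
#'
#' Orchestrates the pipeline stages — genome-wide screening of an expression
#' matrix, RT-qPCR stability ranking of a Cq panel, and reference-gene
#' normalized differential-expression calling — as declared in a single YAML
#' configuration. All inputs for enabled stages are checked before any
#' computation; outputs are TSVs with provenance headers, and a JSON run
#' manifest records digests and record counts for every emitted file.
#'
#' The configuration is a map with an `out_dir` and any of the stage blocks:
#'
#' ```yaml
#' out_dir: results
#' screen:
#'   matrix: fpkm.tsv          # expression table (TSV/CSV)
#'   design: design.tsv        # optional
#'   gtf: annotation.gtf       # optional isoform index
#'   cv_max: 20                # thresholds, all optional
#'   mfc_max: 2
#'   logcv_max: 5
#'   expr_min: 50
#'   expr_max: 1000
#' qpcr:
#'   cq: cq.tsv
#'   layout: wide              # or long
#'   design: design.tsv        # optional: grouped NormFinder
#'   efficiencies: assays.tsv  # optional: QC + geNorm efficiencies
#' normde:
#'   matrix: fpkm.tsv
#'   design: design.tsv
#'   hk: [SSU_S8e, SSU_S4e]    # reference gene ids
#'   treat: PI
#'   control: PN
#'   fc_threshold: 2
#'   compare: external_de.tsv  # optional concordance
#' ```
#'
#' @param config Path to a YAML file or an equivalent named list.
#' @return The run manifest: a list with `started`, `finished`, `config_hash`,
#'   `inputs` (tibble `path`, `md5`), `outputs` (tibble `stage`, `name`,
#'   `path`, `md5`, `n_records`) and per-stage record `counts`; also written
#'   as `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    cfg <- yaml::read_yaml(config)
    cfg_hash <- unname(tools::md5sum(config))
  } else {
    cfg <- config
    cfg_hash <- digest_text(yaml::as.yaml(cfg))
  }
  out_dir <- cfg$out_dir %||% "stableref_out"

  stages <- intersect(c("screen", "qpcr", "normde"), names(cfg))
  if (length(stages) == 0) abort("configuration enables no stage")

  # validate every enabled stage's inputs before any compute
  inputs <- character(0)
  need <- function(block, key, stage) {
    v <- cfg[[block]][[key]]
    if (is.null(v)) {
      abort(paste0("configuration error: stage '", stage, "' needs '", key, "'"))
    }
    v
  }
  for (st in stages) {
    keys <- switch(st, screen = "matrix", qpcr = "cq",
                   normde = c("matrix", "design"))
    for (k in keys) {
      p <- need(st, k, st)
      if (!file.exists(p)) {
        abort(paste0("configuration error: stage '", st, "' input '", k,
                     "' not found: ", p))
      }
      inputs <- c(inputs, p)
    }
    for (k in c("design", "gtf", "efficiencies", "compare")) {
      p <- cfg[[st]][[k]]
      if (!is.null(p)) {
        if (!file.exists(p)) {
          abort(paste0("configuration error: stage '", st, "' input '", k,
                       "' not found: ", p))
        }
        inputs <- c(inputs, p)
      }
    }
  }
  if ("normde" %in% stages) {
    for (k in c("hk", "treat", "control")) need("normde", k, "normde")
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  outputs <- list()
  counts <- list()
  log_stage <- function(stage, msg) {
    message(sprintf("[%s] %s", stage, msg))
  }
  emit <- function(stage, name, x, file) {
    path <- file.path(out_dir, file)
    write_stableref_tsv(x, path, command = paste("run", stage, name))
    outputs[[length(outputs) + 1]] <<-
      tibble(stage = stage, name = name, path = path,
             md5 = unname(tools::md5sum(path)), n_records = nrow(x))
  }

  if ("screen" %in% stages) {
    sc <- cfg$screen
    mat <- read_expression_matrix(sc$matrix,
                                  dialect = sc$dialect %||% "tsv")
    index <- if (!is.null(sc$gtf)) build_isoform_index(sc$gtf) else NULL
    stats <- transcript_stats(mat,
                              detect_threshold = sc$detect_threshold %||% 0,
                              isoforms = index)
    screened <- select_stable(stats,
                              cv_max = sc$cv_max %||% 20,
                              mfc_max = sc$mfc_max %||% 2,
                              logcv_max = sc$logcv_max %||% 5)
    rec <- recommend_references(stats, index = index,
                                cv_max = sc$cv_max %||% 20,
                                mfc_max = sc$mfc_max %||% 2,
                                logcv_max = sc$logcv_max %||% 5,
                                expr_min = sc$expr_min %||% 50,
                                expr_max = sc$expr_max %||% 1000,
                                require_unique_isoform = !is.null(index))
    rep <- screen_report(screened)
    counts$screen <- list(transcripts_in = nrow(stats),
                          constitutive = rep$n_constitutive,
                          stable = rep$n_stable,
                          recommended = nrow(rec))
    log_stage("screen", sprintf(
      "%d transcripts in -> %d constitutive -> %d stable -> %d recommended",
      nrow(stats), rep$n_constitutive, rep$n_stable, nrow(rec)))
    emit("screen", "stats", screened, "screen_stats.tsv")
    emit("screen", "candidates", rec, "screen_candidates.tsv")
    emit("screen", "report", rep, "screen_report.tsv")
  }

  if ("qpcr" %in% stages) {
    qc_cfg <- cfg$qpcr
    cq <- read_cq_table(qc_cfg$cq, layout = qc_cfg$layout %||% "wide")
    design <- if (!is.null(qc_cfg$design)) read_sample_design(qc_cfg$design) else NULL
    assays <- if (!is.null(qc_cfg$efficiencies)) read_assay_table(qc_cfg$efficiencies) else NULL
    if (!is.null(assays)) {
      qc <- qc_candidates(assays, cq = cq,
                          min_efficiency = qc_cfg$min_efficiency %||% 1.8,
                          min_r2 = qc_cfg$min_r2 %||% 0.99,
                          max_cq = qc_cfg$max_cq %||% 40)
      emit("qpcr", "qc", qc, "qpcr_qc.tsv")
      keep <- qc$gene[qc$passed]
      cq <- cq[cq$gene %in% keep, , drop = FALSE]
      log_stage("qpcr", sprintf("%d of %d assays pass QC", length(keep), nrow(qc)))
    }
    panel <- rank_stability(cq, design = design, efficiencies = assays,
                            v_cutoff = qc_cfg$v_cutoff %||% 0.15)
    gn <- attr(panel, "genorm_fit")
    counts$qpcr <- list(genes = nrow(panel), optimal_n = gn$optimal_n)
    log_stage("qpcr", sprintf("%d genes ranked; optimal reference number %d (%s)",
                              nrow(panel), gn$optimal_n, gn$v_flag))
    emit("qpcr", "stability", as_tibble(panel), "qpcr_stability.tsv")
    emit("qpcr", "vcurve", gn$v_curve, "qpcr_vcurve.tsv")
    emit("qpcr", "descriptives", cq_descriptives(cq), "qpcr_descriptives.tsv")
  }

  if ("normde" %in% stages) {
    nd <- cfg$normde
    mat <- read_expression_matrix(nd$matrix, dialect = nd$dialect %||% "tsv")
    design <- read_sample_design(nd$design)
    de <- relative_de(mat, design, hk_ids = unlist(nd$hk),
                      treat = nd$treat, control = nd$control,
                      fc_threshold = nd$fc_threshold %||% 2.0)
    counts$normde <- list(genes = nrow(de),
                          up = sum(de$call == "up"),
                          down = sum(de$call == "down"))
    log_stage("normde", sprintf("%d genes: %d up, %d down",
                                nrow(de), sum(de$call == "up"),
                                sum(de$call == "down")))
    emit("normde", "de", as_tibble(de), "normde_calls.tsv")
    if (!is.null(nd$compare)) {
      ext <- read_de_table(nd$compare, fc_threshold = nd$fc_threshold %||% 2.0)
      cc <- concordance(de, ext)
      counts$normde$same_call <- cc$n_same_call
      log_stage("normde", sprintf(
        "concordance: %d same call, %d same direction, %d discordant",
        cc$n_same_call, cc$n_same_direction_diff_magnitude, cc$n_discordant))
      emit("normde", "concordance", tidy(cc), "normde_concordance.tsv")
    }
  }

  manifest <- list(
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    version = as.character(utils::packageVersion("stableref")),
    config_hash = cfg_hash,
    inputs = tibble(path = unique(inputs),
                    md5 = unname(tools::md5sum(unique(inputs)))),
    outputs = dplyr::bind_rows(outputs),
    counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

digest_text <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}
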