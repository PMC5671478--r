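#' Standard two-tissue, two-treatment sample design
#'
#' The default simulated design: two tissues crossed with
#' infected/control treatment, three biological replicates each — twelve
#' samples in four groups.
#'
#' @param groups Group labels (default `PI`, `XI`, `PN`, `XN`: phloem/xylem
#'   crossed with inoculated/control).
#' @param n_per_group Replicates per group (default 3).
#' @return A sample design tibble (`sample`, `group`, `replicate`).
#' @export
study_design <- function(groups = c("PI", "XI", "PN", "XN"), n_per_group = 3) {
  tibble(sample = paste0(rep(groups, each = n_per_group), "_",
                         rep(seq_len(n_per_group), length(groups))),
         group = rep(groups, each = n_per_group),
         replicate = rep(seq_len(n_per_group), length(groups)))
}

# lognormal sigma giving a target coefficient of variation
lognorm_sigma <- function(cv) sqrt(log(1 + cv^2))

#' Simulate a transcript-by-sample FPKM matrix with known ground truth
#'
#' Generates an expression matrix over a grouped design with five transcript
#' classes: `stable_high` and `stable_low` (log-normal noise at a small target
#' CV, multiplicative deviations clamped so the true maximum fold change stays
#' under `mfc_cap`), `variable` (large log-normal noise), `condition_specific`
#' (expressed in some groups, zero in at least one), and `silent` (all zero).
#' Log-normal noise parameterized by a target CV (`sigma` solved from
#' `CV^2 = exp(sigma^2) - 1`) is the natural multiplicative error model for
#' FPKM data.
#'
#' @param seed Integer seed; generation is fully reproducible.
#' @param design Sample design tibble (default [study_design()]: 4 groups of
#'   3 replicates).
#' @param class_counts Named integer vector of transcripts per class.
#' @param base_expr_range Named list of `c(min, max)` base-expression ranges
#'   (sampled log-uniformly) per expressed class.
#' @param noise_cv Named numeric vector of target CVs per expressed class
#'   (stable classes below 0.1, variable well above).
#' @param mfc_cap True fold-change cap enforced on stable classes (< 2).
#' @param n_zero_groups Number of groups zeroed out for `condition_specific`
#'   transcripts (at least 1).
#' @return A list with `matrix` (expression tibble), `truth` (tibble
#'   `transcript_id`, `class`, `base_expr`, `noise_cv`) and `design`.
#' @export
simulate_fpkm <- function(seed,
                          design = study_design(),
                          class_counts = c(stable_high = 30, stable_low = 20,
                                           variable = 80,
                                           condition_specific = 40,
                                           silent = 30),
                          base_expr_range = list(stable_high = c(50, 1000),
                                                 stable_low = c(0.1, 0.9),
                                                 variable = c(1, 500),
                                                 condition_specific = c(5, 200)),
                          noise_cv = c(stable_high = 0.05, stable_low = 0.08,
                                       variable = 0.6,
                                       condition_specific = 0.5),
                          mfc_cap = 1.5,
                          n_zero_groups = 1) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (sum(class_counts) == 0) abort("class counts sum to zero")
  stopifnot(mfc_cap > 1, mfc_cap < 2, n_zero_groups >= 1)
  design <- validate_sample_design(design)
  n <- nrow(design)
  groups <- unique(design$group)
  if (n_zero_groups >= length(groups)) {
    abort("condition_specific transcripts must stay expressed in at least one group")
  }

  withr::with_seed(seed, {
    classes <- rep(names(class_counts), class_counts)
    n_tx <- length(classes)
    ids <- sprintf("t%04d", seq_len(n_tx))
    rows <- vector("list", n_tx)
    base <- numeric(n_tx)
    for (i in seq_len(n_tx)) {
      cl <- classes[i]
      if (cl == "silent") {
        base[i] <- 0
        rows[[i]] <- rep(0, n)
        next
      }
      rng <- base_expr_range[[cl]]
      base[i] <- exp(runif(1, log(rng[1]), log(rng[2])))
      cv <- noise_cv[[cl]]
      sig <- lognorm_sigma(cv)
      dev <- rnorm(n, 0, sig)
      if (cl %in% c("stable_high", "stable_low")) {
        # clamp multiplicative deviations so the true MFC stays under the cap
        lim <- log(mfc_cap) / 2
        dev <- pmin(pmax(dev, -lim), lim)
      }
      x <- base[i] * exp(dev - sig^2 / 2)
      if (cl == "condition_specific") {
        zero_groups <- sample(groups, n_zero_groups)
        x[design$group %in% zero_groups] <- 0
      }
      rows[[i]] <- x
    }
    values <- do.call(rbind, rows)
    colnames(values) <- design$sample
    mat <- dplyr::bind_cols(tibble(transcript_id = ids), as_tibble(values))
    truth <- tibble(transcript_id = ids, class = classes,
                    base_expr = base,
                    noise_cv = unname(ifelse(classes == "silent", 0,
                                             noise_cv[classes])))
    list(matrix = validate_expression_matrix(mat), truth = truth,
         design = design)
  })
}

#' Simulate an RT-qPCR Cq panel with known stability ground truth
#'
#' Generates gene-by-sample quantification cycles under the additive Gaussian
#' cycle-scale error model: `Cq = base + group_shift + N(0, noise_sd)`.
#' Truth-stable genes get near-zero noise and no group shift; the remaining
#' genes get inflated noise and a per-group shift of magnitude
#' `group_shift_unstable` with random sign, emulating condition-regulated
#' genes. Which genes are stable is drawn from the seed, so gene-id
#' tie-breaking cannot favour the stable set.
#'
#' @param seed Integer seed.
#' @param k_genes Panel size (default 15).
#' @param stable_gene_count Number of truth-stable genes (default 3).
#' @param n_groups,n_per_group Design shape (defaults 2 groups of 6).
#' @param noise_sd_stable,noise_sd_unstable Cycle-scale noise SDs (defaults
#'   0.1 and 1.0).
#' @param group_shift_unstable Magnitude of the per-group shift for unstable
#'   genes, in cycles (default 1.5).
#' @param base_cq_range Base Cq range, sampled uniformly (default 18-32; all
#'   simulated Cq stay below 40).
#' @return A list with `cq` (Cq tibble), `design`, and `truth` (tibble
#'   `gene`, `stable`, `noise_sd`, `shift_sd`, `perturbation`, `truth_rank` —
#'   ascending total perturbation).
#' @export
simulate_cq <- function(seed,
                        k_genes = 15, stable_gene_count = 3,
                        n_groups = 2, n_per_group = 6,
                        noise_sd_stable = 0.1, noise_sd_unstable = 1.0,
                        group_shift_unstable = 1.5,
                        base_cq_range = c(18, 32)) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (!(k_genes >= stable_gene_count && stable_gene_count >= 2)) {
    abort("need k_genes >= stable_gene_count >= 2")
  }
  stopifnot(n_groups >= 1, n_per_group >= 2)
  design <- study_design(groups = paste0("G", seq_len(n_groups)),
                         n_per_group = n_per_group)
  n <- nrow(design)
  genes <- sprintf("gene%02d", seq_len(k_genes))

  withr::with_seed(seed, {
    stable <- genes %in% sample(genes, stable_gene_count)
    base <- runif(k_genes, base_cq_range[1], base_cq_range[2])
    noise_sd <- ifelse(stable, noise_sd_stable, noise_sd_unstable)
    shifts <- matrix(0, k_genes, n_groups,
                     dimnames = list(genes, unique(design$group)))
    for (i in which(!stable)) {
      shifts[i, ] <- sample(c(-1, 1), n_groups, replace = TRUE) *
        group_shift_unstable
    }
    m <- matrix(NA_real_, k_genes, n, dimnames = list(genes, design$sample))
    for (i in seq_len(k_genes)) {
      m[i, ] <- base[i] + shifts[i, design$group] + rnorm(n, 0, noise_sd[i])
    }
    # the generator keeps every Cq inside the quantifiable range
    m <- pmin(m, 39.99)
    shift_sd <- apply(shifts[, design$group, drop = FALSE], 1, sd)
    perturbation <- noise_sd + shift_sd
    truth <- tibble(gene = genes, stable = stable,
                    noise_sd = noise_sd, shift_sd = shift_sd,
                    perturbation = perturbation,
                    truth_rank = rank_by_value(perturbation, genes))
    cq <- dplyr::bind_cols(tibble(gene = genes), as_tibble(m))
    list(cq = validate_cq_table(cq), design = design, truth = truth)
  })
}
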