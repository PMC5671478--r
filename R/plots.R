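#' Plot a genome-wide screen: stability vs expression
#'
#' Scatter of expression stability (CV of expression, percent) against mean
#' expression (log10 scale), with the kept transcripts highlighted when the
#' input carries a `passed` column from [select_stable()].
#'
#' @param stats Tibble from [transcript_stats()] or [select_stable()].
#' @param cv_max Reference line for the CV threshold (percent).
#' @return A ggplot object.
#' @export
plot_screen <- function(stats, cv_max = 20) {
  d <- filter(stats, .data$mean_expr > 0, !is.na(.data$cv))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_expr, y = .data$cv))
  if ("passed" %in% names(d)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$passed),
                                 alpha = 0.6, size = 0.8) +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                              `TRUE` = "#D55E00"),
                                   name = "stable")
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.6, size = 0.8, colour = "grey40")
  }
  p +
    ggplot2::geom_hline(yintercept = cv_max, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mean expression", y = "CV of expression (%)") +
    ggplot2::theme_minimal()
}

#' Box-style plot of per-gene Cq distributions
#'
#' The classic candidate-overview figure: per gene, the Cq range (whiskers)
#' and interquartile box, ordered by median Cq.
#'
#' @param cq Cq table.
#' @return A ggplot object.
#' @export
plot_cq_distribution <- function(cq) {
  d <- cq_descriptives(cq) |> arrange(.data$mean)
  d$gene <- factor(d$gene, levels = d$gene)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$min, ymax = .data$max)) +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$mean, ymin = .data$p25,
                                        ymax = .data$p75),
                           fill = "grey85", width = 0.6) +
    ggplot2::labs(x = NULL, y = "Cq") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @describeIn genorm Plot a geNorm fit: `type = "stability"` shows the
#'   average expression stability `M` in exclusion order (least stable on the
#'   left); `type = "v"` shows the pairwise-variation curve `V(n, n+1)` with
#'   the decision cutoff.
#' @param object A `genorm_fit` object.
#' @param type `"stability"` or `"v"`.
#' @export
autoplot.genorm_fit <- function(object, type = c("stability", "v"), ...) {
  type <- match.arg(type)
  if (type == "stability") {
    d <- object$stability |> arrange(dplyr::desc(.data$rank))
    d$gene <- factor(d$gene, levels = d$gene)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$gene, y = .data$stability,
                                    group = 1)) +
      ggplot2::geom_line(colour = "grey50") +
      ggplot2::geom_point() +
      ggplot2::labs(x = "least stable → most stable",
                    y = "average expression stability M") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  } else {
    d <- object$v_curve |> mutate(label = paste0("V", .data$n, "/", .data$n + 1))
    d$label <- factor(d$label, levels = d$label)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$v)) +
      ggplot2::geom_col(fill = "grey70") +
      ggplot2::geom_hline(yintercept = object$v_cutoff, linetype = 2) +
      ggplot2::labs(x = NULL, y = "pairwise variation V") +
      ggplot2::theme_minimal()
  }
}

#' @describeIn rank_stability Dot plot of per-method stability ranks per gene
#'   (genes ordered by consensus rank), the method-comparison view of the
#'   panel.
#' @param object A `stability_panel` tibble.
#' @param ... Unused.
#' @export
autoplot.stability_panel <- function(object, ...) {
  d <- tidy(object) |>
    left_join(select(as_tibble(object), all_of(c("gene", "final_rank"))),
              by = "gene") |>
    arrange(.data$final_rank)
  d$gene <- factor(d$gene, levels = unique(d$gene))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene, y = .data$rank,
                                  colour = .data$method, group = .data$method)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "consensus order (most stable first)", y = "method rank",
                  colour = "method") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot fold-change concordance between two DE call sets
#'
#' @param x A `de_concordance` object from [concordance()].
#' @return A ggplot object: per-gene log2 fold changes under the two
#'   normalizations, coloured by agreement class.
#' @export
plot_concordance <- function(x) {
  d <- tidy(x) |>
    mutate(log2fc_a = log2(.data$fc_a), log2fc_b = log2(.data$fc_b))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc_a, y = .data$log2fc_b,
                                  colour = .data$agreement)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "log2 FC (set A)", y = "log2 FC (set B)",
                  colour = "agreement") +
    ggplot2::theme_minimal()
}
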