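# ggplot2 views of the main result tables.

#' Volcano plot of meta-analysis results
#'
#' Combined effect size against -log10 p, DM CpGs highlighted.
#'
#' @param meta Tibble from [meta_ewas()].
#' @return A ggplot object.
#' @export
plot_meta_volcano <- function(meta) {
  ggplot2::ggplot(meta, ggplot2::aes(x = .data$b_meta,
                                     y = -log10(.data$p),
                                     colour = .data$dm_flag)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = "DM") +
    ggplot2::labs(x = "combined methylation difference (loaded - control)",
                  y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of meta-analysis p-values
#'
#' @param meta Tibble from [meta_ewas()].
#' @param annotation Probe annotation supplying `chrom` and `pos`.
#' @return A ggplot object.
#' @export
plot_meta_manhattan <- function(meta, annotation) {
  i <- match(meta$probe_id, annotation$probe_id)
  d <- dplyr::mutate(meta, chrom = annotation$chrom[i], pos = annotation$pos[i])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = -log10(.data$p),
                                  colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6, show.legend = FALSE) +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Odds-ratio plot of chromatin-state enrichment
#'
#' @param enrichment Tibble from [enrichment_by_state()].
#' @param q_thresh Highlight states with `q` below this value.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, q_thresh = 0.05) {
  d <- enrichment[!is.na(enrichment$odds_ratio) & is.finite(enrichment$odds_ratio), ]
  d$state <- factor(d$state, levels = rev(CHROMATIN_STATES))
  d$significant <- !is.na(d$q) & d$q < q_thresh
  ggplot2::ggplot(d, ggplot2::aes(x = .data$odds_ratio, y = .data$state,
                                  colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = sprintf("q < %g", q_thresh)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (DM vs background)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano autoplot for a moderated fit
#' @param object A `moderated_fit`.
#' @param ... Unused.
#' @method autoplot moderated_fit
#' @export
autoplot.moderated_fit <- function(object, ...) {
  d <- object$table
  ggplot2::ggplot(d, ggplot2::aes(x = .data$b, y = -log10(.data$p.value),
                                  colour = .data$q.value < 0.05)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = "q < 0.05") +
    ggplot2::labs(x = "group difference", y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}
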