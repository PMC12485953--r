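# ggplot2 views of the three result types: the two-mutant fold-change plane,
# the IP-MS volcano and digestion time courses.

#' Plot peptides in the two-mutant fold-change plane
#'
#' Scatter of each peptide's log2 fold change in the deletion mutant (x)
#' versus the catalytic mutant (y), both relative to wild-type, colored by
#' candidate label; substrate-product pairs are connected. Position-filtered
#' peptides are drawn in grey.
#'
#' @param calls A `substrate_calls` object from [call_substrates()].
#' @return A ggplot object.
#' @export
plot_fc_scatter <- function(calls) {
  stopifnot(inherits(calls, "substrate_calls"))
  pep <- calls$peptides
  thr <- calls$pairing$fc_threshold
  cols <- c(substrate_candidate = "#D55E00", product_candidate = "#0072B2",
            unchanged = "grey60", discordant = "#CC79A7",
            position_filtered = "grey85")
  p <- ggplot2::ggplot(pep, ggplot2::aes(x = .data$fc_del, y = .data$fc_cat,
                                         color = .data$label)) +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = "dashed",
                        color = "grey70") +
    ggplot2::geom_vline(xintercept = c(-thr, thr), linetype = "dashed",
                        color = "grey70") +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::scale_color_manual(values = cols) +
    ggplot2::labs(x = "log2 FC (deletion mutant / wild-type)",
                  y = "log2 FC (catalytic mutant / wild-type)",
                  color = NULL) +
    ggplot2::theme_minimal()
  if (nrow(calls$pairs) > 0) {
    seg <- calls$pairs
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$fc_del_sub, y = .data$fc_cat_sub,
                   xend = .data$fc_del_prod, yend = .data$fc_cat_prod),
      inherit.aes = FALSE, color = "grey40", linewidth = 0.3)
  }
  p
}

#' @rdname ipms_enrichment
#' @param object An `ipms_fit` object.
#' @export
autoplot.ipms_fit <- function(object, ...) {
  tbl <- object$table
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$diff,
                                    y = -log10(.data$p_value),
                                    color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "black")) +
    ggplot2::labs(x = "log2 fold enrichment (bait / control)",
                  y = "-log10 p (two-tailed Student t)",
                  color = "significant") +
    ggplot2::theme_minimal()
}

#' @rdname ipms_enrichment
#' @export
plot_volcano <- function(fit) {
  autoplot.ipms_fit(fit)
}

#' Plot a digestion time course
#'
#' Replicate points with a line through the per-timepoint means, one panel
#' per peptide, colored by enzyme.
#'
#' @param tc Long time-course tibble (see [summarize_timecourse()]).
#' @return A ggplot object.
#' @export
plot_timecourse <- function(tc) {
  means <- summarize_timecourse(tc)
  ggplot2::ggplot(tc, ggplot2::aes(x = .data$time_min, y = .data$intensity,
                                   color = .data$enzyme_label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = means,
                       ggplot2::aes(y = .data$mean_intensity)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$peptide_id), scales = "free_y") +
    ggplot2::labs(x = "reaction time (min)", y = "product MS1 intensity",
                  color = NULL) +
    ggplot2::theme_minimal()
}
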