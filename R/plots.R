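#' @export
autoplot.dyver_scan <- function(object, p_col = "bonf_p", alpha = NULL,
                                ...) {
  tbl <- as_tibble(object)
  tbl$neglogp <- -log10(pmax(tbl[[p_col]], 1e-300))
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data$kb, y = .data$neglogp)) +
    ggplot2::geom_point(alpha = 0.7, colour = "#34495e") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "associated variant position (kb)",
                  y = bquote(-log[10] ~ .(p_col)))
  if (!is.null(alpha))
    p <- p + ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2,
                                 colour = "#c0392b")
  p
}

#' Per-variant DyVER score profile of one gene
#'
#' Manhattan-style locus plot of the DyVER score across all variants for a
#' single gene. The scan must have been run with `keep_scores = TRUE`.
#'
#' @param scan A `dyver_scan` result with the `scores` attribute.
#' @param gene Gene to plot.
#' @return A ggplot object.
#' @export
plot_variant_scores <- function(scan, gene) {
  sc <- attr(scan, "scores")
  if (is.null(sc))
    abort("scan was run without keep_scores = TRUE; per-variant scores unavailable")
  sub <- sc[sc$gene == gene, ]
  if (nrow(sub) == 0) abort(paste0("gene '", gene, "' not in scan"))
  best <- scan[scan$gene == gene, ]
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$kb, y = .data$dyver_score)) +
    ggplot2::geom_point(colour = "#34495e") +
    ggplot2::geom_point(data = best, colour = "#c0392b", size = 3) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(title = gene, x = "variant position (kb)",
                  y = "DyVER score")
}
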