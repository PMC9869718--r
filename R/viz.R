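#' Plot styling shared across views
#'
#' A fixed categorical palette indexed by trend label, so trend `t` keeps
#' the same color in every view of a session; highlighted genes are drawn
#' in black on top.
#'
#' @param palette character vector of colors, length >= 10 (the maximum k);
#'   default is a colorblind-safe categorical set.
#' @param highlight_color color for highlighted genes (default black).
#' @param width,height figure dimensions in inches.
#' @return list of class `plot_style`.
#' @export
plot_style <- function(palette = NULL, highlight_color = "black",
                       width = 8, height = 5) {
  if (is.null(palette))
    palette <- c("#E69F00", "#56B4E9", "#009E73", "#F0E442", "#0072B2",
                 "#D55E00", "#CC79A7", "#999999", "#882255", "#44AA99")
  stopifnot(length(palette) >= 10L)
  structure(list(palette = palette, highlight_color = highlight_color,
                 width = width, height = height),
            class = "plot_style")
}

trend_colors <- function(style, k) {
  stats::setNames(style$palette[seq_len(k)], as.character(seq_len(k) - 1L))
}

#' Save a figure to PNG, PDF or SVG
#'
#' @param plot a ggplot object.
#' @param path output path; the extension (`.png`, `.pdf`, `.svg`) selects
#'   the device.
#' @param style a [plot_style] (for dimensions).
#' @return `path`, invisibly.
#' @export
save_figure <- function(plot, path, style = plot_style()) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "pdf", "svg"))
    stop("unsupported figure format: ", ext)
  ggplot2::ggsave(path, plot, width = style$width, height = style$height,
                  dpi = 150)
  invisible(path)
}

profile_long <- function(result, za, zb) {
  inter <- result$intersecting
  conds <- colnames(result$centroids)
  build <- function(mat, labels, ds) {
    if (nrow(labels) == 0L) return(NULL)
    v <- mat$values[labels$gene, , drop = FALSE]
    data.frame(gene = rep(labels$gene, each = length(conds)),
               dataset = ds,
               condition = factor(rep(conds, nrow(labels)), levels = conds),
               value = as.vector(t(v)),
               trend = rep(labels$label, each = length(conds)),
               stringsAsFactors = FALSE)
  }
  rbind(build(za, data.frame(gene = inter$gene, label = inter$label_a),
              result$dataset_a),
        build(zb, data.frame(gene = inter$gene, label = inter$label_b),
              result$dataset_b))
}

#' Trend diagrams: centroid bands, per-gene profiles, or box plots
#'
#' Facetted by dataset and trend. `centroid` mode shows the mean z-scored
#' profile per trend with a plus/minus one standard-deviation band;
#' `profiles` draws one line per gene; `box` draws per-condition
#' distribution boxes. Highlighted genes are drawn in black on top.
#'
#' @param result a [build_comparison] result.
#' @param za,zb the z-scored [abundance_matrix] objects of the pair.
#' @param mode `"centroid"`, `"profiles"` or `"box"`.
#' @param highlight character vector of gene IDs to overdraw in black.
#' @param style a [plot_style].
#' @return A ggplot object.
#' @export
plot_trends <- function(result, za, zb,
                        mode = c("centroid", "profiles", "box"),
                        highlight = character(0), style = plot_style()) {
  mode <- match.arg(mode)
  df <- profile_long(result, za, zb)
  df$trend_f <- factor(df$trend)
  absent <- setdiff(highlight, df$gene)
  if (length(absent) > 0L)
    warning("highlight IDs absent from data: ",
            paste(absent, collapse = ", "))
  cols <- trend_colors(style, result$k)
  base <- ggplot2::ggplot(df,
    ggplot2::aes(x = .data$condition, y = .data$value)) +
    ggplot2::facet_grid(dataset ~ trend_f,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(y = "z-scored abundance", x = "condition") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (mode == "centroid") {
    agg <- stats::aggregate(value ~ dataset + trend_f + condition, df,
                            function(v) c(mean = mean(v),
                                          sd = stats::sd(v)))
    agg <- cbind(agg[1:3], as.data.frame(agg$value))
    agg$sd[is.na(agg$sd)] <- 0
    p <- base +
      ggplot2::geom_ribbon(
        data = agg,
        ggplot2::aes(y = .data$mean, ymin = .data$mean - .data$sd,
                     ymax = .data$mean + .data$sd,
                     group = .data$trend_f, fill = .data$trend_f),
        alpha = 0.3) +
      ggplot2::geom_line(
        data = agg,
        ggplot2::aes(y = .data$mean, group = .data$trend_f,
                     color = .data$trend_f), linewidth = 1)
  } else if (mode == "profiles") {
    p <- base +
      ggplot2::geom_line(ggplot2::aes(group = .data$gene,
                                      color = .data$trend_f),
                         alpha = 0.4, linewidth = 0.3)
  } else {
    p <- base +
      ggplot2::geom_boxplot(ggplot2::aes(group = .data$condition,
                                         fill = .data$trend_f),
                            outlier.size = 0.4)
  }
  hl <- df[df$gene %in% highlight, , drop = FALSE]
  if (nrow(hl) > 0L)
    p <- p + ggplot2::geom_line(
      data = hl, ggplot2::aes(group = .data$gene),
      color = style$highlight_color, linewidth = 0.6)
  p + ggplot2::scale_color_manual(values = cols, name = "trend") +
    ggplot2::scale_fill_manual(values = cols, name = "trend")
}

#' Sankey diagram of trend intersections
#'
#' Left column: trends of dataset A; right column: trends of dataset B.
#' Node heights are proportional to gene counts, band thickness to
#' intersection sizes. Each band is split at midspan so its left half
#' carries the right node's color and its right half the left node's
#' (inverted gradient), making crossing flows traceable. The title reports
#' the concordant/discordant summary.
#'
#' @param model a `sankey_model` with at least one link.
#' @param style a [plot_style].
#' @return A ggplot object.
#' @export
plot_sankey <- function(model, style = plot_style()) {
  stopifnot(inherits(model, "sankey_model"), nrow(model$links) >= 1L)
  cols <- trend_colors(style, model$k)
  gap <- 0.02 * sum(model$links$size)
  stack_nodes <- function(ds) {
    nd <- model$nodes[model$nodes$dataset == ds, , drop = FALSE]
    nd <- nd[order(nd$trend), , drop = FALSE]
    tops <- cumsum(nd$size + gap) - nd$size - gap
    nd$y0 <- -(tops + nd$size)
    nd$y1 <- -tops
    nd
  }
  na <- stack_nodes(model$dataset_a)
  nb <- stack_nodes(model$dataset_b)
  nodes <- rbind(cbind(na, x0 = 0, x1 = 0.06),
                 cbind(nb, x0 = 0.94, x1 = 1))
  links <- model$links[order(model$links$trend_a, model$links$trend_b), ,
                       drop = FALSE]
  # per-node running offsets for outgoing/incoming bands
  off_a <- stats::setNames(na$y1, as.character(na$trend))
  off_b <- stats::setNames(nb$y1, as.character(nb$trend))
  polys <- list()
  for (i in seq_len(nrow(links))) {
    ta <- as.character(links$trend_a[i]); tb <- as.character(links$trend_b[i])
    s <- links$size[i]
    ya1 <- off_a[ta]; ya0 <- ya1 - s; off_a[ta] <- ya0
    yb1 <- off_b[tb]; yb0 <- yb1 - s; off_b[tb] <- yb0
    ym0 <- (ya0 + yb0) / 2; ym1 <- (ya1 + yb1) / 2
    polys[[length(polys) + 1L]] <- data.frame(
      id = paste0(i, c("L", "L", "L", "L", "R", "R", "R", "R")),
      x = c(0.06, 0.5, 0.5, 0.06, 0.5, 0.94, 0.94, 0.5),
      y = c(ya0, ym0, ym1, ya1, ym0, yb0, yb1, ym1),
      # inverted gradient: left half shows the target trend's color
      fill = rep(c(tb, ta), each = 4L), stringsAsFactors = FALSE)
  }
  poly_df <- do.call(rbind, polys)
  s <- model$summary
  ggplot2::ggplot() +
    ggplot2::geom_polygon(data = poly_df,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$id,
                   fill = .data$fill), alpha = 0.55) +
    ggplot2::geom_rect(data = nodes,
      ggplot2::aes(xmin = .data$x0, xmax = .data$x1, ymin = .data$y0,
                   ymax = .data$y1, fill = factor(.data$trend)),
      color = "grey20") +
    ggplot2::geom_text(data = nodes,
      ggplot2::aes(x = (.data$x0 + .data$x1) / 2,
                   y = (.data$y0 + .data$y1) / 2,
                   label = .data$size), size = 3) +
    ggplot2::scale_fill_manual(values = cols, name = "trend") +
    ggplot2::annotate("text", x = 0.03, y = max(nodes$y1) + 2 * gap,
                      label = model$dataset_a, hjust = 0) +
    ggplot2::annotate("text", x = 0.97, y = max(nodes$y1) + 2 * gap,
                      label = model$dataset_b, hjust = 1) +
    ggplot2::labs(title = sprintf(
      "%d concordant (%.1f%%) / %d discordant (%.1f%%)",
      s$concordant, s$pct_concordant, s$discordant, s$pct_discordant)) +
    ggplot2::theme_void()
}

#' Overview stacked bars across dataset pairs
#'
#' One horizontal bar per pairwise comparison with four segments:
#' concordant and discordant intersecting genes, and the non-intersecting
#' genes of either dataset.
#'
#' @param counts an [overview] table.
#' @param style a [plot_style].
#' @return A ggplot object.
#' @export
plot_overview <- function(counts, style = plot_style()) {
  stopifnot(nrow(counts) >= 1L)
  pair <- paste(counts$dataset_a, "vs", counts$dataset_b)
  seg_levels <- c("concordant", "discordant", "only A", "only B")
  long <- data.frame(
    pair = rep(pair, times = 4L),
    segment = factor(rep(seg_levels, each = nrow(counts)),
                     levels = seg_levels),
    count = c(counts$n_intersecting_concordant,
              counts$n_intersecting_discordant,
              counts$n_only_a, counts$n_only_b))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$count, y = .data$pair,
                                     fill = .data$segment)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c("#0072B2", "#D55E00",
                                          "#999999", "#CCCCCC"),
                               drop = FALSE) +
    ggplot2::labs(x = "genes", y = NULL, fill = NULL) +
    ggplot2::theme_bw()
}

#' Enrichment bar chart
#'
#' Horizontal bars of `-log10(FDR)` for significant terms (or all terms
#' with `all_terms = TRUE`), colored by over/under representation and
#' sorted with the smallest FDR on top. Zero FDRs are clamped to the
#' smallest positive double before the log, for plotting only.
#'
#' @param table an [enrich] table.
#' @param alpha significance threshold used for the default subset.
#' @param all_terms draw every term regardless of significance.
#' @param style a [plot_style].
#' @return A ggplot object.
#' @export
plot_enrichment <- function(table, alpha = 0.05, all_terms = FALSE,
                            style = plot_style()) {
  stopifnot(inherits(table, "enrichment_table"), nrow(table) >= 1L)
  df <- if (all_terms) table else table[table$fdr < alpha, , drop = FALSE]
  if (nrow(df) == 0L) {
    warning("no significant terms to plot")
    df <- table[0L, , drop = FALSE]
  }
  df$neglog_fdr <- -log10(pmax(df$fdr, .Machine$double.xmin))
  df <- df[order(df$fdr, decreasing = TRUE), , drop = FALSE]
  df$term_f <- factor(df$term_id, levels = unique(df$term_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$neglog_fdr, y = .data$term_f,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(over = "#D55E00",
                                          under = "#0072B2"),
                               drop = FALSE) +
    ggplot2::labs(x = expression(-log[10] * "(FDR)"), y = NULL,
                  fill = NULL) +
    ggplot2::theme_bw()
}
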