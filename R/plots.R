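# Figure rendering. Figures are presentation artifacts; every numeric
# claim they display is computed (and tested) on the underlying tables.

#' Heatmap row order by ascending cleavage efficiency
#'
#' @param efficiency Output of [rank_cleavage_efficiency()] (or any
#'   `data.frame` with `site_id` and `cleavage_reads`).
#' @return Character vector of site ids, ascending efficiency, input order
#'   preserved among ties (stable sort).
#' @export
heatmap_row_order <- function(efficiency) {
  efficiency$site_id[order(efficiency$cleavage_reads)]
}

plot_metagene_gg <- function(profiles) {
  stopifnot(all(c("offset", "mean", "group") %in% names(profiles)))
  p <- ggplot2::ggplot(profiles,
                       ggplot2::aes(x = offset, y = mean,
                                    colour = group))
  if ("orientation" %in% names(profiles))
    p <- p + ggplot2::facet_wrap(~orientation, ncol = 1, scales = "free_y")
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "distance from DSB (bp)", y = "mean CPM",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

plot_heatmap_gg <- function(fm, efficiency, clip = c(0.01, 0.99)) {
  if (is.null(efficiency)) stop("heatmap requires an efficiency ranking")
  ord <- heatmap_row_order(efficiency)
  ord <- ord[ord %in% fm$site_ids]
  sub <- subset_sites(fm, ord)
  v <- sub$values
  lim <- stats::quantile(v, clip, names = FALSE)
  v <- pmin(pmax(v, lim[1]), lim[2])
  df <- data.frame(site = factor(rep(ord, ncol(v)), levels = ord),
                   offset = rep(bin_offsets(fm$flank, fm$bin_size),
                                each = nrow(v)),
                   value = as.vector(v))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = offset, y = site,
                                        fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "CPM") +
    ggplot2::labs(x = "distance from DSB (bp)",
                  y = "sites (ascending cleavage efficiency)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  attr(p, "clip_limits") <- lim
  attr(p, "row_order") <- ord
  p
}

plot_fill_gg <- function(fm, site_id) {
  idx <- match(site_id, fm$site_ids)
  if (is.na(idx)) stop("unknown site_id: ", site_id)
  df <- data.frame(offset = bin_offsets(fm$flank, fm$bin_size),
                   value = fm$values[idx, ])
  ggplot2::ggplot(df, ggplot2::aes(x = offset, y = value)) +
    ggplot2::geom_area(fill = "steelblue") +
    ggplot2::labs(title = site_id, x = "distance from DSB (bp)", y = "CPM") +
    ggplot2::theme_minimal()
}

plot_boxplot_gg <- function(fc_tables) {
  df <- do.call(rbind, lapply(names(fc_tables), function(nm) {
    tab <- fc_tables[[nm]]
    tab <- tab[!tab$zero_both, , drop = FALSE]
    data.frame(group = nm, log2fc = tab$log2fc, stringsAsFactors = FALSE)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = group, y = log2fc)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "log2 fold change") +
    ggplot2::theme_minimal()
}

plot_pca_gg <- function(pca, sample_groups = NULL) {
  df <- data.frame(PC1 = pca$coords[, 1],
                   PC2 = if (ncol(pca$coords) > 1) pca$coords[, 2] else 0,
                   sample = rownames(pca$coords))
  df$group <- if (is.null(sample_groups)) df$sample else sample_groups
  ggplot2::ggplot(df, ggplot2::aes(x = PC1, y = PC2,
                                   colour = group)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * pca$explained[1]),
                  y = sprintf("PC2 (%.1f%%)",
                              100 * ifelse(length(pca$explained) > 1,
                                           pca$explained[2], 0)),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Render an analysis figure
#'
#' @param kind One of `"metagene"`, `"heatmap"`, `"fillplot"`,
#'   `"boxplot"`, `"pca_scatter"`.
#' @param data Named list of inputs: `profiles` (metagene), `matrix` +
#'   `efficiency` (heatmap; the ranking is mandatory), `matrix` +
#'   `site_id` (fillplot), `fc_tables` (boxplot), `pca` +
#'   optional `sample_groups` (pca_scatter).
#' @param path Output image path (`.png` or `.svg`); `NULL` returns the
#'   ggplot object without writing.
#' @param width,height Figure size in inches.
#' @return The ggplot object, invisibly; written to `path` when given.
#' @export
render_figures <- function(kind = c("metagene", "heatmap", "fillplot",
                                    "boxplot", "pca_scatter"),
                           data, path = NULL, width = 6, height = 4) {
  kind <- match.arg(kind)
  p <- switch(kind,
    metagene = plot_metagene_gg(data$profiles),
    heatmap = plot_heatmap_gg(data$matrix, data$efficiency),
    fillplot = plot_fill_gg(data$matrix, data$site_id),
    boxplot = plot_boxplot_gg(data$fc_tables),
    pca_scatter = plot_pca_gg(data$pca, data$sample_groups))
  if (!is.null(path))
    suppressMessages(ggplot2::ggsave(path, p, width = width,
                                     height = height, dpi = 120))
  invisible(p)
}
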