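# Basic figure output: masked correlation heatmap and PC score plot with
# 1-SD strain ellipses.

#' Correlation heatmap with nonsignificance marks
#'
#' Tile heatmap of the Pearson correlation matrix; entries whose
#' correlation is nonsignificant (`p > alpha`) are marked with an X.
#'
#' @param corr A [pearson_matrix()] result.
#' @return A ggplot object.
#' @export
plot_correlation_matrix <- function(corr) {
  stopifnot(inherits(corr, "correlation_matrix"))
  tr <- corr$traits
  df <- expand.grid(x = tr, y = tr, stringsAsFactors = FALSE)
  df$r <- as.vector(corr$r[cbind(match(df$y, tr), match(df$x, tr))])
  df$masked <- as.vector(corr$mask[cbind(match(df$y, tr), match(df$x, tr))])
  df$x <- factor(df$x, levels = tr)
  df$y <- factor(df$y, levels = rev(tr))
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y,
                                   fill = r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = df[!is.na(df$masked) & df$masked, ],
                        shape = 4, size = 2) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1),
                                  na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1,
                                                       vjust = 0.5))
}

#' PC score plot with group ellipses and projected animals
#'
#' Scatter of fitted founder scores in two chosen PCs, 1-SD normal data
#' ellipses per strain, and (optionally) projected DO animals overlaid.
#'
#' @param model A [fit_pca()] result.
#' @param groups Group label per fitted row (e.g. strain).
#' @param projected Optional score matrix from [project_onto_pca()].
#' @param pcs Which two PCs to draw (default `c(1, 2)`).
#' @return A ggplot object.
#' @export
plot_pca_scores <- function(model, groups, projected = NULL,
                            pcs = c(1, 2)) {
  stopifnot(inherits(model, "pca_model"), length(pcs) == 2L)
  sc <- model$scores[, pcs, drop = FALSE]
  df <- data.frame(PCa = sc[, 1], PCb = sc[, 2],
                   group = as.character(groups))
  ell <- normal_ellipse(sc, df$group, level = 1)
  paths <- do.call(rbind, lapply(seq_len(nrow(ell)), function(i) {
    p <- ellipse_path(ell[i, ])
    p$group <- ell$group[i]
    p
  }))
  lab <- sprintf("PC%d (%.1f%%)", pcs, 100 * model$explained[pcs])
  g <- ggplot2::ggplot(df, ggplot2::aes(x = PCa, y = PCb,
                                        colour = group)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_path(data = paths,
                       ggplot2::aes(x = x, y = y,
                                    colour = group),
                       inherit.aes = FALSE) +
    ggplot2::labs(x = lab[1], y = lab[2], colour = "group") +
    ggplot2::theme_minimal()
  if (!is.null(projected)) {
    pdf_ <- data.frame(PCa = projected[, pcs[1]], PCb = projected[, pcs[2]])
    g <- g + ggplot2::geom_point(data = pdf_,
                                 ggplot2::aes(x = PCa, y = PCb),
                                 inherit.aes = FALSE, shape = 3,
                                 colour = "black", size = 1.2)
  }
  g
}
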