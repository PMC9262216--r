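#' Plot subjects and clause regions on the clause's feature axes
#'
#' For a two-feature clause: a scatter of all subjects on the two
#' feature axes with the clause rectangle overlaid.  For a
#' three-feature clause: the three pairwise projections of the clause
#' cuboid, as facets, each with its projected rectangle.  Target-class
#' subjects of a perfect clause all fall inside the region.  Clauses of
#' order above 3 cannot be visualized this way and are refused.
#'
#' @param models list of \code{list(clause=, ...)} entries (e.g. from
#'   [selectParsimonious()]).
#' @param table the [FeatureTable-class] to plot.
#' @param outputDir optional directory; when given, each plot is also
#'   written as \code{clause_region_<i>.png}.
#' @return invisible list of ggplot objects, one per model.
#' @export
plotClauseRegions <- function(models, table, outputDir = NULL) {
    plots <- lapply(seq_along(models), function(idx) {
        clause <- models[[idx]]$clause
        ord <- clauseOrder(clause)
        stopIf(ord > 3L,
               "order-%d clauses cannot be drawn as rectangles/cuboids",
               ord)
        stopIf(ord < 2L, "region plots need at least two features")
        feats <- clauseFeatures(clause)
        iv <- clauseIntervals(clause)
        vals <- featureValues(table)
        pairs <- utils::combn(seq_len(ord), 2, simplify = FALSE)
        pts <- do.call(rbind, lapply(pairs, function(p) data.frame(
            panel = sprintf("%s vs %s", feats[p[1]], feats[p[2]]),
            x = vals[, feats[p[1]]], y = vals[, feats[p[2]]],
            outcome = as.character(outcome(table)))))
        boxes <- do.call(rbind, lapply(pairs, function(p) data.frame(
            panel = sprintf("%s vs %s", feats[p[1]], feats[p[2]]),
            xmin = iv[p[1], 1], xmax = iv[p[1], 2],
            ymin = iv[p[2], 1], ymax = iv[p[2], 2])))
        gg <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
            ggplot2::geom_rect(
                data = boxes,
                ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                             ymin = .data$ymin, ymax = .data$ymax),
                inherit.aes = FALSE, fill = "pink", alpha = 0.4) +
            ggplot2::geom_point(ggplot2::aes(colour = .data$outcome)) +
            ggplot2::facet_wrap(~panel, scales = "free") +
            ggplot2::labs(title = sprintf("Clause region (model %d)", idx),
                          x = NULL, y = NULL)
        if (!is.null(outputDir)) {
            dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
            ggplot2::ggsave(
                file.path(outputDir,
                          sprintf("clause_region_%d.png", idx)),
                gg, width = 7, height = 4, dpi = 120)
        }
        gg
    })
    invisible(plots)
}

#' @importFrom rlang .data
NULL
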