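#' Volcano plot of differential expression
#'
#' Base-graphics volcano of log2 fold change vs -log10 p, with the DE rule's
#' cutoff lines and significant genes colored by direction.
#'
#' @param de a [DEResults-class].
#' @param main plot title.
#' @return NULL, invisibly.
#' @export
plotVolcano <- function(de, main = "tumor vs control") {
    md <- metadata(de)
    col <- ifelse(de$direction == "up", "darkgreen",
           ifelse(de$direction == "down", "darkred", "grey50"))
    graphics::plot(de$log2fc, -log10(pmax(de$p_value, 1e-300)),
                   pch = 19, cex = 0.6, col = col,
                   xlab = "log2 fold change", ylab = "-log10 p", main = main)
    graphics::abline(v = c(-md$fc_cut, md$fc_cut), col = "blue", lty = 2)
    graphics::abline(h = -log10(md$alpha), col = "blue", lty = 2)
    invisible(NULL)
}

#' Heatmap of retained lncRNA-mRNA correlations
#'
#' Draws the retained-edge correlation matrix with \pkg{pheatmap} when that
#' package is installed; a plain \code{image()} otherwise.
#'
#' @param edges output of [buildEdges()].
#' @return the correlation matrix used, invisibly.
#' @export
plotCorrelationHeatmap <- function(edges) {
    kept <- edges[edges$retained, , drop = FALSE]
    if (!nrow(kept))
        stop("no retained edges to plot")
    lncs <- unique(kept$lncrna_id)
    mrnas <- unique(kept$mrna_id)
    m <- matrix(0, length(lncs), length(mrnas),
                dimnames = list(lncs, mrnas))
    m[cbind(kept$lncrna_id, kept$mrna_id)] <- kept$r
    if (requireNamespace("pheatmap", quietly = TRUE))
        pheatmap::pheatmap(m)
    else
        graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                        xlab = "mRNA", ylab = "lncRNA", main = "retained r")
    invisible(m)
}
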