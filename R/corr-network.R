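#' Pearson correlation of two sample vectors
#'
#' Standard product-moment estimate. If either vector has zero variance the
#' correlation is undefined: NA is returned and the event logged, so the
#' corresponding edge is dropped rather than invented.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Pearson r, or NA when undefined.
#' @export
pearsonR <- function(x, y) {
    if (length(x) != length(y))
        stop("x and y must have equal length")
    if (length(x) < 3L)
        stop("at least 3 paired samples are required")
    if (any(!is.finite(x)) || any(!is.finite(y)))
        stop("x and y must be finite")
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        message("pearsonR: zero-variance vector, correlation undefined")
        return(NA_real_)
    }
    stats::cor(x, y)
}

#' Build the lncRNA-mRNA correlation edge set
#'
#' One edge per (lncRNA, mRNA) pair with a computable Pearson correlation of
#' \code{log2(FPKM + 1)} across ALL samples (tumor and control jointly, the
#' default; per-group correlation at a handful of samples is unstable but is
#' available via \code{within}). An edge is retained when r > cut or
#' r < -cut, strictly: r = 0.3 exactly is not retained. Pairs where either
#' gene has zero variance are dropped and counted in
#' \code{metadata()$n_dropped}. A t-transform p-value and BH q-value per edge
#' are reported for reference; retention gates on r only.
#'
#' @param se a [LncExperiment-class].
#' @param topLnc,topMrna character vectors of gene ids (non-empty, present in
#'   \code{se}); typically from [topDeregulated()].
#' @param cut correlation magnitude cutoff (default 0.3).
#' @param within \code{"all"} (default), \code{"tumor"} or \code{"control"}:
#'   which samples to correlate across.
#' @return \code{DataFrame(lncrna_id, mrna_id, r, p_value, q_value,
#'   retained)}.
#' @export
buildEdges <- function(se, topLnc, topMrna, cut = 0.3,
                       within = c("all", "tumor", "control")) {
    within <- match.arg(within)
    if (!length(topLnc) || !length(topMrna))
        stop("empty gene list")
    missing <- setdiff(c(topLnc, topMrna), rownames(se))
    if (length(missing))
        stop("gene(s) absent from expression matrix: ",
             paste(utils::head(missing, 5L), collapse = ", "))
    L <- log2Fpkm(se)
    if (within != "all")
        L <- L[, sampleGroup(se) == within, drop = FALSE]
    if (ncol(L) < 3L)
        stop("at least 3 samples are required to correlate")
    lm <- t(L[topLnc, , drop = FALSE])
    mm <- t(L[topMrna, , drop = FALSE])
    lsd <- apply(lm, 2L, stats::sd)
    msd <- apply(mm, 2L, stats::sd)
    R <- suppressWarnings(stats::cor(lm, mm))
    R[lsd == 0, ] <- NA_real_
    R[, msd == 0] <- NA_real_
    edges <- DataFrame(
        lncrna_id = rep(topLnc, times = length(topMrna)),
        mrna_id = rep(topMrna, each = length(topLnc)),
        r = as.vector(R))
    nDropped <- sum(is.na(edges$r))
    if (nDropped)
        message("buildEdges: dropped ", nDropped,
                " edge(s) with zero-variance genes")
    edges <- edges[!is.na(edges$r), , drop = FALSE]
    n <- ncol(L)
    tstat <- edges$r * sqrt((n - 2) / pmax(1 - edges$r^2, .Machine$double.eps))
    edges$p_value <- 2 * stats::pt(-abs(tstat), n - 2)
    edges$q_value <- stats::p.adjust(edges$p_value, method = "BH")
    edges$retained <- edges$r > cut | edges$r < -cut
    metadata(edges) <- list(cut = cut, n_samples = n, within = within,
                            n_dropped = nDropped)
    edges
}

#' Per-lncRNA summary of retained correlations
#'
#' For each lncRNA in the edge set: the mean of its retained positive
#' correlations, the mean of its retained negative correlations (NA when it
#' has none of that sign), the sum of |r| over retained edges, and the number
#' of retained edges. This is the quantity behind the "average correlation"
#' dot summaries and the sum-of-correlations ranking.
#'
#' @param edges output of [buildEdges()].
#' @return \code{DataFrame(lncrna_id, avg_positive_r, avg_negative_r,
#'   sum_abs_r, n_retained)}, one row per lncRNA seen in \code{edges}.
#' @export
summarizeLnc <- function(edges) {
    ids <- unique(edges$lncrna_id)
    rows <- lapply(ids, function(id) {
        r <- edges$r[edges$lncrna_id == id & edges$retained]
        pos <- r[r > 0]
        neg <- r[r < 0]
        DataFrame(lncrna_id = id,
                  avg_positive_r = if (length(pos)) mean(pos) else NA_real_,
                  avg_negative_r = if (length(neg)) mean(neg) else NA_real_,
                  sum_abs_r = sum(abs(r)),
                  n_retained = length(r))
    })
    if (!length(rows))
        return(DataFrame(lncrna_id = character(),
                         avg_positive_r = numeric(),
                         avg_negative_r = numeric(),
                         sum_abs_r = numeric(), n_retained = integer()))
    do.call(rbind, rows)
}

#' Select the lncRNAs with the greatest sum of correlations
#'
#' Ranked by \code{sum_abs_r} descending; ties broken by more retained
#' edges, then lexicographic gene id; truncated to \code{k} (default 10, the
#' published list length).
#'
#' @param summaries output of [summarizeLnc()].
#' @param k list length (>= 1).
#' @return character vector of lncRNA ids.
#' @export
selectTopLnc <- function(summaries, k = 10L) {
    stopifnot(k >= 1L)
    ord <- order(-summaries$sum_abs_r, -summaries$n_retained,
                 summaries$lncrna_id)
    utils::head(summaries$lncrna_id[ord], k)
}
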