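#' @importFrom stats pt p.adjust cor
NULL

#' Log2 fold change of tumor over control mean FPKM
#'
#' \code{log2((mean tumor FPKM + pseudocount) / (mean control FPKM +
#' pseudocount))}. The pseudocount (default 1 on the FPKM scale) keeps
#' all-zero genes at a fold change of 0 instead of -Inf/NaN.
#'
#' @param se a [LncExperiment-class].
#' @param geneId gene to evaluate.
#' @param pseudocount positive offset.
#' @return numeric log2 fold change.
#' @export
log2FC <- function(se, geneId, pseudocount = 1) {
    stopifnot(pseudocount > 0)
    if (!geneId %in% rownames(se))
        stop("gene not present in expression matrix: ", geneId)
    g <- sampleGroup(se)
    v <- fpkm(se)[geneId, ]
    log2((mean(v[g == "tumor"]) + pseudocount) /
         (mean(v[g == "control"]) + pseudocount))
}

#' Welch's two-sample t-test with a zero-variance floor
#'
#' Two-sided Welch t-test. When both groups have zero variance and equal
#' means the p-value is 1 by definition; any zero within-group variance is
#' otherwise replaced by the floor \code{varFloor} (default 1e-8) so that
#' clearly separated constant groups still yield a finite, tiny p-value.
#'
#' @param x,y numeric vectors (each length >= 2).
#' @param varFloor variance floor for degenerate groups.
#' @return two-sided p-value.
#' @export
welchTest <- function(x, y, varFloor = 1e-8) {
    n1 <- length(x)
    n2 <- length(y)
    if (n1 < 2L || n2 < 2L)
        stop("each group needs at least 2 samples")
    m1 <- mean(x)
    m2 <- mean(y)
    v1 <- stats::var(x)
    v2 <- stats::var(y)
    if (v1 == 0 && v2 == 0 && m1 == m2)
        return(1)
    if (v1 == 0) v1 <- varFloor
    if (v2 == 0) v2 <- varFloor
    se2 <- v1 / n1 + v2 / n2
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    2 * stats::pt(-abs(tstat), df)
}

#' Two-group test for one gene
#'
#' Welch t-test on \code{log2(FPKM + 1)} values, tumor vs control.
#'
#' @param se a [LncExperiment-class].
#' @param geneId gene to test.
#' @param varFloor variance floor, see [welchTest()].
#' @return two-sided p-value.
#' @export
deTest <- function(se, geneId, varFloor = 1e-8) {
    if (!geneId %in% rownames(se))
        stop("gene not present in expression matrix: ", geneId)
    g <- sampleGroup(se)
    if (sum(g == "tumor") < 2L || sum(g == "control") < 2L)
        stop("each group needs at least 2 samples")
    v <- log2Fpkm(se)[geneId, ]
    welchTest(v[g == "tumor"], v[g == "control"], varFloor = varFloor)
}

## Vectorized row means/vars by group on a matrix.
.rowVar <- function(m) {
    n <- ncol(m)
    if (n < 2L) return(rep(NA_real_, nrow(m)))
    mu <- rowMeans(m)
    rowSums((m - mu)^2) / (n - 1)
}

#' Call differentially expressed genes
#'
#' Applies the study's rule gene by gene: a gene is differentially expressed
#' when its |log2 fold change| exceeds \code{fcCut} (strictly; a fold change
#' of exactly 1 on the log2 scale does not pass) and its raw Welch p-value is
#' below \code{alpha}. Benjamini-Hochberg q-values over all tested genes are
#' reported for the user but do not gate the flag. Genes with all-zero
#' expression in both groups are reported non-significant with p = 1.
#'
#' @param se a [LncExperiment-class].
#' @param annotation optional biotype source: a \code{GRanges} with a
#'   \code{biotype} column (named by gene), a named character vector, or NULL
#'   to use \code{rowData(se)$biotype}. Only genes shared between \code{se}
#'   and the annotation are tested.
#' @param alpha raw p-value cutoff (default 0.05).
#' @param fcCut log2 fold-change cutoff (default 1).
#' @param pseudocount FPKM pseudocount for the fold change and the log
#'   transform (default 1).
#' @return a [DEResults-class] with one row per tested gene; thresholds in
#'   \code{metadata()}.
#' @examples
#' cohort <- generateCohort(simConfig(
#'     nMrna = 20L, nLncrna = 5L,
#'     plantedDe = data.frame(gene_id = "MRNA0001", log2_effect = 3),
#'     seed = 5L), interactions = FALSE)
#' res <- callDE(cohortExpression(cohort))
#' res[res$significant, ]
#' @export
callDE <- function(se, annotation = NULL, alpha = 0.05, fcCut = 1,
                   pseudocount = 1) {
    stopifnot(alpha > 0, alpha < 1, fcCut >= 0, pseudocount > 0)
    biotype <- .resolveBiotype(se, annotation)
    genes <- intersect(rownames(se), names(biotype))
    if (!length(genes))
        stop("no gene ids shared between expression matrix and annotation")
    m <- fpkm(se)[genes, , drop = FALSE]
    g <- sampleGroup(se)
    if (sum(g == "tumor") < 2L || sum(g == "control") < 2L)
        stop("each group needs at least 2 samples")
    mt <- m[, g == "tumor", drop = FALSE]
    mc <- m[, g == "control", drop = FALSE]
    l2fc <- log2((rowMeans(mt) + pseudocount) /
                 (rowMeans(mc) + pseudocount))
    lt <- log2(mt + pseudocount)
    lc <- log2(mc + pseudocount)
    p <- .welchRows(lt, lc)
    allZero <- rowSums(m) == 0
    p[allZero] <- 1
    q <- stats::p.adjust(p, method = "BH")
    sig <- abs(l2fc) > fcCut & p < alpha
    sig[allZero] <- FALSE
    dir <- rep("none", length(genes))
    dir[sig & l2fc > fcCut] <- "up"
    dir[sig & l2fc < -fcCut] <- "down"
    out <- new("DEResults", DataFrame(
        gene_id = genes,
        biotype = unname(biotype[genes]),
        log2fc = unname(l2fc),
        p_value = unname(p),
        q_value = unname(q),
        significant = unname(sig),
        direction = dir,
        row.names = genes))
    metadata(out) <- list(alpha = alpha, fc_cut = fcCut,
                          pseudocount = pseudocount,
                          n_tumor = sum(g == "tumor"),
                          n_control = sum(g == "control"))
    validObject(out)
    out
}

.welchRows <- function(mt, mc, varFloor = 1e-8) {
    n1 <- ncol(mt)
    n2 <- ncol(mc)
    m1 <- rowMeans(mt)
    m2 <- rowMeans(mc)
    v1 <- .rowVar(mt)
    v2 <- .rowVar(mc)
    degenerate <- v1 == 0 & v2 == 0 & m1 == m2
    v1[v1 == 0] <- varFloor
    v2[v2 == 0] <- varFloor
    se2 <- v1 / n1 + v2 / n2
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    p[degenerate] <- 1
    p
}

.resolveBiotype <- function(se, annotation) {
    if (is.null(annotation)) {
        b <- geneBiotype(se)
        return(b)
    }
    if (methods::is(annotation, "GRanges")) {
        b <- mcols(annotation)$biotype
        names(b) <- names(annotation)
        return(b)
    }
    if (is.character(annotation) && !is.null(names(annotation)))
        return(annotation)
    stop("'annotation' must be a GRanges with a biotype column, ",
         "a named character vector, or NULL")
}

#' Rank the most deregulated genes of a biotype
#'
#' Significant genes of the requested biotype ranked by |log2 fold change|
#' descending, ties broken by smaller p-value, then lexicographic gene id,
#' truncated to \code{k}. If fewer than \code{k} are available, all are
#' returned and a notice is emitted.
#'
#' @param results a [DEResults-class].
#' @param biotype \code{"coding"}, \code{"lncRNA"} or \code{"other"}.
#' @param k list length (>= 1).
#' @return character vector of gene ids, most deregulated first.
#' @export
topDeregulated <- function(results, biotype = c("lncRNA", "coding", "other"),
                           k = 400L) {
    biotype <- match.arg(biotype)
    stopifnot(k >= 1L)
    hit <- results[results$significant & results$biotype == biotype, ,
                   drop = FALSE]
    ord <- order(-abs(hit$log2fc), hit$p_value, hit$gene_id)
    ids <- hit$gene_id[ord]
    if (length(ids) < k)
        message("topDeregulated: only ", length(ids), " significant ",
                biotype, " genes available (k = ", k, ")")
    utils::head(ids, k)
}
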