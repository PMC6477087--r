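## Shared fixtures, all built in code.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
})

## Small LncExperiment from explicit FPKM rows.
makeSE <- function(rows, nTumor, nControl, biotype = NULL) {
    m <- do.call(rbind, rows)
    colnames(m) <- c(paste0("T", seq_len(nTumor)),
                     paste0("C", seq_len(nControl)))
    LncExperiment(m, group = rep(c("tumor", "control"), c(nTumor, nControl)),
                  biotype = biotype)
}

## One-interval GRanges in 1-based closed coordinates.
gr1 <- function(chrom, start, end, id, biotype = "coding", strand = "+") {
    g <- GRanges(chrom, IRanges(start, end), strand = strand,
                 gene_id = id, biotype = biotype)
    names(g) <- id
    g
}

## Write GTF text lines to a temp file.
writeGtfLines <- function(lines) {
    path <- tempfile(fileext = ".gtf")
    writeLines(lines, path)
    path
}

gtfLine <- function(chrom, feature, start, end, id, biotype,
                    strand = "+") {
    paste(chrom, "test", feature, start, end, ".", strand, ".",
          sprintf('gene_id "%s"; gene_biotype "%s";', id, biotype),
          sep = "\t")
}

## Minimal DEResults built by hand (for stages downstream of DE).
makeDE <- function(gene_id, biotype, log2fc, p_value,
                   alpha = 0.05, fcCut = 1) {
    sig <- abs(log2fc) > fcCut & p_value < alpha
    dir <- ifelse(sig & log2fc > fcCut, "up",
           ifelse(sig & log2fc < -fcCut, "down", "none"))
    out <- new("DEResults", DataFrame(
        gene_id = gene_id, biotype = biotype, log2fc = log2fc,
        p_value = p_value,
        q_value = stats::p.adjust(p_value, "BH"),
        significant = sig, direction = dir, row.names = gene_id))
    S4Vectors::metadata(out) <- list(alpha = alpha, fc_cut = fcCut)
    out
}

## Score table helper.
scoreTab <- function(lnc, mrna, energy) {
    DataFrame(lncrna_id = lnc, mrna_id = mrna, sumenergy = energy)
}

## Textbook Welch with the package's stated degenerate-variance contract,
## written independently for use as an oracle.
oracleWelchFloor <- function(x, y, eps = 1e-8) {
    v1 <- var(x); v2 <- var(y)
    if (v1 == 0 && v2 == 0 && mean(x) == mean(y)) return(1)
    if (v1 == 0) v1 <- eps
    if (v2 == 0) v2 <- eps
    se2 <- v1 / length(x) + v2 / length(y)
    tt <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((v1 / length(x))^2 / (length(x) - 1) +
                   (v2 / length(y))^2 / (length(y) - 1))
    2 * pt(-abs(tt), df)
}

## Independent textbook Welch p-value used as oracle.
oracleWelch <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    v1 <- var(x); v2 <- var(y)
    se2 <- v1 / n1 + v2 / n2
    tt <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    2 * pt(-abs(tt), df)
}
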