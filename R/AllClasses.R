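#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData rowData<-
#' @importFrom GenomicRanges GRanges
NULL

#' LncExperiment: FPKM expression for a tumor/control cohort
#'
#' A thin \linkS4class{SummarizedExperiment} subclass holding one assay,
#' \code{"fpkm"}, of non-negative gene-level expression values, with a
#' mandatory two-level \code{group} column (\code{"tumor"} / \code{"control"})
#' in \code{colData}. Gene biotypes (\code{"coding"}, \code{"lncRNA"},
#' \code{"other"}), when known, live in \code{rowData(x)$biotype}.
#'
#' @slot .
#'   inherits all slots from \code{SummarizedExperiment}.
#' @seealso [LncExperiment()] for the constructor, [fpkm()], [sampleGroup()],
#'   [geneBiotype()].
#' @export
setClass("LncExperiment", contains = "SummarizedExperiment")

setValidity("LncExperiment", function(object) {
    msg <- character()
    if (!"fpkm" %in% assayNames(object)) {
        msg <- c(msg, "assay 'fpkm' is required")
    } else {
        m <- assay(object, "fpkm")
        if (!is.numeric(m) || any(!is.finite(m)))
            msg <- c(msg, "fpkm values must be finite numbers")
        else if (any(m < 0))
            msg <- c(msg, "fpkm values must be >= 0")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    if (!"group" %in% colnames(colData(object))) {
        msg <- c(msg, "colData must contain a 'group' column")
    } else {
        g <- as.character(colData(object)$group)
        if (!all(g %in% c("tumor", "control")))
            msg <- c(msg, "group labels must be 'tumor' or 'control'")
        else if (!all(c("tumor", "control") %in% g))
            msg <- c(msg, "both the tumor and control group must be non-empty")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an LncExperiment
#'
#' @param fpkm numeric matrix of non-negative FPKM-like values, genes in rows
#'   (rownames = gene ids), samples in columns (colnames = sample ids).
#' @param group character vector, one of \code{"tumor"}/\code{"control"} per
#'   column of \code{fpkm}.
#' @param biotype optional character vector of per-gene biotypes
#'   (\code{"coding"}, \code{"lncRNA"}, \code{"other"}), either named by gene
#'   id or in row order.
#' @return a [LncExperiment-class] object.
#' @examples
#' m <- matrix(rexp(20, 1/10), 5, 4,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' se <- LncExperiment(m, group = c("tumor", "tumor", "control", "control"))
#' @export
LncExperiment <- function(fpkm, group, biotype = NULL) {
    stopifnot(is.matrix(fpkm))
    if (length(group) != ncol(fpkm))
        stop("'group' must have one label per sample column")
    cd <- DataFrame(group = as.character(group), row.names = colnames(fpkm))
    se <- SummarizedExperiment(assays = list(fpkm = fpkm), colData = cd)
    obj <- new("LncExperiment", se)
    if (!is.null(biotype)) {
        if (!is.null(names(biotype))) {
            missing <- setdiff(rownames(fpkm), names(biotype))
            if (length(missing))
                stop("biotype missing for gene(s): ",
                     paste(utils::head(missing, 5L), collapse = ", "))
            biotype <- biotype[rownames(fpkm)]
        } else if (length(biotype) != nrow(fpkm)) {
            stop("'biotype' must be named by gene id or match nrow(fpkm)")
        }
        rowData(obj)$biotype <- as.character(biotype)
    }
    validObject(obj)
    obj
}

#' Simulation configuration for a synthetic cohort
#'
#' Describes a synthetic two-group FPKM cohort: sample sizes, gene content,
#' planted differential effects, cis-coupled lncRNA/mRNA pairs at controlled
#' genomic gaps, trans correlation blocks driven by single lncRNAs, and the
#' log2-scale noise level. Expression for gene g in sample s is
#' 2^(baseline + group effect + shared latent factors + Gaussian noise).
#'
#' @slot nTumor,nControl integer sample sizes (each >= 2).
#' @slot nMrna,nLncrna integer gene counts; gene ids are
#'   \code{MRNA0001...} and \code{LNC0001...}.
#' @slot chromLength numeric, bases per synthetic chromosome; genes are laid
#'   out on 50 kb slots and wrap onto chr1, chr2, ... as needed.
#' @slot plantedDe data.frame(gene_id, log2_effect): log2 effects added to
#'   tumor samples only.
#' @slot cisPairs data.frame(lncrna_id, mrna_id, gap, r): the lncRNA is placed
#'   at genomic gap \code{gap} (bases between closest gene-body boundaries; 0
#'   places it inside the mRNA) and the pair is correlation-coupled at signed
#'   target Pearson r.
#' @slot transBlocks list of \code{list(lncrna_id=, mrna_ids=, r=)}: the
#'   driver lncRNA and every member share a latent factor at signed target r.
#' @slot noiseSd numeric, log2-scale Gaussian noise SD.
#' @slot baselineLog2Mean numeric, log2 of the typical baseline FPKM.
#' @slot seed integer RNG seed.
#' @seealso [simConfig()], [generateCohort()].
#' @export
setClass("SimConfig",
    representation(
        nTumor = "integer", nControl = "integer",
        nMrna = "integer", nLncrna = "integer",
        chromLength = "numeric",
        plantedDe = "data.frame",
        cisPairs = "data.frame",
        transBlocks = "list",
        noiseSd = "numeric",
        baselineLog2Mean = "numeric",
        seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nTumor < 2L)
        msg <- c(msg, "n_tumor: at least 2 tumor samples are required")
    if (object@nControl < 2L)
        msg <- c(msg, "n_control: at least 2 control samples are required")
    if (object@nMrna < 1L || object@nLncrna < 1L)
        msg <- c(msg, "n_mrna/n_lncrna: at least one gene of each biotype")
    if (object@noiseSd < 0)
        msg <- c(msg, "noise_sd: must be >= 0")
    if (object@chromLength < 5e4)
        msg <- c(msg, "chrom_length: must hold at least one 50 kb gene slot")
    ids <- c(.mrnaIds(object@nMrna), .lncIds(object@nLncrna))
    pd <- object@plantedDe
    if (nrow(pd)) {
        bad <- setdiff(pd$gene_id, ids)
        if (length(bad))
            msg <- c(msg, paste0("planted_de: unknown gene id(s): ",
                                 paste(bad, collapse = ", ")))
    }
    cp <- object@cisPairs
    if (nrow(cp)) {
        bad <- setdiff(c(cp$lncrna_id, cp$mrna_id), ids)
        if (length(bad))
            msg <- c(msg, paste0("cis_pairs: unknown gene id(s): ",
                                 paste(bad, collapse = ", ")))
        if (!all(cp$lncrna_id %in% .lncIds(object@nLncrna)))
            msg <- c(msg, "cis_pairs: lncrna_id must be a lncRNA gene")
        if (!all(cp$mrna_id %in% .mrnaIds(object@nMrna)))
            msg <- c(msg, "cis_pairs: mrna_id must be an mRNA gene")
        if (any(cp$gap < 0))
            msg <- c(msg, "cis_pairs: every gap must be >= 0")
        if (any(abs(cp$r) >= 1))
            msg <- c(msg, "cis_pairs: target r must lie in (-1, 1)")
        if (anyDuplicated(cp$lncrna_id))
            msg <- c(msg, "cis_pairs: each lncRNA may appear in one pair only")
    }
    for (blk in object@transBlocks) {
        if (!all(c("lncrna_id", "mrna_ids", "r") %in% names(blk))) {
            msg <- c(msg,
                "trans_blocks: each block needs lncrna_id, mrna_ids, r")
            next
        }
        bad <- setdiff(c(blk$lncrna_id, blk$mrna_ids), ids)
        if (length(bad))
            msg <- c(msg, paste0("trans_blocks: unknown gene id(s): ",
                                 paste(bad, collapse = ", ")))
        if (abs(blk$r) >= 1)
            msg <- c(msg, "trans_blocks: target r must lie in (-1, 1)")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn SimConfig-class constructor with the study's default shape:
#'   7 tumors vs 3 retina controls, log2 noise SD 0.5, baseline log2 FPKM 5.
#' @param nTumor,nControl,nMrna,nLncrna,chromLength,plantedDe,cisPairs,transBlocks,noiseSd,baselineLog2Mean,seed
#'   see the class slots.
#' @export
simConfig <- function(nTumor = 7L, nControl = 3L, nMrna = 60L, nLncrna = 30L,
                      chromLength = 5e6, plantedDe = NULL, cisPairs = NULL,
                      transBlocks = list(), noiseSd = 0.5,
                      baselineLog2Mean = 5, seed = 1L) {
    if (is.null(plantedDe))
        plantedDe <- data.frame(gene_id = character(), log2_effect = numeric())
    if (is.null(cisPairs))
        cisPairs <- data.frame(lncrna_id = character(), mrna_id = character(),
                               gap = numeric(), r = numeric())
    new("SimConfig",
        nTumor = as.integer(nTumor), nControl = as.integer(nControl),
        nMrna = as.integer(nMrna), nLncrna = as.integer(nLncrna),
        chromLength = as.numeric(chromLength),
        plantedDe = as.data.frame(plantedDe),
        cisPairs = as.data.frame(cisPairs),
        transBlocks = transBlocks,
        noiseSd = as.numeric(noiseSd),
        baselineLog2Mean = as.numeric(baselineLog2Mean),
        seed = as.integer(seed))
}

.mrnaIds <- function(n) sprintf("MRNA%04d", seq_len(n))
.lncIds <- function(n) sprintf("LNC%04d", seq_len(n))

#' A generated synthetic cohort
#'
#' Bundle of everything [generateCohort()] emits: the annotation
#' (\code{GRanges} with \code{gene_id} and \code{biotype}), the
#' [LncExperiment-class] expression object, the clinical-style sample sheet,
#' the interaction-score table, and \code{truth}, the planted effects/pairs/
#' blocks/targets used by recovery tests.
#'
#' @slot config the [SimConfig-class] that produced the cohort.
#' @slot annotation \code{GRanges} named by gene id.
#' @slot expression [LncExperiment-class].
#' @slot samples \code{DataFrame} sample sheet.
#' @slot interactions \code{DataFrame} with lncrna_id, mrna_id, sumenergy.
#' @slot truth list(plantedDe, cisPairs, transBlocks, trueTargets,
#'   promiscuous).
#' @export
setClass("SyntheticCohort",
    representation(
        config = "SimConfig",
        annotation = "GRanges",
        expression = "LncExperiment",
        samples = "DataFrame",
        interactions = "DataFrame",
        truth = "list"))

setValidity("SyntheticCohort", function(object) {
    msg <- character()
    cfg <- object@config
    se <- object@expression
    if (ncol(se) != cfg@nTumor + cfg@nControl)
        msg <- c(msg, "expression must have n_tumor + n_control columns")
    if (nrow(se) != cfg@nMrna + cfg@nLncrna)
        msg <- c(msg, "expression must have n_mrna + n_lncrna rows")
    if (!identical(sort(names(object@annotation)), sort(rownames(se))))
        msg <- c(msg, "annotation and expression must cover the same genes")
    if (length(msg)) msg else TRUE
})

#' Differential-expression results
#'
#' A \code{DataFrame} subclass (one row per gene) with columns
#' \code{gene_id}, \code{biotype}, \code{log2fc}, \code{p_value},
#' \code{q_value} (Benjamini-Hochberg, reported but not gating),
#' \code{significant} and \code{direction}. The thresholds used are stored in
#' \code{metadata()}.
#'
#' @seealso [callDE()]
#' @export
setClass("DEResults", contains = "DFrame")

setValidity("DEResults", function(object) {
    need <- c("gene_id", "biotype", "log2fc", "p_value", "q_value",
              "significant", "direction")
    miss <- setdiff(need, colnames(object))
    if (length(miss))
        return(paste("missing column(s):", paste(miss, collapse = ", ")))
    if (any(object$p_value < 0 | object$p_value > 1, na.rm = TRUE))
        return("p_value must lie in [0, 1]")
    if (any(object$q_value < 0 | object$q_value > 1, na.rm = TRUE))
        return("q_value must lie in [0, 1]")
    TRUE
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nTumor, "tumor vs", object@nControl,
        "control samples;", object@nMrna, "mRNAs +", object@nLncrna,
        "lncRNAs\n")
    cat("  planted DE effects:", nrow(object@plantedDe),
        "| cis pairs:", nrow(object@cisPairs),
        "| trans blocks:", length(object@transBlocks), "\n")
    cat("  noise sd (log2):", object@noiseSd,
        "| baseline log2 FPKM:", object@baselineLog2Mean,
        "| seed:", object@seed, "\n")
})

setMethod("show", "SyntheticCohort", function(object) {
    cat("SyntheticCohort\n")
    show(object@config)
    cat("  interactions:", nrow(object@interactions), "score rows\n")
})
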