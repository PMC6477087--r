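#' Interaction-energy retention of lncRNAs
#'
#' A lncRNA is retained for trans-target analysis when it has SUMENERGY
#' scores strictly above \code{energyCut} (default 2000) for at least
#' \code{minTargets} targets (default 10; the count bound is inclusive).
#'
#' @param scores \code{DataFrame}/data.frame with \code{lncrna_id},
#'   \code{mrna_id}, \code{sumenergy}.
#' @param energyCut strict score threshold.
#' @param minTargets inclusive count threshold.
#' @return sorted character vector of retained lncRNA ids.
#' @export
retainLncrnas <- function(scores, energyCut = 2000, minTargets = 10L) {
    strong <- scores$lncrna_id[scores$sumenergy > energyCut]
    if (!length(strong)) return(character())
    tab <- table(strong)
    sort(names(tab)[tab >= minTargets])
}

#' Substrate-strength filter
#'
#' Keeps score rows whose lncRNA is retained and whose SUMENERGY is strictly
#' above \code{substrateCut} (default 1500), removing weak substrates.
#'
#' @param scores score table as in [retainLncrnas()].
#' @param retained retained lncRNA ids ([retainLncrnas()] output).
#' @param substrateCut strict score threshold.
#' @return filtered score table.
#' @export
filterSubstrates <- function(scores, retained, substrateCut = 1500) {
    keep <- scores$lncrna_id %in% retained & scores$sumenergy > substrateCut
    scores[keep, , drop = FALSE]
}

#' Drop promiscuous mRNAs
#'
#' mRNAs predicted as targets of more than \code{maxLnc} distinct lncRNAs
#' (default 4, so 5 or more) are treated as false positives and removed
#' entirely. Applied after [filterSubstrates()], so the count covers retained
#' lncRNAs only.
#'
#' @param scores filtered score table.
#' @param maxLnc maximum allowed number of distinct lncRNAs per mRNA.
#' @return list(scores = kept rows, dropped = sorted dropped mRNA ids).
#' @export
dropPromiscuous <- function(scores, maxLnc = 4L) {
    if (!nrow(scores))
        return(list(scores = scores, dropped = character()))
    key <- !duplicated(paste(scores$lncrna_id, scores$mrna_id, sep = "\r"))
    counts <- table(scores$mrna_id[key])
    dropped <- sort(names(counts)[counts > maxLnc])
    list(scores = scores[!scores$mrna_id %in% dropped, , drop = FALSE],
         dropped = dropped)
}

#' Full SUMENERGY filter chain
#'
#' Convenience wrapper applying the three rules in their stated order:
#' retention (>2000 for >= 10 targets), substrate filter (>1500), then
#' promiscuity exclusion (>4 lncRNAs). The order matters: promiscuity is
#' counted on the substrate-filtered table.
#'
#' @param scores raw score table.
#' @param energyCut,minTargets,substrateCut,maxLnc thresholds as in the
#'   individual steps.
#' @return list(scores, retained, dropped).
#' @export
transTargetFilter <- function(scores, energyCut = 2000, minTargets = 10L,
                              substrateCut = 1500, maxLnc = 4L) {
    retained <- retainLncrnas(scores, energyCut, minTargets)
    filtered <- filterSubstrates(scores, retained, substrateCut)
    prom <- dropPromiscuous(filtered, maxLnc)
    list(scores = prom$scores, retained = retained, dropped = prom$dropped)
}

#' Stratify surviving trans targets into volcano quadrants
#'
#' Targets of lncRNAs whose differential-expression direction matches
#' \code{lncDirection} are assigned a quadrant from their own expression
#' change, with the fold change on the linear scale (2-fold = |log2fc| > 1):
#' \code{sig_up} (>2-fold up, p < 0.05), \code{ns_up} (>2-fold up,
#' p >= 0.05), \code{sig_down} (>2-fold down, p < 0.05), \code{ns_down}
#' (>2-fold down, p >= 0.05), else \code{unchanged}. Targets missing from
#' \code{de} are reported \code{unchanged} and logged. The gene-count
#' summary counts distinct mRNAs per quadrant.
#'
#' @param scores filtered score table (after [transTargetFilter()]).
#' @param de a [DEResults-class] covering the target mRNAs.
#' @param lncDirection \code{"up"} or \code{"down"}: which deregulated
#'   lncRNAs' targets to stratify.
#' @param alpha significance gate for the sig_* quadrants (default 0.05, per
#'   the volcano-figure legend).
#' @param fcCut log2 fold-change magnitude defining "2-fold" (default 1).
#' @return list(targets = \code{DataFrame(lncrna_id, mrna_id, sumenergy,
#'   mrna_log2fc, mrna_p, quadrant)}, summary = \code{DataFrame(quadrant,
#'   n_genes)}).
#' @export
stratifyTargets <- function(scores, de, lncDirection = c("up", "down"),
                            alpha = 0.05, fcCut = 1) {
    lncDirection <- match.arg(lncDirection)
    lncDir <- de$direction[match(scores$lncrna_id, de$gene_id)]
    keep <- !is.na(lncDir) & lncDir == lncDirection
    sub <- scores[keep, , drop = FALSE]
    i <- match(sub$mrna_id, de$gene_id)
    l2fc <- de$log2fc[i]
    p <- de$p_value[i]
    missing <- is.na(i)
    if (any(missing))
        message("stratifyTargets: ", sum(missing),
                " target(s) missing from DE results, reported unchanged")
    quadrant <- rep("unchanged", nrow(sub))
    up <- !missing & l2fc > fcCut
    down <- !missing & l2fc < -fcCut
    quadrant[up & p < alpha] <- "sig_up"
    quadrant[up & p >= alpha] <- "ns_up"
    quadrant[down & p < alpha] <- "sig_down"
    quadrant[down & p >= alpha] <- "ns_down"
    targets <- DataFrame(
        lncrna_id = sub$lncrna_id, mrna_id = sub$mrna_id,
        sumenergy = sub$sumenergy,
        mrna_log2fc = ifelse(missing, NA_real_, l2fc),
        mrna_p = ifelse(missing, NA_real_, p),
        quadrant = quadrant)
    levs <- c("sig_up", "ns_up", "unchanged", "ns_down", "sig_down")
    counts <- vapply(levs, function(qd)
        length(unique(targets$mrna_id[targets$quadrant == qd])), integer(1))
    list(targets = targets,
         summary = DataFrame(lnc_direction = lncDirection, quadrant = levs,
                             n_genes = unname(counts)))
}
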