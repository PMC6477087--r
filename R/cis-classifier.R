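#' @importFrom GenomicRanges distance findOverlaps countOverlaps
NULL

#' Genomic gap between two gene intervals
#'
#' Bases between the closest gene-body boundaries, strand-agnostic:
#' 0 when the intervals intersect (or touch), \code{Inf} when the genes lie
#' on different chromosomes.
#'
#' @param a,b single-range \code{GRanges} (or two rows of one annotation).
#' @return numeric gap in bases (0, positive, or Inf).
#' @export
intervalGap <- function(a, b) {
    stopifnot(length(a) == 1L, length(b) == 1L)
    d <- GenomicRanges::distance(a, b, ignore.strand = TRUE)
    if (is.na(d)) Inf else as.numeric(d)
}

## Distance class from a gap and an intersection flag. Touching-but-not-
## overlapping intervals (gap 0, no intersection) count as adjoining: they
## are certainly "within 5 kb".
.distanceClass <- function(gap, intersects, adjoining = 5000,
                           proximal = 10000) {
    unname(ifelse(intersects, "overlap",
           ifelse(gap <= adjoining, "adjoining",
           ifelse(gap <= proximal, "proximal", "others"))))
}

#' Classify a lncRNA by distance to its nearest gene
#'
#' The class is determined by the minimum gap over all other genes on the
#' same chromosome, irrespective of their coding nature: \code{overlap} when
#' the nearest gene intersects the lncRNA, \code{adjoining} within 5 kb,
#' \code{proximal} within 10 kb, \code{others} beyond 10 kb (strictly) or
#' when no gene shares the chromosome. Ties at the minimum gap prefer an
#' intersecting gene, then the smaller gene id.
#'
#' @param lncId lncRNA gene id.
#' @param annotation \code{GRanges} named by gene id with a \code{biotype}
#'   column (the lncRNA itself is excluded from the candidates).
#' @param adjoining,proximal class boundaries in bases (defaults 5000/10000).
#' @return list(distance_class, neighbor_id, gap_bp).
#' @export
classifyLnc <- function(lncId, annotation, adjoining = 5000,
                        proximal = 10000) {
    if (!lncId %in% names(annotation))
        stop("gene not present in annotation: ", lncId)
    lnc <- annotation[lncId]
    others <- annotation[names(annotation) != lncId]
    others <- others[as.character(seqnames(others)) ==
                     as.character(seqnames(lnc))]
    if (!length(others))
        return(list(distance_class = "others", neighbor_id = NA_character_,
                    gap_bp = Inf))
    gaps <- GenomicRanges::distance(rep(lnc, length(others)), others,
                                    ignore.strand = TRUE)
    hits <- GenomicRanges::countOverlaps(others, lnc,
                                         ignore.strand = TRUE) > 0
    minGap <- min(gaps)
    cand <- which(gaps == minGap)
    cand <- cand[order(!hits[cand], names(others)[cand])]
    best <- cand[1L]
    list(distance_class = .distanceClass(gaps[best], hits[best],
                                         adjoining, proximal),
         neighbor_id = names(others)[best],
         gap_bp = as.numeric(gaps[best]))
}

#' Pair deregulated lncRNAs with deregulated protein-coding neighbors
#'
#' For every significantly deregulated lncRNA, all significantly deregulated
#' protein-coding genes within the overlap/adjoining/proximal classes
#' (candidates beyond \code{maxClass} are excluded) are emitted as pairs with
#' their distance class, gap, direction labels and concordance (concordant
#' when lncRNA and neighbor move in the same direction, anti-correlated
#' otherwise). The nearest qualifying neighbor of each lncRNA is flagged
#' \code{primary}. lncRNAs with no qualifying neighbor are listed in
#' \code{metadata()$unpaired}.
#'
#' @param de a [DEResults-class].
#' @param annotation \code{GRanges} named by gene id with a \code{biotype}
#'   column.
#' @param maxClass outermost class to report (default \code{"proximal"}).
#' @param adjoining,proximal class boundaries in bases.
#' @return \code{DataFrame(lncrna_id, neighbor_id, distance_class, gap_bp,
#'   lnc_direction, neighbor_direction, concordance, primary)}.
#' @export
pairWithDeNeighbors <- function(de, annotation,
                                maxClass = c("proximal", "adjoining",
                                             "overlap"),
                                adjoining = 5000, proximal = 10000) {
    maxClass <- match.arg(maxClass)
    classRank <- c(overlap = 1L, adjoining = 2L, proximal = 3L, others = 4L)
    maxRank <- classRank[maxClass]
    sig <- de[de$significant, , drop = FALSE]
    lncs <- sig$gene_id[sig$biotype == "lncRNA"]
    coding <- sig$gene_id[sig$biotype == "coding"]
    lncs <- intersect(lncs, names(annotation))
    coding <- intersect(coding, names(annotation))
    dirOf <- function(ids) sig$direction[match(ids, sig$gene_id)]
    empty <- DataFrame(lncrna_id = character(), neighbor_id = character(),
                       distance_class = character(), gap_bp = numeric(),
                       lnc_direction = character(),
                       neighbor_direction = character(),
                       concordance = character(), primary = logical())
    rows <- list()
    unpaired <- character()
    for (id in lncs) {
        lnc <- annotation[id]
        cand <- annotation[setdiff(coding, id)]
        cand <- cand[as.character(seqnames(cand)) ==
                     as.character(seqnames(lnc))]
        if (!length(cand)) { unpaired <- c(unpaired, id); next }
        gaps <- as.numeric(GenomicRanges::distance(
            rep(lnc, length(cand)), cand, ignore.strand = TRUE))
        hits <- GenomicRanges::countOverlaps(cand, lnc,
                                             ignore.strand = TRUE) > 0
        cls <- .distanceClass(gaps, hits, adjoining, proximal)
        keep <- classRank[cls] <= maxRank
        if (!any(keep)) { unpaired <- c(unpaired, id); next }
        nid <- names(cand)[keep]
        g <- gaps[keep]
        nearest <- nid[order(g, nid)][1L]
        ld <- dirOf(id)
        nd <- dirOf(nid)
        rows[[id]] <- DataFrame(
            lncrna_id = id, neighbor_id = nid,
            distance_class = cls[keep], gap_bp = g,
            lnc_direction = ld, neighbor_direction = nd,
            concordance = ifelse(ld == nd, "concordant", "anti-correlated"),
            primary = nid == nearest)
    }
    out <- if (length(rows)) do.call(rbind, unname(rows)) else empty
    metadata(out) <- list(unpaired = unpaired, max_class = maxClass,
                          adjoining = adjoining, proximal = proximal)
    out
}
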