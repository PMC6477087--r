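#' Accessors for LncExperiment and SyntheticCohort
#'
#' \code{fpkm()} returns the FPKM assay matrix; \code{log2Fpkm()} returns
#' \code{log2(fpkm + pseudocount)}, the scale on which the two-group test and
#' all correlations are computed; \code{sampleGroup()} the tumor/control
#' labels; \code{geneBiotype()} the per-gene biotype (or \code{"other"} when
#' unannotated).
#'
#' @param x a [LncExperiment-class] (or [SyntheticCohort-class] where noted).
#' @param pseudocount positive offset avoiding log2(0); default 1.
#' @return \code{fpkm}/\code{log2Fpkm}: numeric matrix; \code{sampleGroup}:
#'   named character vector; \code{geneBiotype}: named character vector.
#' @name lnc-accessors
NULL

#' @rdname lnc-accessors
#' @export
setGeneric("fpkm", function(x) standardGeneric("fpkm"))

#' @rdname lnc-accessors
#' @export
setMethod("fpkm", "LncExperiment", function(x) assay(x, "fpkm"))

#' @rdname lnc-accessors
#' @export
log2Fpkm <- function(x, pseudocount = 1) {
    stopifnot(pseudocount > 0)
    log2(fpkm(x) + pseudocount)
}

#' @rdname lnc-accessors
#' @export
setGeneric("sampleGroup", function(x) standardGeneric("sampleGroup"))

#' @rdname lnc-accessors
#' @export
setMethod("sampleGroup", "LncExperiment", function(x) {
    g <- as.character(colData(x)$group)
    names(g) <- colnames(x)
    g
})

#' @rdname lnc-accessors
#' @export
setGeneric("geneBiotype", function(x) standardGeneric("geneBiotype"))

#' @rdname lnc-accessors
#' @export
setMethod("geneBiotype", "LncExperiment", function(x) {
    b <- rowData(x)$biotype
    if (is.null(b)) b <- rep("other", nrow(x))
    names(b) <- rownames(x)
    b
})

#' @rdname lnc-accessors
#' @export
setGeneric("cohortExpression", function(x) standardGeneric("cohortExpression"))

#' @rdname lnc-accessors
#' @export
setMethod("cohortExpression", "SyntheticCohort", function(x) x@expression)

#' @rdname lnc-accessors
#' @export
setGeneric("cohortAnnotation", function(x) standardGeneric("cohortAnnotation"))

#' @rdname lnc-accessors
#' @export
setMethod("cohortAnnotation", "SyntheticCohort", function(x) x@annotation)

#' @rdname lnc-accessors
#' @export
setGeneric("cohortSamples", function(x) standardGeneric("cohortSamples"))

#' @rdname lnc-accessors
#' @export
setMethod("cohortSamples", "SyntheticCohort", function(x) x@samples)

#' @rdname lnc-accessors
#' @export
setGeneric("cohortInteractions",
           function(x) standardGeneric("cohortInteractions"))

#' @rdname lnc-accessors
#' @export
setMethod("cohortInteractions", "SyntheticCohort", function(x) x@interactions)

#' @rdname lnc-accessors
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' @rdname lnc-accessors
#' @export
setMethod("cohortTruth", "SyntheticCohort", function(x) x@truth)
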