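#' @importFrom GenomicRanges GRanges seqnames start end strand mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom rtracklayer import export
#' @importFrom utils read.delim write.table head
NULL

## Ensembl release-75 vocabulary for the lncRNA class.
.LNC_BIOTYPES <- c("lincRNA", "lncRNA", "antisense", "processed_transcript")

.mapBiotype <- function(x) {
    out <- rep("other", length(x))
    out[x == "protein_coding"] <- "coding"
    out[x %in% .LNC_BIOTYPES] <- "lncRNA"
    out
}

.unmapBiotype <- function(x) {
    c(coding = "protein_coding", lncRNA = "lincRNA", other = "misc_RNA")[x]
}

#' Read a GTF annotation into gene-level GRanges
#'
#' Parses a GTF 2.2 file and collapses it to one interval per \code{gene_id},
#' the envelope (min start, max end) over all of the gene's feature lines.
#' Biotypes from the \code{gene_biotype} attribute are normalized to
#' \code{coding} (protein_coding), \code{lncRNA} (lincRNA, lncRNA, antisense,
#' processed_transcript -- the Ensembl release-75 non-coding vocabulary) or
#' \code{other}. Coordinates stay in the 1-based inclusive GRanges convention.
#'
#' @param path GTF file.
#' @return \code{GRanges} named by gene id with metadata columns
#'   \code{gene_id} and \code{biotype}.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1", "src", "exon", "100", "200", ".", "+", ".",
#'                  "gene_id \"G1\"; gene_biotype \"protein_coding\";",
#'                  sep = "\t"), gtf)
#' readGtf(gtf)
#' @export
readGtf <- function(path) {
    if (!file.exists(path))
        stop("GTF file not found: ", path)
    .validateGtfLines(path)
    gr <- rtracklayer::import(path, format = "gtf")
    if (!length(gr))
        stop("GTF contains no features: ", path)
    if (is.null(mcols(gr)$gene_id) || anyNA(mcols(gr)$gene_id))
        stop("GTF feature without a gene_id attribute in ", path)
    bio <- mcols(gr)$gene_biotype
    if (is.null(bio)) bio <- rep(NA_character_, length(gr))
    ids <- as.character(mcols(gr)$gene_id)
    # envelope over all feature lines of each gene
    lv <- unique(ids)
    f <- factor(ids, levels = lv)
    first <- match(lv, ids)
    firstBio <- vapply(split(bio, f), function(b) {
        b <- b[!is.na(b)]
        if (length(b)) b[1L] else NA_character_
    }, character(1))
    out <- GRanges(as.character(seqnames(gr))[first],
                   IRanges(as.integer(tapply(start(gr), f, min)),
                           as.integer(tapply(end(gr), f, max))),
                   strand = as.character(strand(gr))[first],
                   gene_id = lv,
                   biotype = .mapBiotype(as.character(firstBio)))
    names(out) <- lv
    out
}

## Structural pre-pass so contract violations carry a line number; content
## parsing itself is rtracklayer's job.
.validateGtfLines <- function(path) {
    lines <- readLines(path, warn = FALSE)
    for (i in seq_along(lines)) {
        ln <- lines[i]
        if (!nzchar(ln) || startsWith(ln, "#")) next
        f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
        if (length(f) < 9L)
            stop("malformed GTF line ", i, " in ", path,
                 ": expected 9 tab-separated fields, found ", length(f))
        s <- suppressWarnings(as.numeric(f[4L]))
        e <- suppressWarnings(as.numeric(f[5L]))
        if (is.na(s) || is.na(e) || s < 1 || e < s)
            stop("malformed GTF line ", i, " in ", path,
                 ": invalid start/end '", f[4L], "'/'", f[5L], "'")
        if (!grepl("gene_id", f[9L], fixed = TRUE))
            stop("GTF line ", i, " in ", path,
                 ": missing gene_id attribute")
    }
    invisible(TRUE)
}

#' Write gene-level GRanges as GTF
#'
#' One \code{gene} feature line per record; internal biotypes are written back
#' with Ensembl vocabulary (coding -> protein_coding, lncRNA -> lincRNA,
#' other -> misc_RNA) so that [readGtf()] round-trips.
#'
#' @param annotation GRanges with \code{gene_id} and \code{biotype} columns.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeGtf <- function(annotation, path) {
    gr <- annotation
    mcols(gr) <- NULL
    mcols(gr)$source <- "lncscope"
    mcols(gr)$type <- "gene"
    mcols(gr)$gene_id <- mcols(annotation)$gene_id
    mcols(gr)$gene_biotype <- unname(.unmapBiotype(mcols(annotation)$biotype))
    tryCatch(rtracklayer::export(gr, path, format = "gtf"),
             error = function(e) stop("failed to write GTF to ", path, ": ",
                                      conditionMessage(e)))
    invisible(path)
}

#' Read an FPKM matrix plus sample sheet into an LncExperiment
#'
#' The expression file is a TSV whose first column is the gene id and whose
#' remaining columns are samples (header row = sample ids). Every sample
#' column must appear in the sample sheet, which provides the tumor/control
#' group. Genes whose row is all zero are kept but flagged in
#' \code{rowData(x)$all_zero}.
#'
#' @param path expression TSV.
#' @param sampleSheetPath sample sheet TSV (see [readSampleSheet()]).
#' @return a [LncExperiment-class].
#' @export
readExpression <- function(path, sampleSheetPath) {
    samples <- readSampleSheet(sampleSheetPath)
    tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
    if (ncol(tab) < 2L)
        stop("expression file needs a gene id column plus >= 1 sample: ", path)
    ids <- as.character(tab[[1L]])
    m <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    missing <- setdiff(colnames(m), samples$sample_id)
    if (length(missing))
        stop("sample(s) in expression matrix absent from sample sheet: ",
             paste(missing, collapse = ", "))
    if (any(!is.finite(m)))
        stop("non-numeric or non-finite expression value in ", path)
    if (any(m < 0)) {
        bad <- which(m < 0, arr.ind = TRUE)[1L, ]
        stop("negative expression value for gene '", rownames(m)[bad[1L]],
             "' in ", path)
    }
    grp <- samples$group[match(colnames(m), samples$sample_id)]
    se <- LncExperiment(m, group = grp)
    rowData(se)$all_zero <- rowSums(m) == 0
    se
}

#' Read a clinical-style sample sheet
#'
#' Expects TSV columns \code{sample_id} (or \code{patient_id}), \code{group}
#' (tumor/control), \code{age}, \code{sex}, \code{invasiveness} and optional
#' \code{laterality}. Ages written as \code{"N Y"} (years) or
#' \code{"N Months"} are parsed into months; \code{"N/A"} becomes missing.
#' Sex and invasiveness are normalized case-insensitively; \code{"N/A"} maps
#' to \code{unknown} / \code{not-applicable}.
#'
#' @param path sample sheet TSV.
#' @return \code{DataFrame} with columns sample_id, group, age_months, sex,
#'   invasiveness, laterality.
#' @export
readSampleSheet <- function(path) {
    tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
    names(tab) <- tolower(names(tab))
    if ("patient_id" %in% names(tab) && !"sample_id" %in% names(tab))
        tab$sample_id <- tab$patient_id
    need <- c("sample_id", "group", "age", "sex", "invasiveness")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("sample sheet ", path, " is missing column(s): ",
             paste(miss, collapse = ", "))
    group <- tolower(tab$group)
    if (!all(group %in% c("tumor", "control")))
        stop("sample sheet group labels must be tumor/control")
    sex <- tolower(tab$sex)
    sex[sex %in% c("n/a", "na", "", "unknown") | is.na(sex)] <- "unknown"
    if (!all(sex %in% c("male", "female", "unknown")))
        stop("unrecognized sex value: ",
             paste(setdiff(sex, c("male", "female", "unknown")),
                   collapse = ", "))
    inv <- tolower(tab$invasiveness)
    inv[inv %in% c("n/a", "na", "") | is.na(inv)] <- "not-applicable"
    if (!all(inv %in% c("invasive", "non-invasive", "not-applicable")))
        stop("unrecognized invasiveness value: ",
             paste(setdiff(inv, c("invasive", "non-invasive",
                                  "not-applicable")), collapse = ", "))
    if (any(group == "control" & inv != "not-applicable"))
        stop("control samples must have invasiveness N/A")
    age <- vapply(as.character(tab$age), parseAgeMonths, numeric(1))
    if (any(!is.na(age) & age < 0))
        stop("negative age in sample sheet")
    lat <- if ("laterality" %in% names(tab)) as.character(tab$laterality)
           else rep(NA_character_, nrow(tab))
    lat[lat %in% c("N/A", "n/a", "")] <- NA_character_
    DataFrame(sample_id = as.character(tab$sample_id), group = group,
              age_months = unname(age), sex = sex, invasiveness = inv,
              laterality = lat)
}

#' Parse a clinical age string into months
#'
#' \code{"6 Y"} -> 72, \code{"8 Months"} -> 8, \code{"N/A"} -> NA.
#'
#' @param x one age string.
#' @return age in months (numeric) or NA.
#' @export
parseAgeMonths <- function(x) {
    x <- trimws(x)
    if (is.na(x) || toupper(x) %in% c("N/A", "NA", ""))
        return(NA_real_)
    if (grepl("^[0-9]+(\\.[0-9]+)?\\s*(Y|YR|YRS|YEAR|YEARS)$", x,
              ignore.case = TRUE))
        return(12 * as.numeric(sub("\\s*[A-Za-z]+$", "", x)))
    if (grepl("^[0-9]+(\\.[0-9]+)?\\s*(M|MO|MONTH|MONTHS)$", x,
              ignore.case = TRUE))
        return(as.numeric(sub("\\s*[A-Za-z]+$", "", x)))
    stop("unparseable age string: \"", x, "\"")
}

#' Read an RNA-RNA interaction score table
#'
#' TSV with columns \code{lncrna_id}, \code{mrna_id}, \code{sumenergy}.
#' Duplicate (lncRNA, mRNA) rows are collapsed keeping the maximum score
#' (conservative for a retention filter keyed on high scores). Scores must be
#' numeric and > 0.
#'
#' @param path interaction TSV.
#' @return \code{DataFrame} with one row per (lncRNA, mRNA) pair.
#' @export
readInteractions <- function(path) {
    tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE,
                      colClasses = c("character", "character", "character"))
    need <- c("lncrna_id", "mrna_id", "sumenergy")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("interaction table ", path, " is missing column(s): ",
             paste(miss, collapse = ", "))
    if (!nrow(tab))
        return(DataFrame(lncrna_id = character(), mrna_id = character(),
                         sumenergy = numeric()))
    score <- suppressWarnings(as.numeric(tab$sumenergy))
    if (anyNA(score))
        stop("non-numeric SUMENERGY score at row ",
             which(is.na(score))[1L], " of ", path)
    if (any(score <= 0))
        stop("SUMENERGY scores must be > 0 (row ",
             which(score <= 0)[1L], " of ", path, ")")
    key <- paste(tab$lncrna_id, tab$mrna_id, sep = "\r")
    best <- tapply(score, key, max)
    first <- !duplicated(key)
    out <- DataFrame(lncrna_id = tab$lncrna_id[first],
                     mrna_id = tab$mrna_id[first],
                     sumenergy = as.numeric(best[key[first]]))
    out[order(out$lncrna_id, out$mrna_id), , drop = FALSE]
}

#' Validate a set of pipeline inputs
#'
#' Runs every reader and collects contract violations instead of stopping at
#' the first one.
#'
#' @param gtf,expression,samples,interactions input paths;
#'   \code{interactions} may be NULL.
#' @return character vector of problems (length 0 when everything validates).
#' @export
validateInputs <- function(gtf, expression, samples, interactions = NULL) {
    problems <- character()
    note <- function(stage, e)
        paste0("[", stage, "] ", conditionMessage(e))
    ann <- tryCatch(readGtf(gtf),
                    error = function(e) { problems <<- c(problems,
                        note("annotation", e)); NULL })
    se <- tryCatch(readExpression(expression, samples),
                   error = function(e) { problems <<- c(problems,
                       note("expression", e)); NULL })
    if (!is.null(ann) && !is.null(se) &&
        !length(intersect(names(ann), rownames(se))))
        problems <- c(problems,
            "[expression] no gene ids shared between GTF and matrix")
    if (!is.null(interactions))
        tryCatch(readInteractions(interactions),
                 error = function(e) problems <<- c(problems,
                     note("interactions", e)))
    problems
}
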