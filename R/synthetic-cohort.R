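#' @importFrom stats rnorm runif
NULL

## Deterministic annotation layout: genes sit on 50 kb slots (so unrelated
## neighbors are ~49 kb apart, always class "others"); a cis-paired lncRNA is
## placed at its configured gap from its partner mRNA. Layout depends only on
## the config counts and cis pairs, never on the RNG seed.
.SLOT <- 50000L
.MRNA_LEN <- 1000L
.LNC_LEN <- 800L

.buildAnnotation <- function(config) {
    mrna <- .mrnaIds(config@nMrna)
    lnc <- .lncIds(config@nLncrna)
    cis <- config@cisPairs
    freeLnc <- setdiff(lnc, cis$lncrna_id)
    slotted <- c(mrna, freeLnc)
    slotsPerChrom <- max(1L, as.integer(config@chromLength %/% .SLOT))
    idx <- seq_along(slotted) - 1L
    chrom <- paste0("chr", idx %/% slotsPerChrom + 1L)
    slotStart <- (idx %% slotsPerChrom) * .SLOT + 1L
    width <- ifelse(slotted %in% mrna, .MRNA_LEN, .LNC_LEN)
    gr <- GRanges(chrom, IRanges(slotStart, width = width),
                  strand = rep_len(c("+", "-"), length(slotted)),
                  gene_id = slotted,
                  biotype = ifelse(slotted %in% mrna, "coding", "lncRNA"))
    names(gr) <- slotted
    if (nrow(cis)) {
        partner <- match(cis$mrna_id, names(gr))
        ps <- start(gr)[partner]
        pe <- end(gr)[partner]
        inside <- cis$gap == 0
        # gap g in bases between closest boundaries: start = partner end + g + 1
        cstart <- ifelse(inside, ps + 100L, pe + cis$gap + 1L)
        cwidth <- ifelse(inside, 400L, .LNC_LEN)
        cgr <- GRanges(as.character(seqnames(gr))[partner],
                       IRanges(as.integer(cstart), width = as.integer(cwidth)),
                       strand = "-",
                       gene_id = cis$lncrna_id, biotype = "lncRNA")
        names(cgr) <- cis$lncrna_id
        gr <- c(gr, cgr)
    }
    gr[c(mrna, lnc)]
}

## Latent-factor loading giving expected pair correlation |r| at noise sd s:
## x = lam*f + e, y = sign(r)*lam*f + e' with f ~ N(0,1), e ~ N(0, s^2)
## => cor(x, y) = sign(r) * lam^2 / (lam^2 + s^2), so lam = s*sqrt(|r|/(1-|r|)).
.loading <- function(r, noiseSd) noiseSd * sqrt(abs(r) / (1 - abs(r)))

#' Generate a synthetic tumor/control cohort
#'
#' Builds a deterministic gene annotation (cis pairs placed at their
#' configured genomic gaps, everything else on well-separated 50 kb slots),
#' then simulates FPKM expression as
#' \code{2^(baseline + group effect + latent factors + N(0, noiseSd))}.
#' Planted differential effects are added to tumor samples only. Cis pairs
#' and trans blocks share a per-sample standard-normal latent factor with
#' loading chosen so the expected Pearson correlation of pair members equals
#' the configured target r (sign applied to the partner/member loading).
#' Identical configs (including seed) give bit-identical cohorts.
#'
#' @param config a [SimConfig-class].
#' @param trueTargets optional data.frame(lncrna_id, mrna_id) of true
#'   interaction targets for the score table; defaults to driver x members of
#'   every trans block in \code{config}.
#' @param nBackground,nPromiscuous passed to [generateInteractionTable()].
#' @param interactions logical; generate the interaction score table?
#' @return a [SyntheticCohort-class].
#' @examples
#' cfg <- simConfig(nMrna = 10L, nLncrna = 4L, seed = 11L)
#' cohort <- generateCohort(cfg, interactions = FALSE)
#' cohortExpression(cohort)
#' @export
generateCohort <- function(config, trueTargets = NULL, nBackground = 50L,
                           nPromiscuous = 1L, interactions = TRUE) {
    validObject(config)
    ann <- .buildAnnotation(config)
    nT <- config@nTumor
    nC <- config@nControl
    sampleIds <- c(paste0("T", seq_len(nT)), paste0("C", seq_len(nC)))
    group <- rep(c("tumor", "control"), c(nT, nC))
    genes <- names(ann)
    nGenes <- length(genes)
    nSamp <- nT + nC

    set.seed(config@seed)
    log2m <- config@baselineLog2Mean +
        matrix(rnorm(nGenes * nSamp, 0, config@noiseSd), nGenes, nSamp,
               dimnames = list(genes, sampleIds))
    pd <- config@plantedDe
    for (i in seq_len(nrow(pd)))
        log2m[pd$gene_id[i], seq_len(nT)] <-
            log2m[pd$gene_id[i], seq_len(nT)] + pd$log2_effect[i]
    couple <- function(a, b, r) {
        if (r == 0 || config@noiseSd == 0) {
            rnorm(nSamp)  # burn the draw so layout of the stream is stable
            return(invisible(NULL))
        }
        f <- rnorm(nSamp)
        lam <- .loading(r, config@noiseSd)
        log2m[a, ] <<- log2m[a, ] + lam * f
        for (g in b) log2m[g, ] <<- log2m[g, ] + sign(r) * lam * f
    }
    cis <- config@cisPairs
    for (i in seq_len(nrow(cis)))
        couple(cis$lncrna_id[i], cis$mrna_id[i], cis$r[i])
    for (blk in config@transBlocks)
        couple(blk$lncrna_id, blk$mrna_ids, blk$r)

    mat <- pmax(2^log2m, 0)
    se <- LncExperiment(mat, group = group,
                        biotype = mcols(ann)$biotype[match(rownames(mat),
                                                           names(ann))])
    samples <- .syntheticSampleSheet(sampleIds, group)
    if (is.null(trueTargets)) {
        trueTargets <- do.call(rbind, lapply(config@transBlocks, function(blk)
            data.frame(lncrna_id = blk$lncrna_id, mrna_id = blk$mrna_ids)))
        if (is.null(trueTargets))
            trueTargets <- data.frame(lncrna_id = character(),
                                      mrna_id = character())
    }
    inter <- if (interactions)
        generateInteractionTable(config, trueTargets,
                                 nBackground = nBackground,
                                 nPromiscuous = nPromiscuous)
    else DataFrame(lncrna_id = character(), mrna_id = character(),
                   sumenergy = numeric())
    promiscuous <- metadata(inter)$promiscuous
    new("SyntheticCohort",
        config = config, annotation = ann, expression = se,
        samples = samples, interactions = inter,
        truth = list(plantedDe = pd, cisPairs = cis,
                     transBlocks = config@transBlocks,
                     trueTargets = trueTargets,
                     promiscuous = if (is.null(promiscuous)) character()
                                   else promiscuous))
}

## Clinical-style sheet with deterministic (seed-independent) covariates so
## only the expression noise is reseeded between runs.
.syntheticSampleSheet <- function(sampleIds, group) {
    tumor <- group == "tumor"
    nT <- sum(tumor)
    nC <- sum(!tumor)
    age <- rep(NA_real_, length(group))
    age[tumor] <- rep_len(c(12, 24, 36, 48, 8, 60, 30), nT)
    age[!tumor] <- rep_len(c(144, 60, 264), nC)
    sex <- rep("unknown", length(group))
    sex[tumor] <- rep_len(c("male", "female"), nT)
    inv <- rep("not-applicable", length(group))
    inv[tumor] <- rep_len(c("invasive", "non-invasive"), nT)
    lat <- rep(NA_character_, length(group))
    lat[tumor] <- rep_len(c("OD", "OS"), nT)
    DataFrame(sample_id = sampleIds, group = group, age_months = age,
              sex = sex, invasiveness = inv, laterality = lat)
}

#' Generate an RNA-RNA interaction score table
#'
#' True targets receive SUMENERGY drawn uniformly in (2000, 4000); background
#' pairs in (0, 1500). Each promiscuous mRNA is planted with scores > 1500
#' under 5 distinct lncRNAs; because the downstream promiscuity rule counts
#' only energy-retained lncRNAs, any of those 5 hosts that is not already a
#' true-target driver is given retention credentials (10 extra targets above
#' 2000) so the exclusion rule can actually fire. Deterministic under the
#' config seed.
#'
#' @param config a [SimConfig-class].
#' @param trueTargets data.frame(lncrna_id, mrna_id).
#' @param nBackground number of random weak background pairs.
#' @param nPromiscuous number of promiscuous mRNAs to plant.
#' @return \code{DataFrame(lncrna_id, mrna_id, sumenergy)} with planted
#'   promiscuous mRNA ids in \code{metadata()$promiscuous}.
#' @export
generateInteractionTable <- function(config, trueTargets, nBackground = 50L,
                                     nPromiscuous = 0L) {
    validObject(config)
    mrna <- .mrnaIds(config@nMrna)
    lnc <- .lncIds(config@nLncrna)
    trueTargets <- as.data.frame(trueTargets)
    if (nrow(trueTargets)) {
        bad <- setdiff(c(trueTargets$lncrna_id, trueTargets$mrna_id),
                       c(mrna, lnc))
        if (length(bad))
            stop("trueTargets references unknown gene(s): ",
                 paste(bad, collapse = ", "))
    }
    availMrna <- setdiff(mrna, trueTargets$mrna_id)
    if (nPromiscuous > length(availMrna))
        stop("n_promiscuous (", nPromiscuous,
             ") exceeds available mRNAs (", length(availMrna), ")")
    if (nPromiscuous > 0L && length(lnc) < 5L)
        stop("n_promiscuous > 0 requires at least 5 lncRNAs")

    set.seed(config@seed + 104729L)
    rows <- list()
    if (nrow(trueTargets))
        rows$true <- data.frame(lncrna_id = trueTargets$lncrna_id,
                                mrna_id = trueTargets$mrna_id,
                                sumenergy = runif(nrow(trueTargets),
                                                  2000, 4000))
    if (nBackground > 0L)
        rows$background <- data.frame(
            lncrna_id = sample(lnc, nBackground, replace = TRUE),
            mrna_id = sample(mrna, nBackground, replace = TRUE),
            sumenergy = runif(nBackground, 1, 1500))
    promIds <- character()
    if (nPromiscuous > 0L) {
        promIds <- sample(availMrna, nPromiscuous)
        drivers <- unique(trueTargets$lncrna_id)
        hosts <- c(drivers, setdiff(lnc, drivers))[seq_len(5L)]
        decoys <- setdiff(hosts, drivers)
        for (d in decoys) {
            pool <- setdiff(mrna, c(promIds, trueTargets$mrna_id))
            tgt <- sample(pool, min(10L, length(pool)))
            rows[[paste0("decoy_", d)]] <- data.frame(
                lncrna_id = d, mrna_id = tgt,
                sumenergy = runif(length(tgt), 2100, 3500))
        }
        for (p in promIds)
            rows[[paste0("prom_", p)]] <- data.frame(
                lncrna_id = hosts, mrna_id = p,
                sumenergy = runif(5L, 1600, 1950))
    }
    tab <- if (length(rows)) do.call(rbind, rows)
        else data.frame(lncrna_id = character(), mrna_id = character(),
                        sumenergy = numeric())
    # io collapse rule: keep max score per pair
    key <- paste(tab$lncrna_id, tab$mrna_id, sep = "\r")
    if (nrow(tab)) {
        best <- tapply(tab$sumenergy, key, max)
        first <- !duplicated(key)
        tab <- data.frame(lncrna_id = tab$lncrna_id[first],
                          mrna_id = tab$mrna_id[first],
                          sumenergy = as.numeric(best[key[first]]))
        tab <- tab[order(tab$lncrna_id, tab$mrna_id), , drop = FALSE]
    }
    out <- DataFrame(lncrna_id = tab$lncrna_id, mrna_id = tab$mrna_id,
                     sumenergy = tab$sumenergy)
    metadata(out)$promiscuous <- sort(promIds)
    out
}

#' Write a synthetic cohort to disk as standard flat files
#'
#' Emits \code{genes.gtf}, \code{expression.tsv}, \code{samples.tsv} and
#' \code{interactions.tsv} in \code{directory}; all four round-trip losslessly
#' through [readGtf()], [readExpression()], [readSampleSheet()] and
#' [readInteractions()] (expression up to text-serialization precision).
#'
#' @param cohort a [SyntheticCohort-class].
#' @param directory output directory (created if needed).
#' @return named character vector of the 4 written paths (the manifest).
#' @export
writeFixture <- function(cohort, directory) {
    if (!dir.exists(directory) &&
        !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create fixture directory: ", directory)
    paths <- c(gtf = file.path(directory, "genes.gtf"),
               expression = file.path(directory, "expression.tsv"),
               samples = file.path(directory, "samples.tsv"),
               interactions = file.path(directory, "interactions.tsv"))
    wr <- function(expr, path)
        tryCatch(expr, error = function(e)
            stop("failed writing ", path, ": ", conditionMessage(e)))
    wr(writeGtf(cohort@annotation, paths["gtf"]), paths["gtf"])
    m <- fpkm(cohort@expression)
    expTab <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    wr(write.table(expTab, paths["expression"], sep = "\t", quote = FALSE,
                   row.names = FALSE), paths["expression"])
    s <- cohort@samples
    sheet <- data.frame(
        sample_id = s$sample_id, group = s$group,
        age = ifelse(is.na(s$age_months), "N/A",
                     paste(s$age_months, "Months")),
        sex = ifelse(s$sex == "unknown", "N/A", s$sex),
        invasiveness = ifelse(s$invasiveness == "not-applicable", "N/A",
                              s$invasiveness),
        laterality = ifelse(is.na(s$laterality), "N/A", s$laterality))
    wr(write.table(sheet, paths["samples"], sep = "\t", quote = FALSE,
                   row.names = FALSE), paths["samples"])
    it <- as.data.frame(cohort@interactions)
    wr(write.table(it, paths["interactions"], sep = "\t", quote = FALSE,
                   row.names = FALSE), paths["interactions"])
    paths
}
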