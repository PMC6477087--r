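#' @importFrom jsonlite write_json read_json
#' @importFrom tools md5sum
NULL

#' Pipeline configuration
#'
#' Bundles the input paths and every analysis threshold with its published
#' default. Thresholds must be positive and alpha must lie in (0, 1).
#'
#' @param gtf,expression,samples input paths; \code{interactions} optional
#'   (NULL skips the trans stage).
#' @param interactions optional interaction-score TSV.
#' @param outDir output directory for stage TSVs and the run report.
#' @param alpha,fcCut DE rule: raw p < alpha and |log2fc| > fcCut.
#' @param corrCut correlation retention cutoff (|r| > corrCut).
#' @param topLnc number of most-deregulated lncRNAs entering the network.
#' @param k size of the final sum-of-correlations lncRNA list.
#' @param adjoining,proximal cis distance-class boundaries in bases.
#' @param energyTarget,energySubstrate,minTargets,promiscuity SUMENERGY
#'   filter-chain thresholds.
#' @param seed integer echoed into the report (the analysis itself is
#'   deterministic).
#' @return a list of class \code{"lncscope_config"}.
#' @export
pipelineConfig <- function(gtf, expression, samples, interactions = NULL,
                           outDir = ".", alpha = 0.05, fcCut = 1,
                           corrCut = 0.3, topLnc = 400L, k = 10L,
                           adjoining = 5000, proximal = 10000,
                           energyTarget = 2000, energySubstrate = 1500,
                           minTargets = 10L, promiscuity = 4L, seed = 1L) {
    cfg <- list(gtf = gtf, expression = expression, samples = samples,
                interactions = interactions, outDir = outDir, alpha = alpha,
                fcCut = fcCut, corrCut = corrCut, topLnc = as.integer(topLnc),
                k = as.integer(k), adjoining = adjoining, proximal = proximal,
                energyTarget = energyTarget,
                energySubstrate = energySubstrate,
                minTargets = as.integer(minTargets),
                promiscuity = as.integer(promiscuity),
                seed = as.integer(seed))
    num <- c("alpha", "fcCut", "corrCut", "topLnc", "k", "adjoining",
             "proximal", "energyTarget", "energySubstrate", "minTargets",
             "promiscuity")
    for (f in num)
        if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
            stop("config threshold '", f, "' must be positive")
    if (cfg$alpha >= 1)
        stop("config threshold 'alpha' must lie in (0, 1)")
    class(cfg) <- "lncscope_config"
    cfg
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config a [pipelineConfig()] list.
#' @param path JSON file.
#' @return \code{writePipelineConfig}: the path, invisibly;
#'   \code{readPipelineConfig}: the configuration list.
#' @export
writePipelineConfig <- function(config, path) {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         null = "null", digits = NA, pretty = TRUE)
    invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    do.call(pipelineConfig, raw)
}

#' Run the full tumor-vs-control lncRNA analysis
#'
#' Orchestrates validate -> cohort summary -> differential expression ->
#' correlation network -> cis classification -> trans targets, writing one
#' TSV per stage (\code{de.tsv}, \code{edges.tsv}, \code{lnc_summary.tsv},
#' \code{cis_pairs.tsv}, \code{trans_targets.tsv}) plus \code{report.json}
#' and \code{run.log} under \code{config$outDir}. Any stage error aborts with
#' the stage name. Reruns with identical inputs and config produce identical
#' outputs: nothing downstream of the input files is randomized.
#'
#' @param config a [pipelineConfig()] list.
#' @return the run report, invisibly (also serialized to
#'   \code{report.json}): per-stage counts, config echo, package version and
#'   input checksums.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "lncscope_config"))
    if (!dir.exists(config$outDir) &&
        !dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", config$outDir)
    logPath <- file.path(config$outDir, "run.log")
    logLines <- character()
    note <- function(...) {
        line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
        logLines <<- c(logLines, line)
        message(line)
    }
    stage <- function(name, expr)
        tryCatch(expr, error = function(e) {
            logLines <<- c(logLines, paste0("ERROR in ", name, " stage: ",
                                            conditionMessage(e)))
            writeLines(logLines, logPath)
            stop(name, " stage failed: ", conditionMessage(e), call. = FALSE)
        })
    tsv <- function(x, name) {
        write.table(as.data.frame(x), file.path(config$outDir, name),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        name
    }

    note("annotation stage: reading ", config$gtf)
    ann <- stage("annotation", readGtf(config$gtf))
    note("expression stage: reading ", config$expression)
    se <- stage("expression", readExpression(config$expression,
                                             config$samples))
    sheet <- stage("samples", readSampleSheet(config$samples))
    shared <- intersect(names(ann), rownames(se))
    if (!length(shared))
        stop("expression stage failed: no gene ids shared with annotation")

    note("cohort stage: summarizing ", nrow(sheet), " samples")
    cohortSummary <- stage("cohort", summarizeCohort(sheet))

    note("de stage: testing ", length(shared), " genes")
    de <- stage("de", callDE(se, ann, alpha = config$alpha,
                             fcCut = config$fcCut))
    tsv(de, "de.tsv")

    topLnc <- suppressMessages(topDeregulated(de, "lncRNA", config$topLnc))
    sigMrna <- de$gene_id[de$significant & de$biotype == "coding"]
    edges <- NULL
    summaries <- NULL
    top10 <- character()
    if (length(topLnc) && length(sigMrna)) {
        note("corr stage: ", length(topLnc), " lncRNAs x ", length(sigMrna),
             " mRNAs")
        edges <- stage("corr", buildEdges(se, topLnc, sigMrna,
                                          cut = config$corrCut))
        summaries <- summarizeLnc(edges)
        top10 <- selectTopLnc(summaries, config$k)
        tsv(edges, "edges.tsv")
        tsv(summaries, "lnc_summary.tsv")
    } else {
        note("corr stage skipped: no significant lncRNAs or mRNAs")
    }

    note("cis stage: pairing deregulated lncRNAs with coding neighbors")
    cis <- stage("cis", pairWithDeNeighbors(de, ann,
                                            adjoining = config$adjoining,
                                            proximal = config$proximal))
    tsv(cis, "cis_pairs.tsv")

    trans <- NULL
    if (!is.null(config$interactions)) {
        note("trans stage: filtering ", config$interactions)
        trans <- stage("trans", {
            scores <- readInteractions(config$interactions)
            filt <- transTargetFilter(scores,
                                      energyCut = config$energyTarget,
                                      minTargets = config$minTargets,
                                      substrateCut = config$energySubstrate,
                                      maxLnc = config$promiscuity)
            up <- stratifyTargets(filt$scores, de, "up",
                                  alpha = config$alpha, fcCut = config$fcCut)
            down <- stratifyTargets(filt$scores, de, "down",
                                    alpha = config$alpha,
                                    fcCut = config$fcCut)
            list(retained = filt$retained, dropped = filt$dropped,
                 up = up, down = down)
        })
        both <- rbind(cbind(lnc_direction = "up",
                            as.data.frame(trans$up$targets)),
                      cbind(lnc_direction = "down",
                            as.data.frame(trans$down$targets)))
        tsv(both, "trans_targets.tsv")
    } else {
        note("trans stage skipped: no interaction table supplied")
    }

    inputs <- c(gtf = config$gtf, expression = config$expression,
                samples = config$samples)
    if (!is.null(config$interactions))
        inputs <- c(inputs, interactions = config$interactions)
    report <- list(
        package = "lncscope",
        version = as.character(utils::packageVersion("lncscope")),
        config = unclass(config),
        input_md5 = as.list(tools::md5sum(inputs)),
        cohort = as.list(as.data.frame(cohortSummary)),
        stages = list(
            de = list(
                n_tested = nrow(de),
                n_up_coding = sum(de$direction == "up" &
                                  de$biotype == "coding"),
                n_down_coding = sum(de$direction == "down" &
                                    de$biotype == "coding"),
                n_up_lncrna = sum(de$direction == "up" &
                                  de$biotype == "lncRNA"),
                n_down_lncrna = sum(de$direction == "down" &
                                    de$biotype == "lncRNA")),
            corr = list(
                run = !is.null(edges),
                n_edges = if (is.null(edges)) 0L else nrow(edges),
                n_retained = if (is.null(edges)) 0L
                             else sum(edges$retained),
                top_lnc = as.list(top10)),
            cis = list(
                n_pairs = nrow(cis),
                n_unpaired = length(metadata(cis)$unpaired),
                by_class = as.list(table(cis$distance_class))),
            trans = if (is.null(trans)) list(run = FALSE) else list(
                run = TRUE,
                n_retained_lnc = length(trans$retained),
                n_promiscuous_dropped = length(trans$dropped),
                up = as.list(stats::setNames(trans$up$summary$n_genes,
                                             trans$up$summary$quadrant)),
                down = as.list(stats::setNames(trans$down$summary$n_genes,
                                               trans$down$summary$quadrant)))))
    jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    note("done")
    writeLines(logLines, logPath)
    invisible(report)
}

#' Default demonstration cohort configuration
#'
#' The stated world of the synthetic demo: 7 tumors vs 3 controls, 60 mRNAs +
#' 30 lncRNAs, log2 noise SD 0.5. Planted structure exercises every stage:
#' cis pairs in all four distance classes with both concordant and
#' anti-correlated direction patterns, a trans block of 12 upregulated true
#' targets under one upregulated driver lncRNA, extra up/down effects of both
#' biotypes, and (via the interaction table) one energy-retained driver plus
#' one promiscuous mRNA.
#'
#' @param seed integer RNG seed.
#' @return a [SimConfig-class].
#' @export
demoSimConfig <- function(seed = 7L) {
    transMembers <- sprintf("MRNA%04d", 10:21)
    simConfig(
        nTumor = 7L, nControl = 3L, nMrna = 60L, nLncrna = 30L,
        plantedDe = data.frame(
            gene_id = c("LNC0001", "MRNA0001",   # overlap, both down
                        "LNC0002", "MRNA0002",   # adjoining, lnc down mRNA up
                        "LNC0003", "MRNA0003",   # proximal, both up
                        "LNC0004", "MRNA0004",   # others (>10 kb)
                        "LNC0005",               # trans driver, up
                        transMembers,            # its 12 targets, up
                        "LNC0006", "LNC0007", "MRNA0030", "MRNA0031"),
            # coupled genes carry latent-factor variance on top of the noise,
            # so they get the larger +-3 effects to stay safely detectable
            log2_effect = c(-3, -3,
                            -3, 3,
                            3, 3,
                            3, 3,
                            4,
                            rep(3, length(transMembers)),
                            2.5, -2.5, 3, -3)),
        cisPairs = data.frame(
            lncrna_id = c("LNC0001", "LNC0002", "LNC0003", "LNC0004"),
            mrna_id = c("MRNA0001", "MRNA0002", "MRNA0003", "MRNA0004"),
            gap = c(0, 2000, 8000, 20000),
            # moderate coupling: strong |r| loads latent variance ~ sd 1 on
            # top of the 0.5 noise, which at 3 controls can mask the planted
            # effects the demo exists to display
            r = c(0.6, -0.6, 0.6, 0.5)),
        transBlocks = list(list(lncrna_id = "LNC0005",
                                mrna_ids = transMembers, r = 0.5)),
        noiseSd = 0.5, baselineLog2Mean = 5, seed = seed)
}

#' Write a ready-to-run demonstration fixture
#'
#' Generates the [demoSimConfig()] cohort, writes its four flat files plus a
#' matching \code{config.json} under \code{directory}. Two demos with the
#' same seed are identical; changing the seed reseeds only the noise (the
#' annotation layout and sample sheet are deterministic).
#'
#' @param seed integer RNG seed.
#' @param directory output directory.
#' @return named character vector: the four fixture paths plus
#'   \code{config}.
#' @export
makeDemo <- function(seed = 7L, directory) {
    cohort <- generateCohort(demoSimConfig(seed))
    paths <- writeFixture(cohort, directory)
    cfgPath <- file.path(directory, "config.json")
    cfg <- pipelineConfig(gtf = paths[["gtf"]],
                          expression = paths[["expression"]],
                          samples = paths[["samples"]],
                          interactions = paths[["interactions"]],
                          outDir = file.path(directory, "results"),
                          seed = seed)
    writePipelineConfig(cfg, cfgPath)
    c(paths, config = cfgPath)
}
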