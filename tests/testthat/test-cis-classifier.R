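test_that("interval gaps follow the closest-boundary definition", {
    # spec's half-open (1000,2000)/(1500,3000) = 1-based 1001-2000/1501-3000
    a <- gr1("chr1", 1001, 2000, "A")
    b <- gr1("chr1", 1501, 3000, "B")
    expect_equal(intervalGap(a, b), 0)
    # half-open (1000,2000)/(7000,8000): gap 5000, the adjoining boundary
    d <- gr1("chr1", 7001, 8000, "D")
    expect_equal(intervalGap(a, d), 5000)
    # different chromosomes: infinite
    e <- gr1("chr2", 1001, 2000, "E")
    expect_identical(intervalGap(a, e), Inf)
    # symmetry
    expect_equal(intervalGap(d, a), intervalGap(a, d))
    expect_equal(intervalGap(b, a), intervalGap(a, b))
})

test_that("distance classes partition at the stated boundaries", {
    # lnc at 1-based 1001..2000; neighbors placed at controlled gaps
    lnc <- gr1("chr1", 1001, 2000, "LNC", "lncRNA")
    neighborAt <- function(gap, id)
        gr1("chr1", 2000 + gap + 1, 2000 + gap + 500, id)
    cases <- list(
        list(ann = c(lnc, gr1("chr1", 1500, 2500, "N")), class = "overlap",
             gap = 0),
        list(ann = c(lnc, neighborAt(1, "N")), class = "adjoining", gap = 1),
        list(ann = c(lnc, neighborAt(5000, "N")), class = "adjoining",
             gap = 5000),
        list(ann = c(lnc, neighborAt(5001, "N")), class = "proximal",
             gap = 5001),
        list(ann = c(lnc, neighborAt(10000, "N")), class = "proximal",
             gap = 10000),
        list(ann = c(lnc, neighborAt(10001, "N")), class = "others",
             gap = 10001))
    for (cs in cases) {
        got <- classifyLnc("LNC", cs$ann)
        expect_equal(got$distance_class, cs$class)
        expect_equal(got$gap_bp, cs$gap)
        expect_equal(got$neighbor_id, "N")
    }
    # no same-chromosome gene at all
    lone <- suppressWarnings(c(lnc, gr1("chr9", 1, 500, "FAR")))
    got <- classifyLnc("LNC", lone)
    expect_equal(got$distance_class, "others")
    expect_true(is.na(got$neighbor_id))
})

test_that("nearest-neighbor ties prefer intersection then gene id", {
    lnc <- gr1("chr1", 1001, 2000, "LNC", "lncRNA")
    # two genes both at gap 10: smaller id wins
    ann <- c(lnc, gr1("chr1", 2011, 2400, "ZGENE"),
             gr1("chr1", 2011, 2500, "AGENE"))
    expect_equal(classifyLnc("LNC", ann)$neighbor_id, "AGENE")
    # gap 0 by touching vs gap 0 by intersection: intersecting wins
    ann2 <- c(lnc, gr1("chr1", 2001, 2400, "TOUCH"),
              gr1("chr1", 1900, 2300, "INSIDE"))
    got <- classifyLnc("LNC", ann2)
    expect_equal(got$neighbor_id, "INSIDE")
    expect_equal(got$distance_class, "overlap")
})

test_that("classification equals a brute-force scan over a 200-gene chromosome", {
    set.seed(77)
    n <- 200
    starts <- sort(sample.int(2e6, n))
    widths <- sample(200:3000, n, replace = TRUE)
    ids <- sprintf("G%03d", seq_len(n))
    ann <- GRanges("chr1", IRanges(starts, width = widths),
                   gene_id = ids,
                   biotype = sample(c("coding", "lncRNA"), n, replace = TRUE))
    names(ann) <- ids
    st <- start(ann); en <- end(ann)
    bruteGap <- function(i, j) {
        if (st[i] <= en[j] && st[j] <= en[i]) return(0)
        if (en[i] < st[j]) st[j] - en[i] - 1 else st[i] - en[j] - 1
    }
    for (i in sample(n, 25)) {
        gaps <- vapply(setdiff(seq_len(n), i), bruteGap, numeric(1), i = i)
        got <- classifyLnc(ids[i], ann)
        expect_equal(got$gap_bp, min(gaps))
        cls <- if (min(gaps) == 0 &&
                   any(gaps == 0 & vapply(setdiff(seq_len(n), i), function(j)
                       st[i] <= en[j] && st[j] <= en[i], logical(1))))
            "overlap"
        else if (min(gaps) <= 5000) "adjoining"
        else if (min(gaps) <= 10000) "proximal"
        else "others"
        expect_equal(got$distance_class, cls)
    }
})

test_that("deregulated lncRNAs pair with deregulated coding neighbors", {
    # the published overlap pattern: lnc down, overlapped coding gene down
    ann <- c(gr1("chr1", 5000, 7000, "GNB5like", "coding"),
             gr1("chr1", 5500, 6200, "CERNA1like", "lncRNA"),
             # adjoining anti-correlated pattern: lnc down, neighbor up
             gr1("chr1", 100000, 102000, "NUP50like", "coding"),
             gr1("chr1", 103001, 103800, "NUP50ASlike", "lncRNA"),
             # a non-significant coding gene nearby must not pair
             gr1("chr1", 104500, 105000, "QUIET", "coding"))
    de <- makeDE(
        gene_id = c("GNB5like", "CERNA1like", "NUP50like", "NUP50ASlike",
                    "QUIET"),
        biotype = c("coding", "lncRNA", "coding", "lncRNA", "coding"),
        log2fc = c(-2.5, -3, 2.2, -2.8, 0.1),
        p_value = c(0.01, 0.001, 0.02, 0.004, 0.9))
    pairs <- pairWithDeNeighbors(de, ann)
    expect_equal(nrow(pairs), 2L)
    ov <- pairs[pairs$lncrna_id == "CERNA1like", ]
    expect_equal(ov$distance_class, "overlap")
    expect_equal(ov$concordance, "concordant")
    adj <- pairs[pairs$lncrna_id == "NUP50ASlike", ]
    expect_equal(adj$distance_class, "adjoining")
    expect_equal(adj$gap_bp, 1000)
    expect_equal(adj$concordance, "anti-correlated")
    expect_true(all(pairs$primary))
})

test_that("planted cis pairs classify per brute force and >10 kb is excluded", {
    gaps <- c(0, 100, 4999, 5001, 9999, 10050)
    lncs <- sprintf("LNC%04d", 1:6)
    mrnas <- sprintf("MRNA%04d", 1:6)
    cfg <- simConfig(
        nMrna = 8L, nLncrna = 6L, noiseSd = 0, seed = 13L,
        plantedDe = data.frame(gene_id = c(lncs, mrnas),
                               log2_effect = rep(c(-2, 2), each = 6)),
        cisPairs = data.frame(lncrna_id = lncs, mrna_id = mrnas,
                              gap = gaps, r = 0.5))
    cohort <- generateCohort(cfg, interactions = FALSE)
    de <- callDE(cohortExpression(cohort))
    pairs <- pairWithDeNeighbors(de, cohortAnnotation(cohort))
    got <- setNames(pairs$distance_class, pairs$lncrna_id)
    expect_equal(unname(got[lncs[1:5]]),
                 c("overlap", "adjoining", "adjoining", "proximal",
                   "proximal"))
    # the 10050-gap pair falls outside the reported classes
    expect_false("LNC0006" %in% pairs$lncrna_id)
    expect_true("LNC0006" %in% S4Vectors::metadata(pairs)$unpaired)
    expect_equal(unname(got[lncs[1]]), "overlap")
    expect_true(all(pairs$concordance == "anti-correlated"))
})
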