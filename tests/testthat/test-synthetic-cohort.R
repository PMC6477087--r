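test_that("identical configs give bit-identical cohorts", {
    cfg <- simConfig(nMrna = 10L, nLncrna = 5L, seed = 3L,
                     plantedDe = data.frame(gene_id = "MRNA0001",
                                            log2_effect = 2),
                     cisPairs = data.frame(lncrna_id = "LNC0001",
                                           mrna_id = "MRNA0002",
                                           gap = 100, r = 0.5))
    a <- generateCohort(cfg, nPromiscuous = 1L)
    b <- generateCohort(cfg, nPromiscuous = 1L)
    expect_identical(fpkm(cohortExpression(a)), fpkm(cohortExpression(b)))
    expect_identical(as.data.frame(cohortInteractions(a)),
                     as.data.frame(cohortInteractions(b)))
    # different seed: expression differs, annotation layout identical
    cfg2 <- simConfig(nMrna = 10L, nLncrna = 5L, seed = 4L,
                      plantedDe = cfg@plantedDe, cisPairs = cfg@cisPairs)
    c2 <- generateCohort(cfg2, nPromiscuous = 1L)
    expect_false(identical(fpkm(cohortExpression(a)),
                           fpkm(cohortExpression(c2))))
    expect_identical(as.data.frame(cohortAnnotation(a)),
                     as.data.frame(cohortAnnotation(c2)))
})

test_that("zero noise with no planted effects gives constant genes", {
    cfg <- simConfig(nMrna = 4L, nLncrna = 2L, noiseSd = 0, seed = 1L)
    cohort <- generateCohort(cfg, interactions = FALSE)
    m <- fpkm(cohortExpression(cohort))
    expect_true(all(m == m[, 1]))
    # correlations undefined, reported as such
    expect_message(r <- pearsonR(m[1, ], m[2, ]), "zero-variance")
    expect_true(is.na(r))
})

test_that("cohort dimensions, non-negativity and truth match the config", {
    cfg <- simConfig(nTumor = 5L, nControl = 4L, nMrna = 12L, nLncrna = 6L,
                     seed = 9L,
                     plantedDe = data.frame(gene_id = "LNC0002",
                                            log2_effect = -1.5))
    cohort <- generateCohort(cfg, interactions = FALSE)
    se <- cohortExpression(cohort)
    expect_equal(ncol(se), 9L)
    expect_equal(nrow(se), 18L)
    expect_true(all(fpkm(se) >= 0))
    expect_equal(cohortTruth(cohort)$plantedDe, cfg@plantedDe)
    expect_equal(sum(sampleGroup(se) == "tumor"), 5L)
})

test_that("a planted cis pair reaches its target correlation at n = 50", {
    cfg <- simConfig(nTumor = 25L, nControl = 25L, nMrna = 5L, nLncrna = 2L,
                     seed = 17L,
                     cisPairs = data.frame(lncrna_id = "LNC0001",
                                           mrna_id = "MRNA0001",
                                           gap = 1000, r = 0.9))
    cohort <- generateCohort(cfg, interactions = FALSE)
    L <- log2Fpkm(cohortExpression(cohort))
    # oracle: direct correlation of the emitted matrix
    r <- cor(L["LNC0001", ], L["MRNA0001", ])
    expect_lt(abs(r - 0.9), 0.1)
})

test_that("configs violating invariants are rejected by field name", {
    expect_error(simConfig(nTumor = 1L), "n_tumor")
    expect_error(simConfig(nControl = 1L), "n_control")
    expect_error(
        simConfig(cisPairs = data.frame(lncrna_id = "LNC0001",
                                        mrna_id = "MRNA0001",
                                        gap = -5, r = 0.5)),
        "gap")
    expect_error(
        simConfig(cisPairs = data.frame(lncrna_id = "LNC0001",
                                        mrna_id = "MRNA0001",
                                        gap = 10, r = 1)),
        "cis_pairs")
    expect_error(
        simConfig(plantedDe = data.frame(gene_id = "NOPE",
                                         log2_effect = 1)),
        "planted_de")
})

test_that("interaction tables plant truth, background and promiscuity", {
    cfg <- simConfig(nMrna = 40L, nLncrna = 8L, seed = 5L)
    truth <- data.frame(lncrna_id = "LNC0001",
                        mrna_id = sprintf("MRNA%04d", 1:12))
    # truth only: the driver passes retention downstream
    tab <- generateInteractionTable(cfg, truth, nBackground = 0L,
                                    nPromiscuous = 0L)
    expect_equal(nrow(tab), 12L)
    expect_true(all(tab$sumenergy > 2000 & tab$sumenergy <= 4000))
    expect_equal(retainLncrnas(tab), "LNC0001")

    # background scores are weak
    tab2 <- generateInteractionTable(cfg, truth[0, ], nBackground = 30L,
                                     nPromiscuous = 0L)
    expect_true(all(tab2$sumenergy <= 1500))

    # a planted promiscuous mRNA sits under 5 retained lncRNAs and is
    # flagged by the downstream exclusion rule
    tab3 <- generateInteractionTable(cfg, truth, nBackground = 20L,
                                     nPromiscuous = 1L)
    prom <- metadata(tab3)$promiscuous
    expect_length(prom, 1L)
    hosts <- unique(tab3$lncrna_id[tab3$mrna_id == prom &
                                   tab3$sumenergy > 1500])
    expect_gte(length(hosts), 5L)
    filt <- transTargetFilter(tab3)
    expect_true(prom %in% filt$dropped)

    # empty truth and zero background: empty table
    tab4 <- generateInteractionTable(cfg, truth[0, ], nBackground = 0L,
                                     nPromiscuous = 0L)
    expect_equal(nrow(tab4), 0L)

    expect_error(generateInteractionTable(cfg, truth, nPromiscuous = 100L),
                 "n_promiscuous")
})

test_that("fixtures round-trip through the io readers", {
    cfg <- simConfig(nMrna = 8L, nLncrna = 4L, seed = 21L,
                     cisPairs = data.frame(lncrna_id = "LNC0001",
                                           mrna_id = "MRNA0001",
                                           gap = 0, r = 0.5))
    cohort <- generateCohort(cfg, nBackground = 10L, nPromiscuous = 0L)
    dir <- tempfile("fixture")
    manifest <- writeFixture(cohort, dir)
    expect_length(manifest, 4L)
    expect_true(all(file.exists(manifest)))

    ann <- readGtf(manifest[["gtf"]])
    orig <- cohortAnnotation(cohort)
    ann <- ann[names(orig)]
    expect_equal(start(ann), start(orig))
    expect_equal(end(ann), end(orig))
    expect_equal(as.character(seqnames(ann)), as.character(seqnames(orig)))
    expect_equal(mcols(ann)$biotype, mcols(orig)$biotype)

    se <- readExpression(manifest[["expression"]], manifest[["samples"]])
    expect_equal(fpkm(se), fpkm(cohortExpression(cohort)),
                 tolerance = 1e-12)
    expect_equal(unname(sampleGroup(se)),
                 unname(sampleGroup(cohortExpression(cohort))))

    it <- readInteractions(manifest[["interactions"]])
    orig_it <- cohortInteractions(cohort)
    key <- order(it$lncrna_id, it$mrna_id)
    okey <- order(orig_it$lncrna_id, orig_it$mrna_id)
    expect_equal(it$sumenergy[key], orig_it$sumenergy[okey],
                 tolerance = 1e-9)
})

test_that("planted correlations are calibrated across replicates", {
    # mean sample r within +-0.05 of target at n = 20, r in {0.3, 0.6, 0.9}
    targets <- c(0.3, 0.6, 0.9)
    pairs <- data.frame(
        lncrna_id = c("LNC0001", "LNC0002", "LNC0003"),
        mrna_id = c("MRNA0001", "MRNA0002", "MRNA0003"),
        gap = 1000, r = targets)
    nrep <- 200L
    rsum <- matrix(0, nrep, 3)
    for (i in seq_len(nrep)) {
        cfg <- simConfig(nTumor = 10L, nControl = 10L, nMrna = 4L,
                         nLncrna = 3L, cisPairs = pairs, seed = 1000L + i)
        L <- log2Fpkm(cohortExpression(generateCohort(cfg,
                                                      interactions = FALSE)))
        rsum[i, ] <- vapply(seq_len(3), function(j)
            cor(L[pairs$lncrna_id[j], ], L[pairs$mrna_id[j], ]), numeric(1))
    }
    expect_true(all(abs(colMeans(rsum) - targets) < 0.05))
})

test_that("planted log2 effects are calibrated at 7 vs 3", {
    # mean observed log2FC within +-0.2 of the planted effect at noise 0.5
    eff <- 2
    nrep <- 60L
    obs <- numeric(nrep)
    for (i in seq_len(nrep)) {
        cfg <- simConfig(nMrna = 4L, nLncrna = 2L, seed = 2000L + i,
                         plantedDe = data.frame(gene_id = "MRNA0001",
                                                log2_effect = eff))
        se <- cohortExpression(generateCohort(cfg, interactions = FALSE))
        obs[i] <- log2FC(se, "MRNA0001")
    }
    expect_lt(abs(mean(obs) - eff), 0.2)
})
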