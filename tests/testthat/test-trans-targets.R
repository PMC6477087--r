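test_that("lncRNA retention uses strict >2000 and inclusive >=10 targets", {
    # 10 targets at 2001: retained
    t1 <- scoreTab(rep("L1", 10), paste0("M", 1:10), rep(2001, 10))
    expect_equal(retainLncrnas(t1), "L1")
    # 9 strong targets plus 50 weak ones: excluded
    t2 <- scoreTab(rep("L2", 59), paste0("M", 1:59),
                   c(rep(3000, 9), rep(1900, 50)))
    expect_equal(retainLncrnas(t2), character())
    # 10 targets at exactly 2000: excluded (strict "above")
    t3 <- scoreTab(rep("L3", 10), paste0("M", 1:10), rep(2000, 10))
    expect_equal(retainLncrnas(t3), character())
})

test_that("substrate filtering is strict at 1500 and retention-scoped", {
    tab <- scoreTab(c("L1", "L1", "L2"), c("M1", "M2", "M3"),
                    c(1500, 1501, 3000))
    kept <- filterSubstrates(tab, retained = "L1")
    expect_equal(kept$mrna_id, "M2")   # 1500 dropped, non-retained L2 dropped
})

test_that("promiscuity drops mRNAs under more than 4 lncRNAs", {
    four <- scoreTab(paste0("L", 1:4), rep("M1", 4), rep(2000, 4))
    out4 <- dropPromiscuous(four)
    expect_equal(nrow(out4$scores), 4L)
    expect_length(out4$dropped, 0L)
    five <- scoreTab(paste0("L", 1:5), rep("M1", 5), rep(2000, 5))
    out5 <- dropPromiscuous(five)
    expect_equal(nrow(out5$scores), 0L)
    expect_equal(out5$dropped, "M1")
    empty <- five[0, ]
    expect_equal(nrow(dropPromiscuous(empty)$scores), 0L)
})

test_that("the filter chain matches brute force on a 30-row table", {
    set.seed(19)
    tab <- scoreTab(
        lnc = c(rep("L1", 12), rep("L2", 8), rep("L3", 5), paste0("L", 4:8)),
        mrna = c(paste0("M", 1:12), paste0("M", 13:20), paste0("M", 1:5),
                 rep("MX", 5)),
        energy = c(runif(12, 2050, 3900),          # L1: retained
                   runif(8, 2100, 3000),           # L2: only 8 strong
                   runif(5, 100, 1400),            # L3: weak
                   runif(5, 1600, 1900)))          # MX under L4..L8
    filt <- transTargetFilter(tab)
    # brute force, written out rule by rule
    strong <- tapply(tab$sumenergy > 2000, tab$lncrna_id, sum)
    retained <- sort(names(strong)[strong >= 10])
    rows <- tab[tab$lncrna_id %in% retained & tab$sumenergy > 1500, ]
    cnt <- table(rows$mrna_id)
    dropped <- sort(names(cnt)[cnt > 4])
    rows <- rows[!rows$mrna_id %in% dropped, ]
    expect_equal(filt$retained, retained)
    expect_equal(filt$dropped, dropped)
    expect_equal(as.data.frame(filt$scores), as.data.frame(rows),
                 ignore_attr = TRUE)
    # here: only L1 survives, MX untouched by promiscuity (hosts not retained)
    expect_equal(filt$retained, "L1")
})

test_that("reordering promiscuity before the substrate filter changes results", {
    # MX sits under 5 retained lncRNAs but only one row is > 1500:
    # stated order keeps MX; promiscuity-first wrongly discards it
    strong <- do.call(rbind, lapply(paste0("L", 1:5), function(l)
        scoreTab(rep(l, 10), paste0(l, "_M", 1:10), rep(2500, 10))))
    mx <- scoreTab(paste0("L", 1:5), rep("MX", 5),
                   c(1600, 1200, 1100, 1000, 900))
    tab <- rbind(strong, mx)
    stated <- transTargetFilter(tab)
    expect_false("MX" %in% stated$dropped)
    expect_true("MX" %in% stated$scores$mrna_id)
    # counterexample order
    retained <- retainLncrnas(tab)
    promFirst <- dropPromiscuous(tab[tab$lncrna_id %in% retained, ])
    expect_true("MX" %in% promFirst$dropped)
})

test_that("substrate and promiscuity thresholds act monotonically", {
    set.seed(23)
    tab <- scoreTab(sample(paste0("L", 1:6), 120, replace = TRUE),
                    sample(paste0("M", 1:25), 120, replace = TRUE),
                    runif(120, 500, 4000))
    retained <- retainLncrnas(tab, energyCut = 1000, minTargets = 5L)
    sizes <- vapply(c(1000, 1500, 2000, 3000), function(cut)
        nrow(filterSubstrates(tab, retained, substrateCut = cut)),
        numeric(1))
    expect_true(all(diff(sizes) <= 0))
    filtered <- filterSubstrates(tab, retained, 1000)
    kept <- vapply(1:6, function(mx)
        nrow(dropPromiscuous(filtered, maxLnc = mx)$scores), numeric(1))
    expect_true(all(diff(kept) >= 0))
})

test_that("targets stratify into the five volcano quadrants", {
    de <- makeDE(
        gene_id = c("LUP", "LDOWN", "M1", "M2", "M3", "M4", "M5"),
        biotype = c("lncRNA", "lncRNA", rep("coding", 5)),
        log2fc = c(3, -3, 1.5, -1.1, 0.2, 2.0, -4),
        p_value = c(0.001, 0.001, 0.01, 0.2, 0.5, 0.3, 0.001))
    tab <- scoreTab(c(rep("LUP", 5), "LDOWN"),
                    c(paste0("M", 1:5), "M1"), rep(2500, 6))
    up <- stratifyTargets(tab, de, "up")
    got <- setNames(up$targets$quadrant, up$targets$mrna_id)
    expect_equal(unname(got[paste0("M", 1:5)]),
                 c("sig_up", "ns_down", "unchanged", "ns_up", "sig_down"))
    # quadrants partition: every target in exactly one
    expect_equal(sum(up$summary$n_genes), 5L)
    # direction filter: LDOWN's target appears only under "down"
    down <- stratifyTargets(tab, de, "down")
    expect_equal(down$targets$mrna_id, "M1")
    expect_equal(down$targets$quadrant, "sig_up")
    # a target missing from DE is unchanged and logged
    tab2 <- scoreTab("LUP", "UNSEEN", 2600)
    expect_message(res2 <- stratifyTargets(tab2, de, "up"), "missing")
    expect_equal(res2$targets$quadrant, "unchanged")
    expect_error(stratifyTargets(tab, de, "sideways"))
})

test_that("12 planted true targets come through the full chain as sig_up", {
    members <- sprintf("MRNA%04d", 1:12)
    cfg <- simConfig(
        nMrna = 20L, nLncrna = 6L, noiseSd = 0, seed = 29L,
        plantedDe = data.frame(gene_id = c("LNC0001", members),
                               log2_effect = rep(2, 13)),
        transBlocks = list(list(lncrna_id = "LNC0001", mrna_ids = members,
                                r = 0.5)))
    cohort <- generateCohort(cfg, nBackground = 0L, nPromiscuous = 0L)
    de <- callDE(cohortExpression(cohort))
    filt <- transTargetFilter(cohortInteractions(cohort))
    expect_equal(filt$retained, "LNC0001")
    res <- stratifyTargets(filt$scores, de, "up")
    expect_equal(sum(res$targets$quadrant == "sig_up"), 12L)
    expect_setequal(res$targets$mrna_id, members)
})
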