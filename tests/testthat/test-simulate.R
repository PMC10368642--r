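test_that("simulation is deterministic under a seed, distinct across seeds", {
    cfg <- simulationConfig(nGenes = 150)
    a <- simulateCorpus(cfg, seed = 4)
    b <- simulateCorpus(cfg, seed = 4)
    expect_equal(corpusRecords(a$corpus), corpusRecords(b$corpus))
    expect_equal(a$truth, b$truth)
    c <- simulateCorpus(cfg, seed = 5)
    expect_false(identical(corpusRecords(a$corpus),
                           corpusRecords(c$corpus)))
})

test_that("config validation rejects malformed inputs", {
    expect_error(simulationConfig(flipRate = 1.2), "\\[0, 1\\]")
    expect_error(simulationConfig(backgroundRate = -0.1), "\\[0, 1\\]")
    expect_error(simulationConfig(phaseProps = c(phase1 = 0.6,
                                                 phase2 = 0.3,
                                                 phase3 = 0.3)), "sum")
    d <- defaultStudyDesign(); d$power <- 0
    expect_error(simulationConfig(design = d), "power")
})

test_that("the noise-free limit reports every eligible gene everywhere", {
    sim <- simulateCorpus(noiseFreeConfig(150), seed = 2)
    rec <- corpusRecords(sim$corpus, withMeta = TRUE, depOnly = TRUE)
    # every record passes its scheme by construction
    expect_equal(nrow(rec), nrow(corpusRecords(sim$corpus)))
    # no null gene appears at background rate zero
    nullGenes <- sim$truth$gene_id[sim$truth$true_direction == 0]
    expect_false(any(rec$gene_id[rec$sample_type == "bulk"] %in% nullGenes))
    # a phase-3 gene appears in every advanced non-resistant comparison
    p3 <- sim$truth$gene_id[sim$truth$true_phase == "phase3"][1]
    meta <- comparisonMeta(sim$corpus)
    eligible <- meta$comparison_id[meta$sample_type == "bulk" &
                                   meta$clinical_stage == "advanced" &
                                   meta$region_class != "resistant"]
    expect_setequal(rec$comparison_id[rec$gene_id == p3 &
                                      rec$sample_type == "bulk"], eligible)
    # and never in early or resistant comparisons
    expect_false(any(rec$clinical_stage[rec$gene_id == p3] %in%
                     c("preclinical", "MCI")))
})

test_that("zero flip and background noise yields no inconsistent class", {
    sim <- simulateCorpus(simulationConfig(nGenes = 300, flipRate = 0,
                                           backgroundRate = 0), seed = 8)
    sc <- computeScores(sim$corpus)
    expect_false(any(sc$bulk_class == "inconsistent"))
})

test_that("planted lesion truth is recovered exactly without noise", {
    sim <- simulateCorpus(noiseFreeConfig(200), seed = 6)
    ls <- lesionStatus(sim$corpus)
    for (lt in c("plaque", "NFT", "CAA")) {
        planted <- sim$truth$gene_id[
            sim$truth[[paste0(lt, "_truth")]] == "enriched"]
        called <- ls$gene_id[ls[[paste0(lt, "_status")]] == "enriched"]
        expect_setequal(called, planted)
    }
})

test_that("inconsistency grows and sign accuracy degrades with flip rate", {
    res <- vapply(c(0, 0.2, 0.45), function(fr) {
        sim <- simulateCorpus(simulationConfig(nGenes = 250,
                                               flipRate = fr), seed = 30)
        out <- analyseCorpus(sim$corpus)
        m <- recoveryMetrics(out$scores, out$phases, sim$truth)
        c(m$direction_accuracy, m$inconsistent_fraction)
    }, numeric(2L))
    expect_true(all(diff(res[1, ]) <= 1e-9))   # accuracy non-increasing
    expect_true(all(diff(res[2, ]) >= -1e-9))  # inconsistency non-decreasing
})

test_that("fixture directories round-trip through the pipeline", {
    dir <- file.path(tempdir(), "simfix")
    unlink(dir, recursive = TRUE)
    sim <- simulateCorpus(simulationConfig(nGenes = 120), seed = 13)
    cfgPath <- writeSimulatedCorpus(sim, dir)
    res <- runPipeline(cfgPath)
    expect_equal(unname(res$report["n_records"]),
                 nrow(corpusRecords(sim$corpus)))
    expect_equal(computeScores(res$corpus), computeScores(sim$corpus))
    truthBack <- read.delim(file.path(dir, "truth.tsv"))
    expect_equal(truthBack$gene_id, sim$truth$gene_id)
})
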