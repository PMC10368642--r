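test_that("region scores sum over vulnerability classes, excluding ventricle", {
    meta <- rbind(mkMeta(3L, region = "frontal cortex"),
                  mkMeta(2L, id = c("H1", "H2"), pub = c("PH1", "PH2"),
                         region = "hippocampus"),
                  mkMeta(2L, id = c("B1", "B2"), pub = c("PB1", "PB2"),
                         region = "cerebellum"),
                  mkMeta(1L, id = "V1", pub = "PV1",
                         region = "ventricle wall"),
                  mkMeta(1L, id = "E1", pub = "PE1", stage = "preclinical"))
    recs <- list(
        mkRec(c("C01", "C02", "C03"), "GFAP", 1),
        mkRec(c("H1", "H2"), "GFAP", 1),
        mkRec("B1", "GFAP", 1), mkRec("B2", "GFAP", -1),  # conflict
        mkRec("V1", "GFAP", 1),
        mkRec("E1", "GFAP", 1),          # early stage: out of scope here
        mkRec("V1", "AQP4", 1))          # ventricle-only gene
    rs <- regionScores(callDEP(buildCorpus(meta, recs)))
    g <- rs[rs$gene_id == "GFAP", ]
    expect_equal(g$combined_vulnerable, 5)  # frontal +3, hippocampus +2
    expect_equal(g$combined_resistant, 0)   # cerebellum conflict: no score
    a <- rs[rs$gene_id == "AQP4", ]
    expect_equal(a$combined_vulnerable, 0)
    expect_equal(a$combined_resistant, 0)
})

test_that("vulnerability categories follow the sign pattern at the >= 5 bar", {
    rs <- data.frame(gene_id = letters[1:6],
                     combined_vulnerable = c(6, -5, -5, 4, 5, -6),
                     combined_resistant = c(0, -2, 2, 0, 3, 0),
                     vulnerable_mixed = FALSE, resistant_mixed = FALSE,
                     n_vulnerable = c(6L, 5L, 5L, 4L, 5L, 6L),
                     n_resistant = c(0L, 2L, 2L, 0L, 3L, 0L))
    out <- classifyVulnerability(rs)
    expect_equal(as.character(out$vulnerability_category),
                 c("inc_vuln_only", "dec_both", "dec_vuln_inc_res",
                   "not_high_confidence", "inc_both", "dec_vuln_only"))
    # mixed signs inside a class make the call inconsistent
    rs$vulnerable_mixed[1] <- TRUE
    expect_equal(as.character(
        classifyVulnerability(rs)$vulnerability_category[1]),
        "inconsistent")
    # count-based high confidence admits |score| < 5 with enough support
    rs2 <- rs[4, ]; rs2$n_vulnerable <- 6L; rs2$vulnerable_mixed <- FALSE
    expect_equal(as.character(classifyVulnerability(
        rs2, highConfidence = "count")$vulnerability_category),
        "inc_vuln_only")
})

test_that("categories partition all high-confidence genes", {
    sim <- simulateCorpus(simulationConfig(nGenes = 400), seed = 9)
    rv <- classifyVulnerability(regionScores(sim$corpus),
                                thresholds(sim$corpus))
    hc <- rv$vulnerability_category != "not_high_confidence"
    expect_equal(sum(abs(rv$combined_vulnerable) >= 5), sum(hc))
    expect_false(any(is.na(rv$vulnerability_category)))
    inc <- rv$vulnerability_category == "inc_both"
    expect_true(all(rv$combined_vulnerable[inc] > 0 &
                    rv$combined_resistant[inc] > 0))
})
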