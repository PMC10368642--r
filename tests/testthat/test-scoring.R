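test_that("thresholds validate their constraints", {
    th <- analysisThresholds()
    expect_equal(minStudies(th), 5L)
    expect_equal(outlierAllowance(th), 1L)
    expect_equal(fcCutoff(th), 1.5)
    expect_error(analysisThresholds(minStudies = 3, outlierAllowance = 3),
                 "smaller")
    expect_error(analysisThresholds(fcCutoff = 0.9), "exceed 1")
    expect_error(analysisThresholds(alpha = -0.1), "positive")
})

test_that("bulk consistency classification follows the one-outlier rule", {
    cls <- function(u, d) as.character(classifyDirection(u, d))
    expect_equal(cls(5, 0), "increased")
    expect_equal(cls(5, 8), "inconsistent")  # a binary UCHL1-like split
    expect_equal(cls(4, 1), "increased")
    expect_equal(cls(3, 0), "insufficient")
    expect_equal(cls(0, 5), "decreased")
    expect_equal(cls(2, 3), "inconsistent")
})

test_that("classification agrees with the brute-force oracle to n = 10", {
    for (n in 0:10) for (u in 0:n) {
        expect_identical(as.character(classifyDirection(u, n - u)),
                         oracleClassify(u, n - u),
                         info = paste(u, "up,", n - u, "down"))
    }
})

test_that("scores count DEP comparisons overall and in bulk only", {
    meta <- rbind(mkMeta(3L),
                  mkMeta(2L, id = c("L1", "L2"), pub = c("P04", "P05"),
                         region = "hippocampus", stage = "not_applicable",
                         fraction = "lesion", sample = "plaque",
                         scheme = "LESION_FC"))
    recs <- list(mkRec("C01", c("GFAP", "CLU"), c(1, 1)),
                 mkRec("C02", "GFAP", 1),
                 mkRec("C03", "GFAP", -1),
                 mkRec("L1", "GFAP", 1, fc = 2.2, p = NA),
                 mkRec("L2", "GFAP", 1, fc = 3.1, p = NA))
    sc <- computeScores(callDEP(buildCorpus(meta, recs)))
    g <- sc[sc$gene_id == "GFAP", ]
    expect_equal(g$neuropro_score, 5L)
    expect_equal(g$bulk_score, 3L)
    expect_equal(g$bulk_up, 2L)
    expect_equal(g$bulk_down, 1L)
    expect_equal(as.character(g$bulk_class), "insufficient")
    expect_equal(sc$neuropro_score[sc$gene_id == "CLU"], 1L)
    # empty corpus gives an empty summary
    empty <- computeScores(callDEP(buildCorpus(mkMeta(1L), list())))
    expect_equal(nrow(empty), 0L)
})

test_that("a 13-report binary split is scored 13 and inconsistent", {
    corpus <- tallyCorpus(5, 8)
    sc <- computeScores(corpus)
    expect_equal(sc$bulk_score, 13L)
    expect_equal(as.character(sc$bulk_class), "inconsistent")
})

test_that("publication-level counting collapses multi-comparison studies", {
    meta <- mkMeta(6L, pub = c("P1", "P1", "P2", "P3", "P4", "P5"))
    rec <- mkRec(meta$comparison_id, "GFAP", 1L)
    corpus <- callDEP(buildCorpus(meta, rec))
    expect_equal(computeScores(corpus)$bulk_score, 6L)
    byPub <- computeScores(corpus, countBy = "publication")
    expect_equal(byPub$bulk_score, 5L)
    expect_equal(byPub$bulk_up, 5L)
})

test_that("the top set is score-ordered with lexicographic ties", {
    sc <- data.frame(gene_id = c("B", "C", "A"),
                     neuropro_score = c(15, 14, 16))
    expect_equal(topSet(sc, 15), c("A", "B"))
    expect_equal(topSet(sc[0, ], 15), character(0))
    sc2 <- data.frame(gene_id = c("B", "A"), neuropro_score = c(15, 15))
    expect_equal(topSet(sc2, 15), c("A", "B"))
})

test_that("adding a concordant report never flips a directional class", {
    set.seed(5)
    for (i in 1:50) {
        u <- sample(0:8, 1); d <- sample(0:8, 1)
        cls <- as.character(classifyDirection(u, d))
        if (cls == "increased")
            expect_equal(as.character(classifyDirection(u + 1, d)),
                         "increased")
        if (cls == "decreased")
            expect_equal(as.character(classifyDirection(u, d + 1)),
                         "decreased")
    }
})
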