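lesionMeta <- function(id, sample, scheme = "LESION_FC", pub = id) {
    mkMeta(1L, id = id, pub = pub, region = "hippocampus",
           stage = "not_applicable", fraction = "lesion", sample = sample,
           scheme = scheme)
}

test_that("lesion calls use the strict fold-change band and presence floor", {
    meta <- rbind(lesionMeta("PL1", "plaque"),
                  lesionMeta("PL2", "plaque", "PRESENCE_CASES", "PL2p"),
                  lesionMeta("NF1", "NFT", "PRESENCE_CASES"),
                  lesionMeta("CA1", "CAA"))
    recs <- list(
        rbind(mkRec("PL1", "GFAP", 1, fc = 1.6, p = NA),
              mkRec("PL1", "CLU", 1, fc = 1.5, p = NA)),   # inside the band
        mkRec("PL2", "APOE", dir = NA, fc = NA, p = NA, cases = 4),
        rbind(mkRec("NF1", "MAPT", dir = NA, fc = NA, p = NA, cases = 3),
              mkRec("NF1", "SNCA", dir = NA, fc = NA, p = NA, cases = 2)),
        mkRec("CA1", "VGF", -1, fc = 0.60, p = NA))
    corpus <- suppressWarnings(callDEP(buildCorpus(meta, recs)))
    ls <- lesionStatus(corpus)
    s <- function(g, col) as.character(ls[[col]][ls$gene_id == g])
    expect_equal(s("GFAP", "plaque_status"), "enriched")
    expect_equal(s("CLU", "plaque_status"), "present")  # 1.5 is not > 1.5
    expect_equal(s("APOE", "plaque_status"), "present")
    expect_equal(s("MAPT", "NFT_status"), "present")
    expect_false("SNCA" %in% ls$gene_id)  # 2 cases misses the >= 3 floor
    expect_equal(s("VGF", "CAA_status"), "depleted")  # 0.60 < 1/1.5
    expect_equal(s("GFAP", "CAA_status"), "absent")
})

test_that("conflicting enrichment and depletion fall back to present", {
    meta <- rbind(lesionMeta("PL1", "plaque"), lesionMeta("PL2", "plaque"))
    recs <- list(mkRec("PL1", "GFAP", 1, fc = 2, p = NA),
                 mkRec("PL2", "GFAP", -1, fc = 0.4, p = NA))
    ls <- lesionStatus(callDEP(buildCorpus(meta, recs)))
    expect_equal(as.character(ls$plaque_status), "present")
    expect_true(ls$plaque_conflict)
})

test_that("inverting every lesion fold change swaps enriched and depleted", {
    set.seed(3)
    meta <- lesionMeta("PL1", "plaque")
    fc <- exp(rnorm(40, 0, 0.8))
    recs <- mkRec("PL1", sprintf("G%02d", 1:40),
                  dir = ifelse(fc > 1, 1L, -1L), fc = fc, p = NA)
    ls1 <- lesionStatus(callDEP(buildCorpus(meta, recs)))
    recs$fold_change <- 1 / recs$fold_change
    recs$direction <- -recs$direction
    ls2 <- lesionStatus(callDEP(buildCorpus(meta, recs)))
    e1 <- ls1$gene_id[ls1$plaque_status == "enriched"]
    d2 <- ls2$gene_id[ls2$plaque_status == "depleted"]
    expect_setequal(e1, d2)
    d1 <- ls1$gene_id[ls1$plaque_status == "depleted"]
    e2 <- ls2$gene_id[ls2$plaque_status == "enriched"]
    expect_setequal(d1, e2)
})

test_that("three-set partition matches the worked example and edge cases", {
    v <- vennPartition(c("A", "B", "C"), c("B", "C", "D"), "C")
    expect_equal(v$A_B_C, "C")
    expect_equal(v$A_B, "B")
    expect_equal(v$A_only, "A")
    expect_equal(v$B_only, "D")
    expect_equal(lengths(v[c("C_only", "A_C", "B_C")]),
                 c(C_only = 0L, A_C = 0L, B_C = 0L))
    same <- vennPartition(letters[1:4], letters[1:4], letters[1:4])
    expect_equal(same$A_B_C, letters[1:4])
    expect_equal(sum(lengths(same)), 4L)
    disj <- vennPartition("x", "y", "z")
    expect_equal(lengths(disj[c("A_only", "B_only", "C_only")]),
                 c(A_only = 1L, B_only = 1L, C_only = 1L))
})

test_that("bulk cross-tabulation is exhaustive and conserving", {
    sc <- data.frame(gene_id = c("X", "Y", "Z"),
                     bulk_class = factor(c("increased", "insufficient",
                                           "inconsistent")))
    ct <- bulkCrosstab(c("X", "Y"), sc)
    expect_equal(ct, c(increased = 1L, decreased = 0L, inconsistent = 0L,
                       unaltered = 1L))
    expect_equal(sum(bulkCrosstab(character(0), sc)), 0L)
    # genes absent from bulk scoring count as unaltered
    ct2 <- bulkCrosstab(c("X", "Z", "UNSEEN"), sc)
    expect_equal(sum(ct2), 3L)
    expect_equal(unname(ct2["unaltered"]), 1L)
})
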