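test_that("Welch t-test matches the frozen oracle values and conventions", {
    r <- welchTTest(c(2, 3, 4), c(1, 2, 3))
    expect_equal(r$t, 1.224745, tolerance = 1e-5)
    expect_equal(r$df, 4, tolerance = 1e-6)
    expect_equal(r$p, 0.287864, tolerance = 1e-5)
    # swapping groups flips the sign only
    r2 <- welchTTest(c(1, 2, 3), c(2, 3, 4))
    expect_equal(r2$t, -r$t)
    expect_equal(r2$p, r$p)
    # identical groups
    r3 <- welchTTest(c(1, 2, 3), c(1, 2, 3))
    expect_equal(r3$t, 0)
    expect_equal(r3$p, 1)
    # degenerate conventions and preconditions
    expect_equal(welchTTest(c(2, 2), c(2, 2))$p, 1)
    expect_equal(welchTTest(c(3, 3), c(2, 2))$p, 0)
    expect_error(welchTTest(c(2, 3), 1), "n >= 2")
})

test_that("null p-values are uniform (KS at 10,000 replicates)", {
    set.seed(42)
    p <- replicate(10000, welchTTest(rnorm(4), rnorm(4))$p)
    expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("fold change is a positive ratio with reciprocal symmetry", {
    expect_equal(foldChange(3, 2), 1.5)
    expect_equal(foldChange(2, 3), 2 / 3)
    for (x in c(0.1, 1, 7.3)) expect_equal(foldChange(x, x), 1)
    set.seed(1)
    a <- runif(50, 0.1, 10); b <- runif(50, 0.1, 10)
    expect_equal(foldChange(a, b) * foldChange(b, a), rep(1, 50))
    expect_error(foldChange(-1, 2), "positive")
    expect_error(foldChange(1, 0), "positive")
})

test_that("BH adjustment matches the step-up rule and its invariances", {
    expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhFDR(0.03), 0.03)
    expect_equal(bhFDR(c(0.5, 0.5)), c(0.5, 0.5))
    expect_error(bhFDR(c(0.5, 1.2)), "\\[0, 1\\]")
    set.seed(7)
    p <- runif(40)
    q <- bhFDR(p)
    expect_true(all(q >= p) && all(q <= 1))
    # permutation invariance and elementwise monotonicity
    perm <- sample(40)
    expect_equal(bhFDR(p[perm]), q[perm])
    p2 <- p; p2[5] <- p2[5] / 2
    expect_true(all(bhFDR(p2) <= q + 1e-12))
})

test_that("scheme rules use strict cutoffs and infer direction from FC", {
    th <- analysisThresholds()
    expect_true(callDEPRecord(list(p_value = 0.01, fold_change = 1.6),
                              "FC_AND_P", th)$is_dep)
    expect_equal(callDEPRecord(list(p_value = 0.01, fold_change = 1.6),
                               "FC_AND_P", th)$direction, 1L)
    # 1.5 exactly fails the strict > 1.5 rule
    expect_false(callDEPRecord(list(p_value = 0.01, fold_change = 1.5),
                               "FC_AND_P", th)$is_dep)
    expect_false(callDEPRecord(list(p_value = 0.06, fold_change = 3),
                               "FC_AND_P", th)$is_dep)
    expect_true(callDEPRecord(list(fdr = 0.049), "FDR5", th)$is_dep)
    expect_false(callDEPRecord(list(fdr = 0.05), "FDR5", th)$is_dep)
    expect_true(callDEPRecord(list(case_presence = 3), "PRESENCE_CASES",
                              th)$is_dep)
    expect_false(callDEPRecord(list(case_presence = 2), "PRESENCE_CASES",
                               th)$is_dep)
    expect_true(is.na(callDEPRecord(list(fold_change = 2), "FC_AND_P",
                                    th)$is_dep))
    # reciprocal symmetry: (p, FC) is a DEP iff (p, 1/FC) is, opposite sign
    set.seed(11)
    for (i in 1:25) {
        fc <- exp(rnorm(1, 0, 1)); p <- runif(1, 0, 0.1)
        a <- callDEPRecord(list(p_value = p, fold_change = fc),
                           "FC_AND_P", th)
        b <- callDEPRecord(list(p_value = p, fold_change = 1 / fc),
                           "FC_AND_P", th)
        expect_identical(a$is_dep, b$is_dep)
        if (isTRUE(a$is_dep)) expect_equal(a$direction, -b$direction)
    }
})

test_that("corpus-level DEP calls follow each comparison's scheme", {
    meta <- rbind(mkMeta(1L, id = "C01", scheme = "FC_AND_P"),
                  mkMeta(1L, id = "C02", pub = "P02", scheme = "FDR5"))
    recs <- list(
        rbind(mkRec("C01", "GFAP", fc = 1.6, p = 0.01),
              mkRec("C01", "CLU", fc = 1.4, p = 0.01),   # below FC cutoff
              mkRec("C01", "VGF", -1, fc = 0.5, p = 0.2)),  # p too big
        rbind(mkRec("C02", "GFAP", fc = 1.2, fdr = 0.01),
              mkRec("C02", "CLU", fc = 1.2, fdr = 0.2)))
    corpus <- suppressWarnings(callDEP(buildCorpus(meta, recs)))
    dep <- corpusRecords(corpus, depOnly = TRUE)
    key <- paste(dep$comparison_id, dep$gene_id)
    expect_setequal(key, c("C01 GFAP", "C02 GFAP"))
})
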