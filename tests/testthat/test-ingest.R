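test_that("protein tables read with column mapping, preserving gaps", {
    f <- tempfile(fileext = ".tsv")
    writeLines(c("gene\tuniprot\tlog2fc\tp",
                 "GFAP\tP14136\t1.0\t0.001",
                 "CLU\tP10909-2\t\t0.2",
                 "VGF\tO15240\t-2.0\t"), f)
    raw <- readProteinTable(f, c(gene = "gene", uniprot = "uniprot",
                                 fold_change = "log2fc", p_value = "p"),
                            fcScale = "log2")
    expect_equal(nrow(raw), 3L)
    expect_equal(raw$gene, c("GFAP", "CLU", "VGF"))
    expect_true(is.na(raw$fold_change[2]))  # missing, not zero
    expect_true(is.na(raw$p_value[3]))
    expect_identical(attr(raw, "fc_scale"), "log2")

    writeLines("gene\tuniprot\tlog2fc\tp", f)
    expect_equal(nrow(readProteinTable(f, c(gene = "gene"))), 0L)

    writeLines(c("foo\tbar", "1\t2"), f)
    expect_error(readProteinTable(f, c(gene = "gene")), "schema")

    writeLines(c("gene\tp", "GFAP\tnot-a-number"), f)
    expect_error(readProteinTable(f, c(gene = "gene", p_value = "p")),
                 "line 2")
})

test_that("harmonization applies the identifier and filtering rules", {
    raw <- data.frame(
        gene = c("GFAP;GFAP-AS1", "CLU", "CLU", "APP", "VGF", NA),
        uniprot = c("P14136", "P10909-2", "P10909", "P05067-4", NA, NA),
        fold_change = c(1, 2, 1.8, 0.5, NA, 2),
        p_value = c(0.001, 0.04, 0.01, 0.02, 0.03, 0.01),
        direction = c(NA, NA, NA, NA, "down", NA),
        n_peptides = c(5, 3, 3, 1, 4, 2))
    attr(raw, "fc_scale") <- "log2"
    expect_warning(
        rec <- harmonizeRecords(raw, mkMeta(1L)),
        "no usable gene")
    # log2 converted, first gene kept, isoforms stripped
    expect_equal(rec$fold_change[rec$gene_id == "GFAP"], 2)
    expect_false(any(grepl("-[0-9]+$", rec$uniprot_id)))
    expect_true("GFAP" %in% rec$gene_id)
    # CLU deduplicated keeping the smaller p
    expect_equal(sum(rec$gene_id == "CLU"), 1L)
    expect_equal(rec$p_value[rec$gene_id == "CLU"], 0.01)
    # single-peptide APP removed; direction-only VGF kept with direction -1
    expect_false("APP" %in% rec$gene_id)
    expect_equal(rec$direction[rec$gene_id == "VGF"], -1L)
    dl <- attr(rec, "dropLog")
    expect_equal(dl$unidentifiable, 1L)
    expect_equal(dl$peptide_filter, 1L)
    expect_equal(dl$duplicate_gene, 1L)
    # conservation: rows in = records out + drops
    expect_equal(nrow(raw), nrow(rec) + sum(unlist(dl)))
    # idempotence
    again <- harmonizeRecords(rec, mkMeta(1L))
    expect_equal(again[, colnames(rec)], rec, ignore_attr = TRUE)
})

test_that("corpus assembly conserves records and enforces referential integrity", {
    meta <- mkMeta(2L)
    r1 <- mkRec("C01", c("GFAP", "CLU", "VGF"), c(1, 1, -1))
    r2 <- mkRec("C02", c("GFAP", "APP", "CLU", "SNAP25"), c(1, 1, 1, -1))
    corpus <- buildCorpus(meta, list(r1, r2))
    expect_s4_class(corpus, "ProteinCorpus")
    expect_equal(nrow(corpusRecords(corpus)), 7L)
    expect_equal(sum(!is.na(SummarizedExperiment::assay(corpus,
                                                        "direction")["GFAP", ])),
                 2L)
    bad <- mkRec("CX", "GFAP")
    expect_error(buildCorpus(meta, list(r1, bad)), "unknown comparison_id")
    expect_error(buildCorpus(meta, list(r1, r1)), "duplicate")
    # no isoform suffixes or duplicate pairs survive in a built corpus
    rec <- corpusRecords(corpus)
    expect_false(any(grepl("-[0-9]+$", rec$uniprot_id[!is.na(rec$uniprot_id)])))
    expect_false(anyDuplicated(paste(rec$comparison_id, rec$gene_id)) > 0)
})

test_that("metadata validation rejects incoherent comparisons", {
    meta <- mkMeta(1L)
    meta$sample_type <- "plaque"  # lesion sample with bulk scheme
    expect_error(buildCorpus(meta, mkRec("C01", "GFAP")), "lesion")
})

test_that("ventricle wall must stay unassigned", {
    meta <- mkMeta(1L, region = "ventricle wall")
    expect_identical(meta$region_class, "unassigned")
    meta$region_class <- "vulnerable"
    expect_error(buildCorpus(meta, mkRec("C01", "A")), "ventricle")
})

test_that("long-export round trip reproduces the corpus", {
    meta <- mkMeta(3L)
    recs <- list(mkRec("C01", c("GFAP", "CLU"), c(1, -1)),
                 mkRec("C02", c("GFAP", "VGF"), c(1, -1)),
                 mkRec("C03", "GFAP", 1))
    corpus <- callDEP(buildCorpus(meta, recs))
    f <- tempfile(fileext = ".tsv")
    exportCorpus(corpus, f)
    back <- callDEP(importCorpusExport(f))
    expect_equal(corpusRecords(back)[, c("comparison_id", "gene_id",
                                         "direction")],
                 corpusRecords(corpus)[, c("comparison_id", "gene_id",
                                           "direction")])
    expect_equal(computeScores(back), computeScores(corpus))
})
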