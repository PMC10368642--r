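# Builders for tiny in-code corpora and independent rule oracles.

mkMeta <- function(n = 1L, id = sprintf("C%02d", seq_len(n)),
                   pub = sprintf("P%02d", seq_len(n)),
                   region = "frontal cortex", stage = "advanced",
                   fraction = "total", sample = "bulk",
                   scheme = "FC_AND_P") {
    data.frame(comparison_id = id, publication_id = pub,
               brain_region = region, clinical_stage = stage,
               tissue_fraction = fraction, sample_type = sample,
               dep_scheme = scheme,
               region_class = defaultRegionClass(region),
               stringsAsFactors = FALSE)
}

mkRec <- function(cid, gene, dir = 1L, fc = NULL, p = 0.01,
                  fdr = NA_real_, peptides = 5, cases = NA_real_,
                  uniprot = NA_character_) {
    if (is.null(fc)) fc <- ifelse(dir > 0, 2, 0.5)
    data.frame(comparison_id = cid, gene_id = gene, uniprot_id = uniprot,
               direction = as.integer(dir), fold_change = fc, p_value = p,
               fdr = fdr, n_peptides = peptides, case_presence = cases,
               stringsAsFactors = FALSE)
}

# one gene reported in a given up/down split across FC_AND_P bulk
# comparisons of one stage/region
tallyCorpus <- function(nUp, nDown, gene = "GENE1", stage = "advanced",
                        region = "frontal cortex") {
    n <- nUp + nDown
    meta <- mkMeta(n, region = region, stage = stage)
    dirs <- c(rep(1L, nUp), rep(-1L, nDown))
    rec <- mkRec(meta$comparison_id, gene, dirs)
    callDEP(buildCorpus(meta, rec))
}

# the bulk-consistency rule, written directly from its verbal definition
oracleClassify <- function(up, down, k = 5L, m = 1L) {
    n <- up + down
    if (n < k) return("insufficient")
    if (min(up, down) <= m && up != down)
        return(if (up > down) "increased" else "decreased")
    "inconsistent"
}

# the within-stratum rule: unanimity below k, one outlier at >= k
oracleStage <- function(up, down, k = 5L, m = 1L) {
    n <- up + down
    if (n == 0L) return(NA_integer_)
    if (min(up, down) == 0L) return(as.integer(sign(up - down)))
    if (n >= k && min(up, down) <= m && up != down)
        return(as.integer(sign(up - down)))
    NA_integer_
}

# criterion design used for recovery benchmarking: 12 advanced-vulnerable,
# 6 early-stage, 4 advanced-resistant bulk comparisons
recoveryDesign <- function(power = 0.6) {
    add <- function(n, stage, region, tag)
        mkMeta(n, id = sprintf("%s%02d", tag, seq_len(n)),
               pub = sprintf("PUB_%s%02d", tag, seq_len(n)),
               region = region, stage = stage)
    d <- rbind(add(12, "advanced", "frontal cortex", "ADV"),
               add(3, "preclinical", "frontal cortex", "PRE"),
               add(3, "MCI", "frontal cortex", "MCI"),
               add(4, "advanced", "cerebellum", "RES"))
    d$power <- power
    d
}

noiseFreeConfig <- function(nGenes = 400L) {
    d <- defaultStudyDesign()
    d$power <- 1
    simulationConfig(nGenes = nGenes, design = d, flipRate = 0,
                     backgroundRate = 0, effectSdlog = 0)
}
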