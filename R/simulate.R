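#' Default multi-study design for simulated corpora
#'
#' A corpus layout emulating the published study landscape the analysis
#' was built for: 59 bulk-tissue comparisons from 32 publications spanning
#' 13 brain regions, three clinical stages and several tissue fractions
#' and significance schemes, plus 7 lesion comparisons (4 amyloid-plaque,
#' 2 NFT, 1 CAA). Per-comparison detection power is tiered by the size of
#' the DEP list the corresponding study class reports: high-powered
#' studies 0.9, mid 0.5, low 0.2 -- reflecting that low-powered studies
#' mostly miss subtle changes (false negatives) rather than invent false
#' positives.
#'
#' @return A data.frame of comparison templates with a \code{power}
#'   column, suitable for [simulationConfig()].
#' @export
defaultStudyDesign <- function() {
    study <- function(pub, regions, stages, fraction, scheme, power,
                      sample = "bulk") {
        g <- expand.grid(brain_region = regions, clinical_stage = stages,
                         stringsAsFactors = FALSE)
        data.frame(publication_id = pub, brain_region = g$brain_region,
                   clinical_stage = g$clinical_stage,
                   tissue_fraction = fraction, sample_type = sample,
                   dep_scheme = scheme, power = power,
                   stringsAsFactors = FALSE)
    }
    adv <- "advanced"
    allStages <- c("preclinical", "MCI", "advanced")
    preAdv <- c("preclinical", "advanced")
    d <- rbind(
        study("PUB01", "temporal cortex", adv, "total", "FDR5", 0.5),
        study("PUB02", "entorhinal cortex", adv, "total", "FC_AND_P", 0.5),
        study("PUB03", "frontal cortex", allStages, "total", "FC_AND_P", 0.2),
        study("PUB04", "parietal cortex", preAdv, "synaptic", "FDR5", 0.5),
        study("PUB05", "frontal cortex", adv, "total", "FC_AND_P", 0.5),
        study("PUB06", "frontal cortex", adv, "membrane", "FC_AND_P", 0.2),
        study("PUB07", "frontal cortex", allStages, "insoluble",
              "FC_AND_P", 0.5),
        study("PUB08", "hippocampus", adv, "subregion", "FDR5", 0.2),
        study("PUB09", "frontal cortex", adv, "total", "FC_AND_P", 0.5),
        study("PUB10", "hippocampus", adv, "subregion", "FDR5", 0.5),
        study("PUB11", "hippocampus", adv, "subregion", "FDR5", 0.5),
        study("PUB12", "frontal cortex", preAdv, "total",
              "ANOVA_POSTHOC", 0.9),
        study("PUB13", "frontal cortex", preAdv, "total",
              "ANOVA_POSTHOC", 0.9),
        study("PUB14", "frontal cortex", preAdv, "total",
              "ANOVA_POSTHOC", 0.9),
        study("PUB15", "occipital cortex", preAdv, "soluble",
              "KRUSKAL_WALLIS", 0.2),
        study("PUB16", c("hippocampus", "cerebellum"), adv, "total",
              "FC_AND_P", 0.2),
        study("PUB17", "entorhinal cortex", adv, "total", "FC_AND_P", 0.5),
        study("PUB18", c("entorhinal cortex", "parahippocampal cortex",
                         "frontal cortex", "temporal cortex"),
              c("MCI", "advanced"), "total", "FC_AND_P", 0.9),
        study("PUB19", "frontal cortex", adv, "extracellular-vesicle",
              "FC_AND_P", 0.2),
        study("PUB20", "temporal cortex", adv, "total", "FC_AND_P", 0.2),
        study("PUB21", "frontal cortex", adv, "blood-vessel",
              "FC_AND_P", 0.2),
        study("PUB22", "frontal cortex", adv, "blood-vessel",
              "FC_AND_P", 0.5),
        study("PUB23", "ventricle wall", adv, "membrane", "FDR5", 0.2),
        study("PUB24", "frontal cortex", preAdv, "total", "FC_AND_P", 0.5),
        study("PUB25", c("frontal cortex", "precuneus"), preAdv, "total",
              "ANOVA_POSTHOC", 0.9),
        study("PUB26", c("hippocampus", "parietal cortex"), adv, "total",
              "FC_AND_P", 0.2),
        study("PUB27", "entorhinal cortex", adv, "total", "FDR5", 0.5),
        study("PUB28", "frontal cortex", adv, "total", "FDR5", 0.5),
        study("PUB29", "frontal cortex", adv, "total", "FDR5", 0.9),
        study("PUB30", c("hippocampus", "entorhinal cortex",
                         "cingulate gyrus", "motor cortex",
                         "sensory cortex", "cerebellum"), adv, "total",
              "FDR5", 0.9),
        study("PUB31", "parietal cortex", adv, "blood-vessel",
              "FC_AND_P", 0.5),
        study("PUB32", "frontal cortex", adv, "total", "FDR5", 0.5),
        # microdissected lesion proteomes
        study("PUB33", "hippocampus", "not_applicable", "lesion",
              "PRESENCE_CASES", 0.9, sample = "plaque"),
        study("PUB34", "hippocampus", "not_applicable", "lesion",
              "LESION_FC", 0.9, sample = "plaque"),
        study("PUB35", "frontal cortex", "not_applicable", "lesion",
              "LESION_FC", 0.2, sample = "plaque"),
        study("PUB36", "hippocampus", "not_applicable", "lesion",
              "LESION_FC", 0.5, sample = "plaque"),
        study("PUB37", "hippocampus", "not_applicable", "lesion",
              "PRESENCE_CASES", 0.5, sample = "NFT"),
        study("PUB38", "hippocampus", "not_applicable", "lesion",
              "LESION_FC", 0.5, sample = "NFT"),
        study("PUB31", "parietal cortex", "not_applicable", "lesion",
              "LESION_FC", 0.5, sample = "CAA"))
    d$comparison_id <- sprintf("C%03d", seq_len(nrow(d)))
    d$region_class <- defaultRegionClass(d$brain_region)
    d[, c("comparison_id", "publication_id", "brain_region",
          "clinical_stage", "tissue_fraction", "sample_type", "dep_scheme",
          "region_class", "power")]
}

#' Configuration of the synthetic-corpus generator
#'
#' Bundles and validates the generator's knobs. The noise model follows
#' the false-negative-dominated account of inter-study inconsistency:
#' detection of a truly altered gene succeeds with probability
#' power x effect magnitude (capped at 1), so low-powered studies mostly
#' miss subtle effects; a detected change is reported with the wrong sign
#' rarely (\code{flipRate}), and null genes almost never appear
#' (\code{backgroundRate} much smaller than \code{flipRate}).
#'
#' @param nGenes size of the gene universe.
#' @param design comparison templates with a \code{power} column, as from
#'   [defaultStudyDesign()].
#' @param flipRate probability a detected change is reported with the
#'   wrong sign.
#' @param backgroundRate probability a null gene is falsely reported in a
#'   comparison.
#' @param phaseProps named proportions of genes planted in phases 1-3; the
#'   remainder are null.
#' @param propIncreased proportion of altered genes whose true direction
#'   is an increase.
#' @param effectMeanlog,effectSdlog log-normal parameters of the positive
#'   effect-magnitude distribution that scales detectability (long-tailed,
#'   so low power naturally truncates weak effects).
#' @param lesionRates named probabilities a gene belongs to each lesion
#'   proteome (plaque, NFT, CAA).
#' @param lesionEnrichedFrac fraction of lesion members planted as
#'   enriched (> fold-change cutoff); the rest are planted depleted.
#' @param seed default random seed used by [simulateCorpus()].
#' @return A validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(nGenes = 2000L,
                             design = defaultStudyDesign(),
                             flipRate = 0.02,
                             backgroundRate = 0.002,
                             phaseProps = c(phase1 = 0.03, phase2 = 0.10,
                                            phase3 = 0.27),
                             propIncreased = 0.40,
                             effectMeanlog = 0, effectSdlog = 0.5,
                             lesionRates = c(plaque = 0.10, NFT = 0.03,
                                             CAA = 0.03),
                             lesionEnrichedFrac = 0.70,
                             seed = 1L) {
    probs <- c(flipRate, backgroundRate, phaseProps, propIncreased,
               lesionRates, lesionEnrichedFrac)
    if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
        stop("all rates and proportions must lie in [0, 1]")
    if (sum(phaseProps) > 1)
        stop("phase proportions must sum to at most 1")
    if (!all(c("phase1", "phase2", "phase3") %in% names(phaseProps)))
        stop("phaseProps needs names phase1, phase2, phase3")
    if (!all(.LESION_TYPES %in% names(lesionRates)))
        stop("lesionRates needs names plaque, NFT, CAA")
    if (!"power" %in% colnames(design) ||
        any(design$power <= 0 | design$power > 1))
        stop("design needs a power column in (0, 1]")
    validateComparisonMeta(design[, .META_COLUMNS])
    structure(list(nGenes = as.integer(nGenes), design = design,
                   flipRate = flipRate, backgroundRate = backgroundRate,
                   phaseProps = phaseProps, propIncreased = propIncreased,
                   effectMeanlog = effectMeanlog,
                   effectSdlog = effectSdlog, lesionRates = lesionRates,
                   lesionEnrichedFrac = lesionEnrichedFrac,
                   seed = as.integer(seed)),
              class = "SimulationConfig")
}

.fcOnSide <- function(n, dir, tau) {
    mag <- tau * exp(runif(n, 0.02, 0.80))
    ifelse(dir > 0, mag, 1 / mag)
}

#' Simulate a multi-study corpus with known ground truth
#'
#' Plants a per-gene truth (direction, disease phase, effect magnitude,
#' lesion membership with fold changes beyond the cutoff) and emits, per
#' comparison, the DEP reports a study of the given power would publish.
#' Phase-1 genes are eligible in resistant-region, early-stage and
#' advanced comparisons; phase-2 genes in early-stage and advanced
#' non-resistant comparisons; phase-3 genes in advanced non-resistant
#' comparisons only. Emitted fold changes, p-values, FDRs and presence
#' counts are drawn conditional on passing the comparison's scheme, so
#' every emitted record is a planted DEP report. Fixed seeds give
#' identical corpora.
#'
#' @param config a [simulationConfig()].
#' @param seed random seed (defaults to the one in `config`).
#' @return A list with \code{corpus} (a [ProteinCorpus-class], DEP calls
#'   already made) and \code{truth} (a data.frame with the planted
#'   per-gene direction, phase, magnitude and lesion status).
#' @export
simulateCorpus <- function(config = simulationConfig(),
                           seed = config$seed) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(seed)
    th <- analysisThresholds()
    tau <- th@fcCutoff
    n <- config$nGenes
    genes <- sprintf("G%05d", seq_len(n))
    pp <- config$phaseProps
    phase <- sample(c("phase1", "phase2", "phase3", "null"), n,
                    replace = TRUE,
                    prob = c(pp["phase1"], pp["phase2"], pp["phase3"],
                             1 - sum(pp)))
    dir <- ifelse(phase == "null", 0L,
                  ifelse(runif(n) < config$propIncreased, 1L, -1L))
    mag <- rlnorm(n, config$effectMeanlog, config$effectSdlog)
    truth <- data.frame(gene_id = genes,
                        uniprot_id = sprintf("Q%05d", seq_len(n)),
                        true_direction = dir, true_phase = phase,
                        effect_magnitude = mag,
                        stringsAsFactors = FALSE)
    for (lt in .LESION_TYPES) {
        member <- runif(n) < config$lesionRates[[lt]]
        status <- ifelse(!member, "none",
                         ifelse(runif(n) < config$lesionEnrichedFrac,
                                "enriched", "depleted"))
        truth[[paste0(lt, "_truth")]] <- status
    }
    design <- config$design
    records <- vector("list", nrow(design))
    for (j in seq_len(nrow(design))) {
        cmp <- design[j, ]
        if (cmp$sample_type == "bulk") {
            eligible <- switch(
                cmp$clinical_stage,
                preclinical = , MCI = phase %in% c("phase1", "phase2"),
                advanced = if (cmp$region_class == "resistant")
                    phase == "phase1"
                else phase %in% c("phase1", "phase2", "phase3"),
                rep(FALSE, n))
            detected <- eligible &
                runif(n) < pmin(1, cmp$power * mag)
            background <- phase == "null" &
                runif(n) < config$backgroundRate
            idx <- which(detected | background)
            if (length(idx) == 0L) next
            repDir <- integer(length(idx))
            isBg <- phase[idx] == "null"
            repDir[isBg] <- sample(c(-1L, 1L), sum(isBg), replace = TRUE)
            flip <- runif(sum(!isBg)) < config$flipRate
            repDir[!isBg] <- dir[idx[!isBg]] * ifelse(flip, -1L, 1L)
            m <- length(idx)
            fc <- .fcOnSide(m, repDir, tau)
            rec <- data.frame(
                comparison_id = cmp$comparison_id,
                gene_id = genes[idx], uniprot_id = truth$uniprot_id[idx],
                direction = repDir, fold_change = fc,
                p_value = runif(m, 0, th@alpha * 0.98),
                fdr = if (cmp$dep_scheme == "FDR5")
                    runif(m, 0, th@fdrCutoff * 0.98) else NA_real_,
                n_peptides = 2 + rpois(m, 4),
                case_presence = NA_real_, stringsAsFactors = FALSE)
            records[[j]] <- rec
        } else {
            st <- truth[[paste0(cmp$sample_type, "_truth")]]
            member <- st != "none"
            detected <- member & runif(n) < pmin(1, cmp$power * mag)
            idx <- which(detected)
            if (length(idx) == 0L) next
            m <- length(idx)
            if (cmp$dep_scheme == "PRESENCE_CASES") {
                rec <- data.frame(
                    comparison_id = cmp$comparison_id,
                    gene_id = genes[idx],
                    uniprot_id = truth$uniprot_id[idx],
                    direction = NA_integer_, fold_change = NA_real_,
                    p_value = NA_real_, fdr = NA_real_,
                    n_peptides = 2 + rpois(m, 4),
                    case_presence = th@presenceMinCases + rpois(m, 2),
                    stringsAsFactors = FALSE)
            } else {
                side <- ifelse(st[idx] == "enriched", 1L, -1L)
                fc <- .fcOnSide(m, side, tau)
                rec <- data.frame(
                    comparison_id = cmp$comparison_id,
                    gene_id = genes[idx],
                    uniprot_id = truth$uniprot_id[idx],
                    direction = side, fold_change = fc,
                    p_value = NA_real_, fdr = NA_real_,
                    n_peptides = 2 + rpois(m, 4),
                    case_presence = NA_real_, stringsAsFactors = FALSE)
            }
            records[[j]] <- rec
        }
    }
    corpus <- buildCorpus(design[, .META_COLUMNS],
                          records[!vapply(records, is.null, logical(1L))],
                          th)
    corpus <- callDEP(corpus)
    list(corpus = corpus, truth = truth)
}

#' Write a simulated corpus as a ready-to-run fixture directory
#'
#' Writes the comparison metadata, one per-comparison protein TSV in the
#' schema the ingest functions read, the truth table, and a pipeline
#' config (YAML) pointing at them.
#'
#' @param sim result of [simulateCorpus()].
#' @param dir output directory (created if needed).
#' @return The path of the written config file, invisibly.
#' @export
writeSimulatedCorpus <- function(sim, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    meta <- comparisonMeta(sim$corpus)
    write.table(meta, file.path(dir, "comparisons.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, na = "")
    rec <- corpusRecords(sim$corpus)
    tables <- lapply(meta$comparison_id, function(ci) {
        sub <- rec[rec$comparison_id == ci,
                   c("gene_id", "uniprot_id", "direction", "fold_change",
                     "p_value", "fdr", "n_peptides", "case_presence")]
        colnames(sub)[1:2] <- c("gene", "uniprot")
        f <- paste0(ci, ".tsv")
        write.table(sub, file.path(dir, f), sep = "\t", quote = FALSE,
                    row.names = FALSE, na = "")
        list(path = f, comparison_id = ci, fc_scale = "ratio",
             columns = list(gene = "gene", uniprot = "uniprot",
                            direction = "direction",
                            fold_change = "fold_change",
                            p_value = "p_value", fdr = "fdr",
                            n_peptides = "n_peptides",
                            case_presence = "case_presence"))
    })
    write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, na = "")
    cfg <- list(meta = "comparisons.tsv", tables = tables,
                output_dir = "out")
    cfgPath <- file.path(dir, "config.yaml")
    yaml::write_yaml(cfg, cfgPath)
    invisible(cfgPath)
}

#' Recovery of planted truth by the pipeline
#'
#' Compares inferred bulk-consistency classes and phase assignments with
#' the planted truth, restricted to genes meeting the detection floor (at
#' least \code{minStudies} bulk DEP reports). The metrics partition the
#' failure modes: direction accuracy is the fraction of truly altered
#' floor genes, among those that received a directional class, whose
#' sign matches the planted direction; the inconsistent fraction counts
#' floor genes that received no direction because of discordant reports;
#' phase accuracy is the fraction of truly phased floor genes assigned
#' their planted phase.
#'
#' @param scores data.frame from [computeScores()].
#' @param phases data.frame from [assignPhases()].
#' @param truth truth table from [simulateCorpus()].
#' @param thresholds an [AnalysisThresholds-class].
#' @return A list with \code{direction_accuracy}, \code{phase_accuracy},
#'   \code{inconsistent_fraction} and the numbers of genes scored.
#' @export
recoveryMetrics <- function(scores, phases, truth,
                            thresholds = analysisThresholds()) {
    k <- thresholds@minStudies
    floorGenes <- scores$gene_id[scores$bulk_up + scores$bulk_down >= k]
    tIdx <- match(floorGenes, truth$gene_id)
    altered <- floorGenes[truth$true_direction[tIdx] != 0]
    cls <- scores$bulk_class[match(altered, scores$gene_id)]
    trueDir <- truth$true_direction[match(altered, truth$gene_id)]
    directional <- cls %in% c("increased", "decreased")
    dirOK <- (cls[directional] == "increased") ==
        (trueDir[directional] == 1L)
    phaseMap <- c(phase1 = "phase1_pre_neuropathology",
                  phase2 = "phase2_early_AD",
                  phase3 = "phase3_advanced_AD")
    phased <- altered[truth$true_phase[match(altered, truth$gene_id)] %in%
                      names(phaseMap)]
    inferred <- as.character(phases$phase[match(phased, phases$gene_id)])
    planted <- phaseMap[truth$true_phase[match(phased, truth$gene_id)]]
    list(direction_accuracy = if (sum(directional)) mean(dirOK)
         else NA_real_,
         phase_accuracy = if (length(phased))
             mean(!is.na(inferred) & inferred == unname(planted))
         else NA_real_,
         inconsistent_fraction = if (length(floorGenes))
             mean(scores$bulk_class[match(floorGenes,
                                          scores$gene_id)] == "inconsistent")
         else NA_real_,
         n_floor = length(floorGenes), n_altered = length(altered),
         n_directional = sum(directional), n_phased = length(phased))
}
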