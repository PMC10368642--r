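#' Annotate summaries with reference gene sets
#'
#' Joins plain gene-symbol reference lists (for example high-confidence
#' mitochondrial or synaptic protein sets) onto a summary table as one
#' logical membership column per set. Matching is by exact symbol after
#' uppercasing; duplicate symbols in a reference file are deduplicated
#' silently; an empty reference yields a warning and an all-FALSE column.
#'
#' @param summaries data.frame with a \code{gene_id} column.
#' @param referenceSets named list; each element a character vector of
#'   gene symbols or the path of a one-symbol-per-line text file.
#' @return `summaries` with one additional logical column per set, named
#'   \code{in_<set name>}.
#' @examples
#' s <- data.frame(gene_id = c("GFAP", "ATP5F1A"))
#' annotateReferenceSets(s, list(mito = c("ATP5F1A")))
#' @export
annotateReferenceSets <- function(summaries, referenceSets = list()) {
    for (nm in names(referenceSets)) {
        ref <- referenceSets[[nm]]
        if (is.character(ref) && length(ref) == 1L && file.exists(ref))
            ref <- readLines(ref, warn = FALSE)
        ref <- unique(toupper(trimws(as.character(ref))))
        ref <- ref[ref != ""]
        if (length(ref) == 0L)
            warning("reference set '", nm, "' is empty")
        summaries[[paste0("in_", nm)]] <-
            toupper(summaries$gene_id) %in% ref
    }
    summaries
}

#' Full analysis of a built corpus
#'
#' Runs every analysis stage on a corpus with DEP calls: vote-count
#' scores and bulk consistency, staging, region vulnerability, phase
#' assignment, lesion statuses and overlaps, and the lesion-vs-bulk
#' cross-tabulations.
#'
#' @param corpus a [ProteinCorpus-class] (DEP calls are made if absent).
#' @param countBy counting unit, as in [computeScores()].
#' @param vulnerabilityConfidence high-confidence rule for
#'   [classifyVulnerability()].
#' @param minResistant resistant-side floor for [assignPhases()].
#' @param referenceSets optional reference sets for
#'   [annotateReferenceSets()].
#' @return A list with elements \code{corpus}, \code{scores},
#'   \code{stages}, \code{regions}, \code{phases}, \code{lesions},
#'   \code{venn} (enriched and depleted partitions), \code{crosstabs},
#'   \code{summaries} (the master per-gene table) and \code{report}.
#' @export
analyseCorpus <- function(corpus,
                          countBy = c("comparison", "publication"),
                          vulnerabilityConfidence = c("signed", "count"),
                          minResistant = 1,
                          referenceSets = list()) {
    countBy <- match.arg(countBy)
    vulnerabilityConfidence <- match.arg(vulnerabilityConfidence)
    th <- thresholds(corpus)
    if (all(is.na(SummarizedExperiment::assay(corpus, "isDEP"))) &&
        nrow(corpus) > 0L)
        corpus <- callDEP(corpus)
    scores <- computeScores(corpus, countBy)
    stages <- compareStages(stageScores(corpus, countBy), th)
    regions <- classifyVulnerability(regionScores(corpus, countBy), th,
                                     vulnerabilityConfidence)
    phases <- assignPhases(stages, regions, th, minResistant)
    lesions <- lesionStatus(corpus)
    enriched <- lesionSets(lesions, "enriched")
    depleted <- lesionSets(lesions, "depleted")
    venn <- list(
        enriched = vennPartition(enriched$plaque, enriched$NFT,
                                 enriched$CAA,
                                 labels = c("plaque", "NFT", "CAA")),
        depleted = vennPartition(depleted$plaque, depleted$NFT,
                                 depleted$CAA,
                                 labels = c("plaque", "NFT", "CAA")))
    crosstabs <- lapply(enriched, bulkCrosstab, scores = scores)
    summaries <- Reduce(function(a, b) merge(a, b, by = "gene_id",
                                             all = TRUE),
                        list(scores, stages, regions, lesions, phases))
    summaries <- summaries[order(summaries$gene_id), , drop = FALSE]
    rownames(summaries) <- NULL
    if (length(referenceSets))
        summaries <- annotateReferenceSets(summaries, referenceSets)
    res <- list(corpus = corpus, scores = scores, stages = stages,
                regions = regions, phases = phases, lesions = lesions,
                venn = venn, crosstabs = crosstabs, summaries = summaries)
    res$report <- summaryReport(res)
    res
}

#' Headline counts of an analysis
#'
#' Collapses an [analyseCorpus()] result into the flat named counts a
#' study of this kind reports: record totals, the consistency split of
#' genes with at least \code{minStudies} bulk reports, the top-set size,
#' stage / vulnerability / phase category counts, and lesion
#' enrichment/depletion/overlap sizes. Every count is reproducible from
#' the corresponding export table.
#'
#' @param res list from [analyseCorpus()].
#' @return Named numeric vector of counts.
#' @export
summaryReport <- function(res) {
    scores <- res$scores
    rec <- corpusRecords(res$corpus)
    dep <- corpusRecords(res$corpus, depOnly = TRUE)
    th <- thresholds(res$corpus)
    cls <- table(scores$bulk_class)
    stage <- table(res$stages$stage_category)
    vuln <- table(res$regions$vulnerability_category)
    phase <- table(res$phases$phase)
    lesionCount <- function(which) {
        vapply(lesionSets(res$lesions, which), length, integer(1L))
    }
    enr <- lesionCount("enriched")
    depl <- lesionCount("depleted")
    pres <- lesionCount("present")
    out <- c(
        n_records = nrow(rec),
        n_dep_records = nrow(dep),
        n_significant_genes = length(unique(dep$gene_id)),
        n_bulk_ge_min = sum(scores$bulk_up + scores$bulk_down >=
                            th@minStudies),
        n_increased = unname(cls["increased"]),
        n_decreased = unname(cls["decreased"]),
        n_inconsistent = unname(cls["inconsistent"]),
        n_top_set = length(topSet(scores, th@topSetCutoff)),
        setNames(as.integer(stage), paste0("stage_", names(stage))),
        setNames(as.integer(vuln), paste0("region_", names(vuln))),
        setNames(as.integer(phase), paste0("phase_", names(phase))),
        setNames(as.integer(enr), paste0(names(enr), "_enriched")),
        setNames(as.integer(depl), paste0(names(depl), "_depleted")),
        setNames(as.integer(pres), paste0(names(pres), "_present")),
        setNames(vapply(res$venn$enriched, length, integer(1L)),
                 paste0("venn_enriched_", names(res$venn$enriched))),
        setNames(vapply(res$venn$depleted, length, integer(1L)),
                 paste0("venn_depleted_", names(res$venn$depleted))))
    dl <- S4Vectors::metadata(res$corpus)$dropLog
    dropKeys <- c("unidentifiable", "no_direction", "peptide_filter",
                  "duplicate_gene")
    drops <- setNames(integer(length(dropKeys)),
                      paste0("dropped_", dropKeys))
    for (k in names(dl)) drops[paste0("dropped_", k)] <- dl[[k]]
    c(out, drops)
}

.writeExport <- function(df, path) {
    num <- vapply(df, is.numeric, logical(1L))
    df[num] <- lapply(df[num], signif, digits = 6L)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
}

#' Run the full pipeline from a config file
#'
#' Reads a YAML config describing the inputs (a comparison-metadata TSV
#' plus either per-comparison protein tables with column mappings, or a
#' single long-format export), harmonizes and assembles the corpus,
#' applies each comparison's significance scheme, runs every analysis
#' stage and writes the export TSVs and a key-value report into the
#' configured output directory. Relative paths resolve against the config
#' file's directory.
#'
#' Config keys: \code{meta} (path), \code{tables} (list of blocks with
#' \code{path}, \code{comparison_id}, \code{fc_scale}, \code{columns}),
#' or \code{export} (block with \code{path}, \code{fc_scale},
#' \code{columns}); optional \code{thresholds} (named overrides of
#' [analysisThresholds()] arguments), \code{output_dir},
#' \code{reference_sets} (name: path), and \code{options}
#' (\code{count_by}, \code{vulnerability_confidence},
#' \code{min_resistant}).
#'
#' @param configPath path to the YAML config.
#' @return Invisibly, the [analyseCorpus()] result list with an added
#'   \code{exports} element naming the written files.
#' @export
runPipeline <- function(configPath) {
    cfg <- yaml::read_yaml(configPath)
    base <- dirname(normalizePath(configPath))
    rel <- function(p) if (is.null(p) || grepl("^/", p)) p
                       else file.path(base, p)
    thArgs <- cfg$thresholds %||% list()
    names(thArgs) <- sub("^min_studies$", "minStudies",
                     sub("^outlier_allowance$", "outlierAllowance",
                     sub("^fc_cutoff$", "fcCutoff",
                     sub("^fdr_cutoff$", "fdrCutoff",
                     sub("^presence_min_cases$", "presenceMinCases",
                     sub("^top_set_cutoff$", "topSetCutoff",
                     sub("^min_peptides$", "minPeptides",
                         names(thArgs))))))))
    th <- do.call(analysisThresholds, thArgs)
    if (!is.null(cfg$export)) {
        corpus <- importCorpusExport(rel(cfg$export$path),
                                     columns = cfg$export$columns,
                                     fcScale = cfg$export$fc_scale %||%
                                         "ratio",
                                     thresholds = th)
    } else {
        if (is.null(cfg$meta) || is.null(cfg$tables))
            stop("config needs either an 'export' block or 'meta' + 'tables'")
        meta <- readComparisonMeta(rel(cfg$meta))
        records <- lapply(cfg$tables, function(tb) {
            if (!tb$comparison_id %in% meta$comparison_id)
                stop("table block references unknown comparison_id ",
                     tb$comparison_id)
            raw <- readProteinTable(rel(tb$path), tb$columns,
                                    fcScale = tb$fc_scale %||% "ratio")
            harmonizeRecords(raw,
                             meta[meta$comparison_id == tb$comparison_id, ],
                             th)
        })
        corpus <- buildCorpus(meta, records, th)
    }
    corpus <- callDEP(corpus)
    opts <- cfg$options %||% list()
    res <- analyseCorpus(
        corpus,
        countBy = opts$count_by %||% "comparison",
        vulnerabilityConfidence = opts$vulnerability_confidence %||%
            "signed",
        minResistant = opts$min_resistant %||% 1,
        referenceSets = lapply(cfg$reference_sets %||% list(), rel))
    outDir <- rel(cfg$output_dir %||% "out")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    exports <- c(
        corpus = file.path(outDir, "corpus_records.tsv"),
        summaries = file.path(outDir, "protein_summaries.tsv"),
        stages = file.path(outDir, "stage_comparison.tsv"),
        regions = file.path(outDir, "region_report.tsv"),
        phases = file.path(outDir, "phase_assignments.tsv"),
        lesions = file.path(outDir, "lesion_report.tsv"),
        venn = file.path(outDir, "venn_cells.tsv"),
        report = file.path(outDir, "report.tsv"))
    exportCorpus(res$corpus, exports["corpus"])
    .writeExport(res$summaries, exports["summaries"])
    .writeExport(res$stages, exports["stages"])
    .writeExport(res$regions, exports["regions"])
    .writeExport(res$phases, exports["phases"])
    .writeExport(res$lesions, exports["lesions"])
    vennRows <- do.call(rbind, lapply(names(res$venn), function(status)
        do.call(rbind, lapply(names(res$venn[[status]]), function(cellName) {
            g <- res$venn[[status]][[cellName]]
            if (length(g) == 0L) return(NULL)
            data.frame(status = status, cell = cellName, gene_id = g,
                       stringsAsFactors = FALSE)
        }))))
    if (is.null(vennRows))
        vennRows <- data.frame(status = character(0), cell = character(0),
                               gene_id = character(0))
    .writeExport(vennRows, exports["venn"])
    .writeExport(data.frame(key = names(res$report),
                            value = unname(res$report)),
                 exports["report"])
    message("pipeline complete: ", res$report[["n_records"]],
            " records, ", res$report[["n_significant_genes"]],
            " significant genes; exports in ", outDir)
    res$exports <- exports
    invisible(res)
}
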