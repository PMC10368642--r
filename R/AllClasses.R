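#' Controlled vocabularies used throughout the package
#'
#' Brain regions, clinical stages, sample types and significance schemes
#' recognised in comparison metadata, plus the literature-consensus split of
#' regions into neuropathology-vulnerable and neuropathology-resistant
#' classes. The ventricle wall is deliberately in neither class: too little
#' is known about its pathology burden to place it, so it is excluded from
#' the region-vulnerability analysis.
#'
#' @name vocabularies
#' @keywords internal
NULL

#' @rdname vocabularies
#' @export
brainRegions <- function() {
    c("frontal cortex", "hippocampus", "parahippocampal cortex",
      "entorhinal cortex", "temporal cortex", "parietal cortex",
      "cingulate gyrus", "precuneus", "motor cortex", "sensory cortex",
      "occipital cortex", "ventricle wall", "cerebellum")
}

#' @rdname vocabularies
#' @export
vulnerableRegions <- function() {
    c("entorhinal cortex", "hippocampus", "parahippocampal cortex",
      "temporal cortex", "frontal cortex", "parietal cortex", "precuneus",
      "cingulate gyrus", "occipital cortex")
}

#' @rdname vocabularies
#' @export
resistantRegions <- function() {
    c("sensory cortex", "motor cortex", "cerebellum")
}

#' @rdname vocabularies
#' @export
clinicalStages <- function() {
    c("preclinical", "MCI", "advanced", "not_applicable")
}

#' @rdname vocabularies
#' @export
sampleTypes <- function() {
    c("bulk", "plaque", "NFT", "CAA")
}

#' @rdname vocabularies
#' @export
depSchemes <- function() {
    c("FDR5", "FC_AND_P", "ANOVA_POSTHOC", "KRUSKAL_WALLIS",
      "PRESENCE_CASES", "LESION_FC")
}

.LESION_SCHEMES <- c("PRESENCE_CASES", "LESION_FC")
.LESION_TYPES <- c("plaque", "NFT", "CAA")

.META_COLUMNS <- c("comparison_id", "publication_id", "brain_region",
                   "clinical_stage", "tissue_fraction", "sample_type",
                   "dep_scheme", "region_class")

.RECORD_COLUMNS <- c("comparison_id", "gene_id", "uniprot_id", "direction",
                     "fold_change", "p_value", "fdr", "n_peptides",
                     "case_presence")

.CORPUS_ASSAYS <- c("direction", "foldChange", "pValue", "fdr",
                    "nPeptides", "casePresence", "isDEP")

#' Numeric rule constants of the meta-analysis
#'
#' Holds every numeric threshold the classification rules use: the minimum
#' number of supporting bulk-tissue comparisons (\code{minStudies}, k = 5),
#' the number of discordant reports tolerated by the one-outlier rule
#' (\code{outlierAllowance}, m = 1), the fold-change cutoff on the linear
#' ratio scale (\code{fcCutoff}, 1.5), the p-value and FDR cutoffs, the
#' minimum number of cases a protein must be detected in for lesion
#' presence calls (\code{presenceMinCases}, 3), the score cutoff for the
#' most-consistent protein set (\code{topSetCutoff}, 15), and the minimum
#' peptide support per protein (\code{minPeptides}, 2; single-peptide
#' identifications are excluded).
#'
#' @slot minStudies integer, minimum comparisons for a consistency call.
#' @slot outlierAllowance integer, discordant reports tolerated (< minStudies).
#' @slot fcCutoff numeric ratio > 1, strict fold-change cutoff.
#' @slot alpha numeric, p-value cutoff.
#' @slot fdrCutoff numeric, FDR cutoff.
#' @slot presenceMinCases integer, minimum cases for lesion presence.
#' @slot topSetCutoff integer, score cutoff for the top protein set.
#' @slot minPeptides integer, minimum peptides per retained protein.
#'
#' @seealso [analysisThresholds()]
#' @export
setClass("AnalysisThresholds",
    representation(
        minStudies = "integer",
        outlierAllowance = "integer",
        fcCutoff = "numeric",
        alpha = "numeric",
        fdrCutoff = "numeric",
        presenceMinCases = "integer",
        topSetCutoff = "integer",
        minPeptides = "integer"
    )
)

setValidity("AnalysisThresholds", function(object) {
    msg <- character()
    num <- c(minStudies = object@minStudies,
             outlierAllowance = object@outlierAllowance,
             fcCutoff = object@fcCutoff,
             alpha = object@alpha,
             fdrCutoff = object@fdrCutoff,
             presenceMinCases = object@presenceMinCases,
             topSetCutoff = object@topSetCutoff,
             minPeptides = object@minPeptides)
    if (any(!is.finite(num)) || any(num <= 0))
        msg <- c(msg, "all thresholds must be finite and strictly positive")
    if (length(msg) == 0L && object@outlierAllowance >= object@minStudies)
        msg <- c(msg, "outlierAllowance must be smaller than minStudies")
    if (length(msg) == 0L && object@fcCutoff <= 1)
        msg <- c(msg, "fcCutoff is a linear ratio and must exceed 1")
    if (length(msg) == 0L &&
        (object@alpha > 1 || object@fdrCutoff > 1))
        msg <- c(msg, "alpha and fdrCutoff are probabilities in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Construct an AnalysisThresholds object
#'
#' @param minStudies minimum bulk comparisons (k) before a consistency
#'   class is assigned; below it a protein is "insufficient".
#' @param outlierAllowance discordant reports (m) tolerated by the
#'   one-outlier rule once \code{minStudies} is reached.
#' @param fcCutoff strict fold-change cutoff on the linear ratio scale;
#'   1/\code{fcCutoff} bounds depletion symmetrically.
#' @param alpha p-value cutoff for schemes that combine p with fold change.
#' @param fdrCutoff FDR cutoff for the FDR-controlled scheme.
#' @param presenceMinCases minimum cases a protein must appear in for a
#'   lesion presence call.
#' @param topSetCutoff score cutoff defining the most-consistent protein set.
#' @param minPeptides minimum peptides per protein; rows below are dropped.
#'
#' @return An [AnalysisThresholds-class] object.
#' @examples
#' th <- analysisThresholds()
#' minStudies(th)
#' @export
analysisThresholds <- function(minStudies = 5L, outlierAllowance = 1L,
                               fcCutoff = 1.5, alpha = 0.05,
                               fdrCutoff = 0.05, presenceMinCases = 3L,
                               topSetCutoff = 15L, minPeptides = 2L) {
    new("AnalysisThresholds",
        minStudies = as.integer(minStudies),
        outlierAllowance = as.integer(outlierAllowance),
        fcCutoff = as.numeric(fcCutoff),
        alpha = as.numeric(alpha),
        fdrCutoff = as.numeric(fdrCutoff),
        presenceMinCases = as.integer(presenceMinCases),
        topSetCutoff = as.integer(topSetCutoff),
        minPeptides = as.integer(minPeptides))
}

#' Corpus of harmonized protein-change reports
#'
#' A \linkS4class{SummarizedExperiment} whose rows are gene symbols, whose
#' columns are study comparisons (one publication x brain region x clinical
#' stage x tissue fraction combination), and whose assays carry the per
#' (gene, comparison) report: reported direction (+1/-1), linear fold
#' change, p-value, FDR, peptide count, lesion case-presence count, and the
#' differential-expression call made under the comparison's significance
#' scheme. Cells with no report are NA in every assay. Comparison metadata
#' lives in \code{colData}; the rule constants in
#' \code{metadata(x)$thresholds}.
#'
#' Build one with [buildCorpus()]; recover the long record table with
#' [corpusRecords()].
#'
#' @seealso [buildCorpus()], [corpusRecords()], [callDEP()]
#' @export
setClass("ProteinCorpus", contains = "SummarizedExperiment")

setValidity("ProteinCorpus", function(object) {
    msg <- character()
    an <- SummarizedExperiment::assayNames(object)
    missing <- setdiff(.CORPUS_ASSAYS, an)
    if (length(missing))
        msg <- c(msg, paste("missing assays:", paste(missing, collapse = ", ")))
    cd <- SummarizedExperiment::colData(object)
    missingCols <- setdiff(setdiff(.META_COLUMNS, "comparison_id"),
                           colnames(cd))
    if (length(missingCols))
        msg <- c(msg, paste("missing colData columns:",
                            paste(missingCols, collapse = ", ")))
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "comparison_id (colnames) must be unique")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene_id (rownames) must be unique")
    if (length(msg) == 0L && ncol(object) > 0L) {
        lesionSample <- cd$sample_type %in% .LESION_TYPES
        lesionScheme <- cd$dep_scheme %in% .LESION_SCHEMES
        if (!all(lesionSample == lesionScheme))
            msg <- c(msg, paste("lesion sample types (plaque/NFT/CAA) must",
                                "pair with lesion schemes",
                                "(PRESENCE_CASES/LESION_FC) and vice versa"))
        vw <- cd$brain_region == "ventricle wall"
        if (any(vw & cd$region_class != "unassigned"))
            msg <- c(msg, "ventricle wall comparisons must have region_class 'unassigned'")
        if (!all(cd$brain_region %in% brainRegions()))
            msg <- c(msg, "unknown brain_region in colData")
        if (!all(cd$clinical_stage %in% clinicalStages()))
            msg <- c(msg, "unknown clinical_stage in colData")
        if (!all(cd$sample_type %in% sampleTypes()))
            msg <- c(msg, "unknown sample_type in colData")
        if (!all(cd$dep_scheme %in% depSchemes()))
            msg <- c(msg, "unknown dep_scheme in colData")
    }
    if (length(msg) == 0L && nrow(object) > 0L && ncol(object) > 0L) {
        dir <- SummarizedExperiment::assay(object, "direction")
        fc <- SummarizedExperiment::assay(object, "foldChange")
        both <- !is.na(dir) & !is.na(fc) & fc != 1
        if (any(sign(fc[both] - 1) != dir[both]))
            msg <- c(msg, "direction must agree with fold_change where both present")
        th <- S4Vectors::metadata(object)$thresholds
        if (is.null(th) || !methods::is(th, "AnalysisThresholds"))
            msg <- c(msg, "metadata(x)$thresholds must hold an AnalysisThresholds object")
        up <- SummarizedExperiment::rowData(object)$uniprot_id
        if (!is.null(up) && any(grepl("-[0-9]+$", up[!is.na(up)])))
            msg <- c(msg, "uniprot ids must be isoform-stripped")
    }
    if (length(msg)) msg else TRUE
})
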