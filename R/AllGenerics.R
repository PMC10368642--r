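#' @import methods
#' @importFrom stats p.adjust rbinom rlnorm rpois runif rnorm t.test
#'   setNames aggregate
#' @importFrom utils read.delim write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors metadata DataFrame
NULL

#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @export
setGeneric("thresholds<-", function(x, value) standardGeneric("thresholds<-"))

#' @export
setGeneric("comparisonMeta", function(x) standardGeneric("comparisonMeta"))

#' @export
setGeneric("corpusRecords", function(x, ...) standardGeneric("corpusRecords"))

#' @export
setGeneric("callDEP", function(x, ...) standardGeneric("callDEP"))

#' @export
setGeneric("minStudies", function(x) standardGeneric("minStudies"))

#' @export
setGeneric("outlierAllowance", function(x) standardGeneric("outlierAllowance"))

#' @export
setGeneric("fcCutoff", function(x) standardGeneric("fcCutoff"))

#' Accessors for AnalysisThresholds
#'
#' @param x an [AnalysisThresholds-class] or [ProteinCorpus-class] object
#'   (corpora delegate to the thresholds stored in their metadata).
#' @return The requested threshold value.
#' @name thresholds-accessors
#' @aliases minStudies outlierAllowance fcCutoff
#' @examples
#' minStudies(analysisThresholds())
NULL

#' @rdname thresholds-accessors
#' @export
setMethod("minStudies", "AnalysisThresholds", function(x) x@minStudies)

#' @rdname thresholds-accessors
#' @export
setMethod("outlierAllowance", "AnalysisThresholds",
          function(x) x@outlierAllowance)

#' @rdname thresholds-accessors
#' @export
setMethod("fcCutoff", "AnalysisThresholds", function(x) x@fcCutoff)

#' @describeIn ProteinCorpus-class rule constants stored with the corpus.
#' @param x a ProteinCorpus.
#' @export
setMethod("thresholds", "ProteinCorpus", function(x) {
    S4Vectors::metadata(x)$thresholds
})

#' @describeIn ProteinCorpus-class replace the stored rule constants.
#' @param value an AnalysisThresholds object.
#' @export
setMethod("thresholds<-", "ProteinCorpus", function(x, value) {
    stopifnot(methods::is(value, "AnalysisThresholds"))
    S4Vectors::metadata(x)$thresholds <- value
    methods::validObject(x)
    x
})

#' @describeIn ProteinCorpus-class comparison metadata as a data.frame
#'   (one row per comparison, including \code{comparison_id}).
#' @export
setMethod("comparisonMeta", "ProteinCorpus", function(x) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    data.frame(comparison_id = colnames(x), cd, row.names = NULL,
               stringsAsFactors = FALSE)
})

setMethod("show", "AnalysisThresholds", function(object) {
    cat("AnalysisThresholds\n")
    cat("  minStudies (k):       ", object@minStudies, "\n")
    cat("  outlierAllowance (m): ", object@outlierAllowance, "\n")
    cat("  fcCutoff:             ", object@fcCutoff, "\n")
    cat("  alpha:                ", object@alpha, "\n")
    cat("  fdrCutoff:            ", object@fdrCutoff, "\n")
    cat("  presenceMinCases:     ", object@presenceMinCases, "\n")
    cat("  topSetCutoff:         ", object@topSetCutoff, "\n")
    cat("  minPeptides:          ", object@minPeptides, "\n")
})

setMethod("show", "ProteinCorpus", function(object) {
    cd <- SummarizedExperiment::colData(object)
    nRec <- sum(!is.na(SummarizedExperiment::assay(object, "direction")) |
                !is.na(SummarizedExperiment::assay(object, "casePresence")))
    cat("ProteinCorpus:", nrow(object), "genes x", ncol(object),
        "comparisons;", nRec, "protein-change records\n")
    if (ncol(object)) {
        cat("  sample types: ",
            paste(sprintf("%s (%d)", names(table(cd$sample_type)),
                          table(cd$sample_type)), collapse = ", "), "\n")
        cat("  stages:       ",
            paste(sprintf("%s (%d)", names(table(cd$clinical_stage)),
                          table(cd$clinical_stage)), collapse = ", "), "\n")
    }
    dl <- S4Vectors::metadata(object)$dropLog
    if (!is.null(dl) && sum(unlist(dl)) > 0)
        cat("  harmonization drops:", sum(unlist(dl)), "rows\n")
})
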