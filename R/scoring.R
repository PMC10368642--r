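#' Tally DEP directions per gene (and optional context columns)
#'
#' Internal workhorse shared by the bulk-consistency, per-stage and
#' per-region analyses. Each counting unit is either one comparison
#' (default, matching the rule that every publication x region x stage x
#' fraction combination counts once) or one publication (config
#' alternative); under publication counting a publication contributes the
#' net sign of its comparisons' directions, and drops out if they cancel.
#'
#' @noRd
.directionTally <- function(dep, groupCols = "gene_id",
                            countBy = c("comparison", "publication")) {
    countBy <- match.arg(countBy)
    empty <- data.frame(setNames(rep(list(character(0)), length(groupCols)),
                                 groupCols),
                        n_up = integer(0), n_down = integer(0),
                        stringsAsFactors = FALSE)
    if (is.null(dep) || nrow(dep) == 0L) return(empty)
    dep <- dep[!is.na(dep$direction), , drop = FALSE]
    if (nrow(dep) == 0L) return(empty)
    unit <- if (countBy == "publication") dep$publication_id
            else dep$comparison_id
    df <- data.frame(dep[groupCols], .unit = unit,
                     direction = dep$direction, stringsAsFactors = FALSE)
    net <- aggregate(direction ~ ., data = df,
                     FUN = function(d) sign(sum(d)))
    net <- net[net$direction != 0L, , drop = FALSE]
    if (nrow(net) == 0L) return(empty)
    out <- aggregate(list(n_up = net$direction == 1L,
                          n_down = net$direction == -1L),
                     by = net[, groupCols, drop = FALSE], FUN = sum)
    out$n_up <- as.integer(out$n_up)
    out$n_down <- as.integer(out$n_down)
    out[do.call(order, out[groupCols]), , drop = FALSE]
}

#' Classify bulk-tissue directional consistency
#'
#' Vote-count rule with a one-outlier allowance: a protein reported as a
#' DEP in fewer than \code{minStudies} bulk comparisons is
#' \code{insufficient}; at or above that floor it is \code{increased} or
#' \code{decreased} when at most \code{outlierAllowance} reports go the
#' other way, and \code{inconsistent} otherwise (two or more outliers).
#' The result depends only on the tally, so it is invariant to comparison
#' ordering.
#'
#' @param nUp,nDown integer vectors: comparisons reporting the protein up,
#'   resp. down.
#' @param thresholds an [AnalysisThresholds-class].
#' @return A factor with levels increased, decreased, inconsistent,
#'   insufficient.
#' @examples
#' classifyDirection(c(5, 5, 4, 3), c(0, 8, 1, 0))
#' @export
classifyDirection <- function(nUp, nDown,
                              thresholds = analysisThresholds()) {
    nUp <- as.integer(nUp); nDown <- as.integer(nDown)
    stopifnot(length(nUp) == length(nDown), all(nUp >= 0), all(nDown >= 0))
    n <- nUp + nDown
    cls <- rep("insufficient", length(n))
    enough <- n >= thresholds@minStudies
    cls[enough] <- "inconsistent"
    consistent <- enough & pmin(nUp, nDown) <= thresholds@outlierAllowance &
        nUp != nDown
    cls[consistent & nUp > nDown] <- "increased"
    cls[consistent & nDown > nUp] <- "decreased"
    factor(cls, levels = c("increased", "decreased", "inconsistent",
                           "insufficient"))
}

#' Per-gene vote-count scores and bulk consistency classes
#'
#' Computes, for every gene in the corpus, the overall score (number of
#' comparisons in which the gene was called a DEP, bulk and lesion alike),
#' the bulk-tissue-only score, the bulk up/down tally and its consistency
#' class under [classifyDirection()].
#'
#' @param x a [ProteinCorpus-class] with DEP calls ([callDEP()]).
#' @param countBy count unique comparisons (default) or collapse to unique
#'   publications.
#' @return A data.frame sorted by gene: \code{gene_id},
#'   \code{uniprot_id}, \code{neuropro_score}, \code{bulk_score},
#'   \code{bulk_up}, \code{bulk_down}, \code{bulk_class}.
#' @export
computeScores <- function(x, countBy = c("comparison", "publication")) {
    countBy <- match.arg(countBy)
    th <- thresholds(x)
    genes <- rownames(x)
    uni <- SummarizedExperiment::rowData(x)$uniprot_id
    if (is.null(uni)) uni <- rep(NA_character_, length(genes))
    zero <- rep(0L, length(genes))
    out <- data.frame(
        gene_id = genes, uniprot_id = uni,
        neuropro_score = zero, bulk_score = zero,
        bulk_up = zero, bulk_down = zero,
        stringsAsFactors = FALSE)
    rec <- corpusRecords(x, withMeta = TRUE, depOnly = TRUE)
    if (nrow(rec)) {
        unit <- if (countBy == "publication") rec$publication_id
                else rec$comparison_id
        tab <- tapply(unit, rec$gene_id, function(z) length(unique(z)))
        out$neuropro_score[match(names(tab), out$gene_id)] <- as.integer(tab)
        bulk <- rec[rec$sample_type == "bulk", , drop = FALSE]
        bunit <- if (countBy == "publication") bulk$publication_id
                 else bulk$comparison_id
        if (nrow(bulk)) {
            bt <- tapply(bunit, bulk$gene_id,
                         function(z) length(unique(z)))
            out$bulk_score[match(names(bt), out$gene_id)] <- as.integer(bt)
            tal <- .directionTally(bulk, "gene_id", countBy)
            i <- match(tal$gene_id, out$gene_id)
            out$bulk_up[i] <- tal$n_up
            out$bulk_down[i] <- tal$n_down
        }
    }
    out$bulk_class <- classifyDirection(out$bulk_up, out$bulk_down, th)
    out <- out[order(out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Most consistently identified proteins
#'
#' Genes whose overall score reaches \code{minScore}, ordered by score
#' descending with alphabetical tie-break.
#'
#' @param scores data.frame from [computeScores()].
#' @param minScore score cutoff (default: the \code{topSetCutoff} used for
#'   the most-consistent set, 15).
#' @return Character vector of gene ids.
#' @export
topSet <- function(scores, minScore = 15L) {
    keep <- scores[scores$neuropro_score >= minScore, , drop = FALSE]
    keep <- keep[order(-keep$neuropro_score, keep$gene_id), , drop = FALSE]
    keep$gene_id
}
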