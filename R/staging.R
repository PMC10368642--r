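#' Directional call within one clinical stage (or one brain region)
#'
#' Stricter variant of the consistency rule used inside a single stratum:
#' below \code{minStudies} reports a direction is assigned only when the
#' reports are unanimous; at \code{minStudies} or more, one directional
#' outlier is permitted. A gene passing the rule receives a signed score
#' whose magnitude is the full number of supporting reports (the permitted
#' outlier included) and whose sign is the majority direction; otherwise
#' it is inconsistent within the stratum and gets no score.
#'
#' @param nUp,nDown integer vectors of up/down DEP reports in the stratum.
#' @param thresholds an [AnalysisThresholds-class].
#' @return A data.frame with \code{direction} (+1/-1, NA when no score),
#'   \code{signed_score} (NA when no score) and \code{n} (total reports).
#' @examples
#' stageDirection(c(0, 1, 5), c(3, 2, 1))
#' @export
stageDirection <- function(nUp, nDown, thresholds = analysisThresholds()) {
    nUp <- as.integer(nUp); nDown <- as.integer(nDown)
    stopifnot(length(nUp) == length(nDown), all(nUp >= 0), all(nDown >= 0))
    n <- nUp + nDown
    minority <- pmin(nUp, nDown)
    unanimous <- n >= 1L & minority == 0L
    outlierOK <- n >= thresholds@minStudies &
        minority <= thresholds@outlierAllowance & nUp != nDown
    dir <- ifelse(unanimous | outlierOK,
                  as.integer(sign(nUp - nDown)), NA_integer_)
    data.frame(direction = dir, signed_score = dir * n, n = n)
}

#' Merge preclinical and MCI calls into an early-AD call
#'
#' Early AD is defined as either preclinical AD or MCI: if only one
#' sub-stage carries a direction, it is adopted; if both agree, the signed
#' scores add; if they conflict, the merged early call is withheld (no
#' score) and the conflict flagged.
#'
#' @param preclinicalScore,mciScore signed stage scores (NA = no score).
#' @return A data.frame with \code{early_score}, \code{early_direction}
#'   and \code{early_conflict}.
#' @examples
#' earlyDirection(c(5, 5, 5, NA), c(NA, 2, -1, NA))
#' @export
earlyDirection <- function(preclinicalScore, mciScore) {
    p <- as.numeric(preclinicalScore); m <- as.numeric(mciScore)
    stopifnot(length(p) == length(m))
    conflict <- !is.na(p) & !is.na(m) & sign(p) != sign(m)
    score <- ifelse(conflict, NA_real_,
                    ifelse(is.na(p), m, ifelse(is.na(m), p, p + m)))
    data.frame(early_score = score,
               early_direction = ifelse(is.na(score), NA_integer_,
                                        as.integer(sign(score))),
               early_conflict = conflict)
}

#' Per-stage signed scores for every gene
#'
#' Tallies bulk-tissue DEP reports within each clinical stage, applies
#' [stageDirection()] per stage, and merges preclinical and MCI into the
#' early-AD group via [earlyDirection()].
#'
#' @param x a [ProteinCorpus-class] with DEP calls.
#' @param countBy counting unit, as in [computeScores()].
#' @return A data.frame, one row per gene with a DEP report in at least
#'   one stage: signed scores and tally sizes per stage, plus the merged
#'   early columns.
#' @export
stageScores <- function(x, countBy = c("comparison", "publication")) {
    countBy <- match.arg(countBy)
    th <- thresholds(x)
    rec <- corpusRecords(x, withMeta = TRUE, depOnly = TRUE)
    bulk <- rec[rec$sample_type == "bulk" &
                rec$clinical_stage %in% c("preclinical", "MCI", "advanced"),
                , drop = FALSE]
    tal <- .directionTally(bulk, c("gene_id", "clinical_stage"), countBy)
    genes <- sort(unique(tal$gene_id))
    out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
    for (st in c("preclinical", "MCI", "advanced")) {
        sub <- tal[tal$clinical_stage == st, , drop = FALSE]
        sd <- stageDirection(sub$n_up, sub$n_down, th)
        i <- match(sub$gene_id, genes)
        scoreCol <- paste0(tolower(st), "_score")
        nCol <- paste0(tolower(st), "_n")
        out[[scoreCol]] <- NA_real_
        out[[nCol]] <- 0L
        out[[scoreCol]][i] <- sd$signed_score
        out[[nCol]][i] <- sd$n
    }
    em <- earlyDirection(out$preclinical_score, out$mci_score)
    cbind(out, em)
}

#' Categorize genes by early-stage vs advanced behaviour
#'
#' High-confidence advanced calls require at least \code{minStudies}
#' advanced bulk reports (one outlier permitted). Genes altered in the
#' same direction early and in high-confidence advanced are proposed
#' early-AD changes; genes with a high-confidence advanced call but no
#' early direction are advanced-only changes; opposite directions (or an
#' early direction with no advanced direction at all) are opposite
#' changes; everything else scored in at least one stage is unable to
#' group.
#'
#' @param stages data.frame from [stageScores()].
#' @param thresholds an [AnalysisThresholds-class].
#' @return `stages` with columns \code{advanced_hc_direction} and
#'   \code{stage_category} (factor: early_AD_change, advanced_only_change,
#'   opposite_change, unable_to_group) appended.
#' @export
compareStages <- function(stages, thresholds = analysisThresholds()) {
    e <- stages$early_direction
    aScore <- stages$advanced_score
    aDir <- ifelse(is.na(aScore), NA_integer_, as.integer(sign(aScore)))
    aHC <- ifelse(!is.na(aScore) & abs(aScore) >= thresholds@minStudies,
                  aDir, NA_integer_)
    cat <- rep("unable_to_group", nrow(stages))
    cat[!is.na(e) & !is.na(aHC) & e == aHC] <- "early_AD_change"
    cat[is.na(e) & !is.na(aHC)] <- "advanced_only_change"
    cat[!is.na(e) & !is.na(aHC) & e != aHC] <- "opposite_change"
    cat[!is.na(e) & is.na(aDir)] <- "opposite_change"  # early-only change
    stages$advanced_hc_direction <- aHC
    stages$stage_category <- factor(cat, levels = c(
        "early_AD_change", "advanced_only_change", "opposite_change",
        "unable_to_group"))
    stages
}
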