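#' Per-region signed scores and combined vulnerability scores
#'
#' Restricted to advanced-AD bulk comparisons, tallies DEP reports within
#' each brain region, applies the within-stratum rule of
#' [stageDirection()] (unanimity below \code{minStudies}, one outlier at
#' or above it), and sums the resulting signed region scores over the
#' vulnerable and resistant region classes. Ventricle-wall comparisons
#' (region class unassigned) contribute to neither combined score. A
#' region whose reports conflict contributes nothing.
#'
#' @param x a [ProteinCorpus-class] with DEP calls.
#' @param countBy counting unit, as in [computeScores()].
#' @return A data.frame, one row per gene with an advanced bulk DEP
#'   report: one signed-score column per scored region (NA where no score),
#'   \code{combined_vulnerable}, \code{combined_resistant}, sign-mixture
#'   flags \code{vulnerable_mixed} / \code{resistant_mixed}, and the
#'   supporting comparison counts \code{n_vulnerable} / \code{n_resistant}.
#' @export
regionScores <- function(x, countBy = c("comparison", "publication")) {
    countBy <- match.arg(countBy)
    th <- thresholds(x)
    rec <- corpusRecords(x, withMeta = TRUE, depOnly = TRUE)
    adv <- rec[rec$sample_type == "bulk" &
               rec$clinical_stage == "advanced", , drop = FALSE]
    tal <- .directionTally(adv, c("gene_id", "brain_region"), countBy)
    genes <- sort(unique(tal$gene_id))
    out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
    regionCols <- character(0)
    for (rg in intersect(brainRegions(), unique(tal$brain_region))) {
        sub <- tal[tal$brain_region == rg, , drop = FALSE]
        sd <- stageDirection(sub$n_up, sub$n_down, th)
        col <- paste0("region_", gsub(" ", "_", rg))
        out[[col]] <- NA_real_
        out[[col]][match(sub$gene_id, genes)] <- sd$signed_score
        regionCols <- c(regionCols, col)
    }
    classOf <- setNames(defaultRegionClass(brainRegions()), brainRegions())
    combine <- function(cls) {
        cols <- regionCols[classOf[gsub("_", " ",
                                        sub("^region_", "", regionCols))] == cls]
        if (length(cols) == 0L)
            return(list(sum = rep(0, nrow(out)),
                        mixed = rep(FALSE, nrow(out)),
                        n = rep(0L, nrow(out))))
        m <- as.matrix(out[, cols, drop = FALSE])
        list(sum = rowSums(m, na.rm = TRUE),
             mixed = apply(m, 1L, function(v) {
                 v <- v[!is.na(v)]
                 length(unique(sign(v))) > 1L
             }),
             n = as.integer(rowSums(abs(m), na.rm = TRUE)))
    }
    v <- combine("vulnerable")
    r <- combine("resistant")
    out$combined_vulnerable <- v$sum
    out$combined_resistant <- r$sum
    out$vulnerable_mixed <- v$mixed
    out$resistant_mixed <- r$mixed
    out$n_vulnerable <- v$n
    out$n_resistant <- r$n
    out
}

#' Assign the seven vulnerability categories
#'
#' High-confidence protein changes are those whose combined vulnerable
#' region score reaches \code{minStudies} in magnitude (default), or --
#' under the \code{"count"} alternative -- those supported by at least
#' \code{minStudies} scored vulnerable-region comparisons. High-confidence
#' genes are placed in one of seven categories from the signs of the
#' combined vulnerable and resistant scores; genes whose scored regions
#' disagree in sign within a class are \code{inconsistent}. A zero (or
#' absent) resistant score reads as "unchanged in resistant regions".
#'
#' @param regions data.frame from [regionScores()].
#' @param thresholds an [AnalysisThresholds-class].
#' @param highConfidence \code{"signed"} (|combined vulnerable score| >=
#'   minStudies) or \code{"count"} (supporting vulnerable comparisons >=
#'   minStudies).
#' @return `regions` with \code{vulnerability_category} appended (factor:
#'   the seven categories plus not_high_confidence).
#' @examples
#' rs <- data.frame(gene_id = "A", combined_vulnerable = 6,
#'                  combined_resistant = 0, vulnerable_mixed = FALSE,
#'                  resistant_mixed = FALSE, n_vulnerable = 6L,
#'                  n_resistant = 0L)
#' classifyVulnerability(rs)$vulnerability_category
#' @export
classifyVulnerability <- function(regions,
                                  thresholds = analysisThresholds(),
                                  highConfidence = c("signed", "count")) {
    highConfidence <- match.arg(highConfidence)
    k <- thresholds@minStudies
    hc <- if (highConfidence == "signed")
        abs(regions$combined_vulnerable) >= k
    else regions$n_vulnerable >= k
    vs <- sign(regions$combined_vulnerable)
    rs <- sign(regions$combined_resistant)
    mixed <- regions$vulnerable_mixed | regions$resistant_mixed
    cat <- rep("not_high_confidence", nrow(regions))
    cat[hc & mixed] <- "inconsistent"
    ok <- hc & !mixed
    cat[ok & vs > 0 & rs == 0] <- "inc_vuln_only"
    cat[ok & vs < 0 & rs == 0] <- "dec_vuln_only"
    cat[ok & vs > 0 & rs > 0] <- "inc_both"
    cat[ok & vs < 0 & rs < 0] <- "dec_both"
    cat[ok & vs > 0 & rs < 0] <- "inc_vuln_dec_res"
    cat[ok & vs < 0 & rs > 0] <- "dec_vuln_inc_res"
    cat[ok & vs == 0] <- "inconsistent"  # cancelled signs within the class
    regions$vulnerability_category <- factor(cat, levels = c(
        "inc_vuln_only", "dec_vuln_only", "inc_both", "dec_both",
        "inc_vuln_dec_res", "dec_vuln_inc_res", "inconsistent",
        "not_high_confidence"))
    regions
}
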