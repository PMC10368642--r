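#' Assign each gene to one of the three temporal phases
#'
#' Combines the stage and region analyses into the temporal ordering of
#' protein changes: Phase 1 (pre-neuropathology) proteins change in the
#' same direction in resistant brain regions, early-stage AD and advanced
#' AD; Phase 2 (early AD) proteins change in the same direction in early
#' and advanced AD but show no resistant-region direction; Phase 3
#' (advanced AD) proteins change in advanced AD only. Any directional
#' conflict between the three evidence subsets excludes the gene as
#' inconsistent; genes with no qualifying evidence stay unassigned.
#'
#' The advanced direction used here is the high-confidence one (at least
#' \code{minStudies} advanced bulk reports, one outlier permitted); the
#' resistant-region direction requires a coherent sign across scored
#' resistant regions and \code{|combined resistant score| >=
#' minResistant}.
#'
#' @param stages data.frame from [compareStages()].
#' @param regions data.frame from [regionScores()] (with or without
#'   vulnerability categories).
#' @param thresholds an [AnalysisThresholds-class].
#' @param minResistant minimum magnitude of the combined resistant score
#'   for a resistant-region direction (default 1).
#' @return A data.frame with one row per gene appearing in either input:
#'   \code{gene_id}, \code{early_direction}, \code{advanced_direction},
#'   \code{resistant_direction}, \code{phase} (factor:
#'   phase1_pre_neuropathology, phase2_early_AD, phase3_advanced_AD,
#'   excluded_inconsistent, unassigned) and \code{phase_direction}.
#' @export
assignPhases <- function(stages, regions,
                         thresholds = analysisThresholds(),
                         minResistant = 1) {
    genes <- sort(union(stages$gene_id, regions$gene_id))
    si <- match(genes, stages$gene_id)
    ri <- match(genes, regions$gene_id)
    e <- stages$early_direction[si]
    a <- stages$advanced_hc_direction[si]
    if (is.null(stages$advanced_hc_direction))
        stop("run compareStages() before assignPhases()")
    rScore <- regions$combined_resistant[ri]
    rMixed <- regions$resistant_mixed[ri]
    r <- ifelse(!is.na(rScore) & !rMixed & abs(rScore) >= minResistant,
                as.integer(sign(rScore)), NA_integer_)
    conflict <- vapply(seq_along(genes), function(i) {
        d <- c(e[i], a[i], r[i])
        d <- d[!is.na(d)]
        length(unique(d)) > 1L
    }, logical(1L))
    phase <- rep("unassigned", length(genes))
    dir <- rep(NA_integer_, length(genes))
    phase[conflict] <- "excluded_inconsistent"
    ok <- !conflict
    p1 <- ok & !is.na(e) & !is.na(a) & !is.na(r)
    p2 <- ok & !is.na(e) & !is.na(a) & is.na(r)
    p3 <- ok & is.na(e) & !is.na(a) & is.na(r)
    phase[p1] <- "phase1_pre_neuropathology"
    phase[p2] <- "phase2_early_AD"
    phase[p3] <- "phase3_advanced_AD"
    dir[p1] <- a[p1]; dir[p2] <- a[p2]; dir[p3] <- a[p3]
    data.frame(gene_id = genes,
               early_direction = e,
               advanced_direction = a,
               resistant_direction = r,
               phase = factor(phase, levels = c(
                   "phase1_pre_neuropathology", "phase2_early_AD",
                   "phase3_advanced_AD", "excluded_inconsistent",
                   "unassigned")),
               phase_direction = dir,
               stringsAsFactors = FALSE)
}
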