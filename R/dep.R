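#' Welch two-sample t-test on published group values
#'
#' Recomputes significance between disease and control groups when a
#' source study published per-subject values but no test, using an
#' unpaired two-sided t-test with the Welch degrees-of-freedom correction
#' (the variance structure of source studies is unknown, so equal
#' variances are not assumed). Two degenerate cases get conventions: both
#' groups constant with equal means gives t = 0, p = 1; both groups
#' constant with different means gives p = 0.
#'
#' @param disease,control numeric vectors of abundance values (n >= 2
#'   each).
#' @return A list with elements \code{t}, \code{df} and \code{p}.
#' @examples
#' welchTTest(c(2, 3, 4), c(1, 2, 3))
#' @export
welchTTest <- function(disease, control) {
    disease <- as.numeric(disease[!is.na(disease)])
    control <- as.numeric(control[!is.na(control)])
    if (length(disease) < 2L || length(control) < 2L)
        stop("both groups need n >= 2 for a t-test")
    vd <- stats::var(disease)
    vc <- stats::var(control)
    if (vd == 0 && vc == 0) {
        if (mean(disease) == mean(control))
            return(list(t = 0, df = length(disease) + length(control) - 2L,
                        p = 1))
        return(list(t = sign(mean(disease) - mean(control)) * Inf,
                    df = length(disease) + length(control) - 2L, p = 0))
    }
    ht <- t.test(disease, control, var.equal = FALSE,
                 alternative = "two.sided")
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = unname(ht$p.value))
}

#' Linear fold change between group means
#'
#' @param diseaseMean,controlMean positive group means.
#' @return The ratio diseaseMean / controlMean. Satisfies
#'   \code{foldChange(a, b) * foldChange(b, a) == 1}.
#' @examples
#' foldChange(3, 2)
#' @export
foldChange <- function(diseaseMean, controlMean) {
    if (any(!is.finite(diseaseMean)) || any(!is.finite(controlMean)) ||
        any(diseaseMean <= 0) || any(controlMean <= 0))
        stop("fold change needs strictly positive, finite group means")
    diseaseMean / controlMean
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment, returned in the input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted q-values, elementwise >= p, capped at 1.
#' @examples
#' bhFDR(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhFDR <- function(p) {
    p <- as.numeric(p)
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

.depCall <- function(scheme, direction, fold_change, p_value, fdr,
                     case_presence, th) {
    tau <- th@fcCutoff
    switch(scheme,
        FDR5 = ifelse(is.na(fdr), NA, fdr < th@fdrCutoff),
        FC_AND_P = ifelse(is.na(p_value) | is.na(fold_change), NA,
                          p_value < th@alpha &
                          (fold_change > tau | fold_change < 1 / tau)),
        ANOVA_POSTHOC = ,
        KRUSKAL_WALLIS = ifelse(is.na(p_value),
                                # the source study's significance call is
                                # taken as given when no p accompanies it
                                !is.na(direction),
                                p_value < th@alpha),
        PRESENCE_CASES = ifelse(is.na(case_presence), NA,
                                case_presence >= th@presenceMinCases),
        LESION_FC = ifelse(is.na(fold_change), NA,
                           fold_change > tau | fold_change < 1 / tau),
        stop("unknown dep_scheme: ", scheme))
}

#' Apply each comparison's significance scheme
#'
#' Evaluates the per-record differential-expression call under the scheme
#' declared for its comparison, with strict inequalities throughout
#' (fold change must exceed 1.5, or fall below 1/1.5, to count): FDR < 5%
#' (\code{FDR5}); p < alpha together with the fold-change cutoff
#' (\code{FC_AND_P}); the source study's ANOVA-post-hoc or Kruskal-Wallis
#' significance taken as given, gated on p < alpha when a p-value is
#' carried (\code{ANOVA_POSTHOC}, \code{KRUSKAL_WALLIS}); presence in at
#' least \code{presenceMinCases} cases (\code{PRESENCE_CASES}); and the
#' fold-change cutoff alone for lesion-vs-neighbouring-tissue ratios
#' (\code{LESION_FC}). Records lacking the fields their scheme needs are
#' skipped (call stays NA) with one summary warning.
#'
#' @param x a [ProteinCorpus-class].
#' @param ... unused.
#' @return The corpus with its DEP-call assay populated (1 = DEP, 0 = not).
#' @export
setMethod("callDEP", "ProteinCorpus", function(x, ...) {
    th <- thresholds(x)
    a <- function(n) SummarizedExperiment::assay(x, n)
    dir <- a("direction"); fc <- a("foldChange"); p <- a("pValue")
    q <- a("fdr"); cp <- a("casePresence")
    present <- !is.na(dir) | !is.na(cp) | !is.na(fc) | !is.na(p) | !is.na(q)
    isDep <- matrix(NA_real_, nrow(x), ncol(x),
                    dimnames = dimnames(a("direction")))
    scheme <- SummarizedExperiment::colData(x)$dep_scheme
    for (j in seq_len(ncol(x))) {
        call <- .depCall(scheme[j], dir[, j], fc[, j], p[, j], q[, j],
                         cp[, j], th)
        isDep[, j] <- ifelse(present[, j], as.numeric(call), NA_real_)
    }
    skipped <- sum(present & is.na(isDep))
    if (skipped > 0L)
        warning(skipped, " record(s) lacked the fields their scheme ",
                "requires and were skipped (DEP call left NA)")
    SummarizedExperiment::assay(x, "isDEP") <- isDep
    methods::validObject(x)
    x
})

#' Single-record DEP call
#'
#' Convenience scalar form of the scheme rules in [callDEP()].
#'
#' @param record a one-row data.frame or list with any of
#'   \code{direction}, \code{fold_change}, \code{p_value}, \code{fdr},
#'   \code{case_presence}.
#' @param scheme one of [depSchemes()].
#' @param thresholds an [AnalysisThresholds-class].
#' @return A list with \code{is_dep} (logical, NA when the needed field is
#'   absent) and \code{direction} (+1/-1 or NA), the latter taken from the
#'   fold change when available.
#' @examples
#' callDEPRecord(list(p_value = 0.01, fold_change = 1.6), "FC_AND_P")
#' @export
callDEPRecord <- function(record, scheme,
                          thresholds = analysisThresholds()) {
    g <- function(f) {
        v <- record[[f]]
        if (is.null(v) || length(v) == 0L) NA_real_ else as.numeric(v[1L])
    }
    dirIn <- record[["direction"]]
    dirIn <- if (is.null(dirIn) || is.na(dirIn[1L])) NA_integer_
             else as.integer(dirIn[1L])
    fc <- g("fold_change")
    isDep <- .depCall(scheme, dirIn, fc, g("p_value"), g("fdr"),
                      g("case_presence"), thresholds)
    dirOut <- if (!is.na(fc) && fc != 1) as.integer(sign(fc - 1)) else dirIn
    list(is_dep = as.logical(isDep), direction = dirOut)
}
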