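#' Per-lesion status calls for every gene
#'
#' For each lesion type (amyloid plaque, neurofibrillary tangle,
#' CAA-containing blood vessel), a gene is \code{enriched} if any lesion
#' comparison reports a fold change strictly above the cutoff
#' (lesion vs neighbouring control tissue), \code{depleted} if any reports
#' one strictly below its reciprocal, and \code{present} if it was
#' detected in at least \code{presenceMinCases} cases under a
#' presence-scheme study or carried a fold change inside the band.
#' Enrichment calls from different studies of the same lesion are merged
#' by union; should one study report enrichment and another depletion for
#' the same lesion type, the status falls back to \code{present} with a
#' conflict flag (no such case is expected in curated data).
#' Presence-only evidence never promotes a gene into the
#' enriched/depleted sets.
#'
#' @param x a [ProteinCorpus-class] with DEP calls.
#' @return A data.frame, one row per gene with any passing lesion record:
#'   per-lesion status factors (\code{plaque_status}, \code{NFT_status},
#'   \code{CAA_status}; levels enriched, depleted, present, absent) and
#'   conflict flags.
#' @export
lesionStatus <- function(x) {
    th <- thresholds(x)
    tau <- th@fcCutoff
    rec <- corpusRecords(x, withMeta = TRUE)
    les <- rec[rec$sample_type %in% .LESION_TYPES, , drop = FALSE]
    # a fold-change record inside the band is still a lesion-proteome
    # member (present); presence-scheme records must meet the case floor
    les <- les[(les$dep_scheme == "LESION_FC" & !is.na(les$fold_change)) |
               (les$dep_scheme == "PRESENCE_CASES" & !is.na(les$is_dep) &
                les$is_dep), , drop = FALSE]
    genes <- sort(unique(les$gene_id))
    out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
    for (lt in .LESION_TYPES) {
        sub <- les[les$sample_type == lt, , drop = FALSE]
        status <- rep("absent", length(genes))
        conflict <- rep(FALSE, length(genes))
        if (nrow(sub)) {
            enr <- unique(sub$gene_id[!is.na(sub$fold_change) &
                                      sub$fold_change > tau])
            dep <- unique(sub$gene_id[!is.na(sub$fold_change) &
                                      sub$fold_change < 1 / tau])
            pres <- unique(sub$gene_id)  # every passing record implies presence
            both <- intersect(enr, dep)
            status[genes %in% pres] <- "present"
            status[genes %in% setdiff(enr, both)] <- "enriched"
            status[genes %in% setdiff(dep, both)] <- "depleted"
            conflict[genes %in% both] <- TRUE
        }
        out[[paste0(lt, "_status")]] <-
            factor(status, levels = c("enriched", "depleted", "present",
                                      "absent"))
        out[[paste0(lt, "_conflict")]] <- conflict
    }
    out
}

#' Gene sets with a given status per lesion type
#'
#' @param status data.frame from [lesionStatus()].
#' @param which \code{"enriched"}, \code{"depleted"} or \code{"present"}
#'   (presence includes enriched/depleted genes, which are by definition
#'   present).
#' @return Named list of character vectors (plaque, NFT, CAA).
#' @export
lesionSets <- function(status, which = c("enriched", "depleted",
                                         "present")) {
    which <- match.arg(which)
    out <- lapply(.LESION_TYPES, function(lt) {
        s <- status[[paste0(lt, "_status")]]
        keep <- if (which == "present") s != "absent" else s == which
        sort(status$gene_id[keep])
    })
    names(out) <- .LESION_TYPES
    out
}

#' Disjoint three-set overlap partition
#'
#' Splits the union of three gene sets into the seven disjoint cells of a
#' three-set Venn diagram, with genes sorted within each cell.
#'
#' @param setA,setB,setC character vectors.
#' @param labels names for the three sets (used in the cell names).
#' @return Named list of seven character vectors: \code{A_only},
#'   \code{B_only}, \code{C_only}, \code{A_B}, \code{A_C}, \code{B_C},
#'   \code{A_B_C} with A/B/C replaced by `labels`.
#' @examples
#' vennPartition(c("A", "B", "C"), c("B", "C", "D"), "C")
#' @export
vennPartition <- function(setA, setB, setC,
                          labels = c("A", "B", "C")) {
    A <- unique(as.character(setA)); B <- unique(as.character(setB))
    C <- unique(as.character(setC))
    u <- sort(union(union(A, B), C))
    inA <- u %in% A; inB <- u %in% B; inC <- u %in% C
    cell <- function(a, b, c) sort(u[inA == a & inB == b & inC == c])
    out <- list(cell(TRUE, FALSE, FALSE), cell(FALSE, TRUE, FALSE),
                cell(FALSE, FALSE, TRUE), cell(TRUE, TRUE, FALSE),
                cell(TRUE, FALSE, TRUE), cell(FALSE, TRUE, TRUE),
                cell(TRUE, TRUE, TRUE))
    names(out) <- c(paste0(labels[1L], "_only"), paste0(labels[2L], "_only"),
                    paste0(labels[3L], "_only"),
                    paste(labels[1L], labels[2L], sep = "_"),
                    paste(labels[1L], labels[3L], sep = "_"),
                    paste(labels[2L], labels[3L], sep = "_"),
                    paste(labels[1L], labels[2L], labels[3L], sep = "_"))
    out
}

#' Cross-tabulate a lesion gene set against bulk-tissue classes
#'
#' Answers how lesion-associated proteins behave in bulk tissue: each gene
#' of the lesion set is assigned to exactly one of increased, decreased,
#' inconsistent (consistency classes from [computeScores()]) or unaltered
#' (fewer than \code{minStudies} bulk reports, or absent from bulk
#' altogether). Counts sum to the lesion-set size.
#'
#' @param lesionSet character vector of gene ids.
#' @param scores data.frame from [computeScores()].
#' @return Named integer vector: increased, decreased, inconsistent,
#'   unaltered.
#' @export
bulkCrosstab <- function(lesionSet, scores) {
    lesionSet <- unique(as.character(lesionSet))
    cls <- as.character(scores$bulk_class[match(lesionSet,
                                                scores$gene_id)])
    cls[is.na(cls) | cls == "insufficient"] <- "unaltered"
    out <- c(increased = sum(cls == "increased"),
             decreased = sum(cls == "decreased"),
             inconsistent = sum(cls == "inconsistent"),
             unaltered = sum(cls == "unaltered"))
    out
}
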