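#' Read a comparison-metadata table
#'
#' Reads the TSV describing each study comparison (publication, brain
#' region, clinical stage, tissue fraction, sample type and the statistical
#' scheme its DEP list was produced under). A missing \code{region_class}
#' column is filled from the literature-consensus vulnerable/resistant
#' lists; the ventricle wall is always forced to \code{unassigned}.
#'
#' @param path path to a tab-delimited file with columns
#'   \code{comparison_id}, \code{publication_id}, \code{brain_region},
#'   \code{clinical_stage}, \code{tissue_fraction}, \code{sample_type},
#'   \code{dep_scheme} and optionally \code{region_class}.
#' @return A data.frame of validated comparison metadata.
#' @export
readComparisonMeta <- function(path) {
    meta <- read.delim(path, stringsAsFactors = FALSE,
                       check.names = FALSE, comment.char = "")
    need <- setdiff(.META_COLUMNS, "region_class")
    missing <- setdiff(need, colnames(meta))
    if (length(missing))
        stop("comparison metadata ", path, " lacks column(s): ",
             paste(missing, collapse = ", "))
    if (!"region_class" %in% colnames(meta))
        meta$region_class <- defaultRegionClass(meta$brain_region)
    meta$region_class[meta$brain_region == "ventricle wall"] <- "unassigned"
    validateComparisonMeta(meta)
    meta[, .META_COLUMNS]
}

#' Default vulnerability class for a brain region
#'
#' @param region character vector of region names.
#' @return "vulnerable", "resistant" or "unassigned" per region.
#' @export
defaultRegionClass <- function(region) {
    ifelse(region %in% vulnerableRegions(), "vulnerable",
           ifelse(region %in% resistantRegions(), "resistant", "unassigned"))
}

validateComparisonMeta <- function(meta) {
    if (anyDuplicated(meta$comparison_id))
        stop("comparison_id values must be unique")
    bad <- function(x, ok) unique(x[!x %in% ok])
    b <- bad(meta$brain_region, brainRegions())
    if (length(b)) stop("unknown brain_region: ", paste(b, collapse = ", "))
    b <- bad(meta$clinical_stage, clinicalStages())
    if (length(b)) stop("unknown clinical_stage: ", paste(b, collapse = ", "))
    b <- bad(meta$sample_type, sampleTypes())
    if (length(b)) stop("unknown sample_type: ", paste(b, collapse = ", "))
    b <- bad(meta$dep_scheme, depSchemes())
    if (length(b)) stop("unknown dep_scheme: ", paste(b, collapse = ", "))
    b <- bad(meta$region_class, c("vulnerable", "resistant", "unassigned"))
    if (length(b)) stop("unknown region_class: ", paste(b, collapse = ", "))
    lesionSample <- meta$sample_type %in% .LESION_TYPES
    lesionScheme <- meta$dep_scheme %in% .LESION_SCHEMES
    if (!all(lesionSample == lesionScheme))
        stop("lesion sample types (plaque/NFT/CAA) must pair with lesion ",
             "schemes (PRESENCE_CASES/LESION_FC), and only those")
    invisible(meta)
}

#' Read one per-comparison protein table
#'
#' Reads a delimited protein-change table and maps its columns onto the
#' canonical record fields. Missing numeric cells stay missing (NA), never
#' zero; row order is preserved. Cells that are present but unparseable as
#' numbers raise an error naming the offending line.
#'
#' @param path path to a tab-delimited file with a header.
#' @param columns named character vector or list mapping canonical field
#'   names (\code{gene}, \code{uniprot}, \code{direction},
#'   \code{fold_change}, \code{p_value}, \code{fdr}, \code{n_peptides},
#'   \code{case_presence}) to the file's column names. At least one of
#'   \code{gene}/\code{uniprot} must be mapped and present.
#' @param fcScale \code{"ratio"} if the fold-change column is already a
#'   linear disease/control ratio, \code{"log2"} if it is log2 and must be
#'   exponentiated.
#' @param sep field separator, tab by default.
#' @return A data.frame of raw rows with canonical column names and an
#'   \code{fc_scale} attribute consumed by [harmonizeRecords()].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tacc\tlfc\tp", "GFAP\tP14136\t1.2\t0.001"), f)
#' readProteinTable(f, c(gene = "gene", uniprot = "acc",
#'                       fold_change = "lfc", p_value = "p"),
#'                  fcScale = "log2")
#' @export
readProteinTable <- function(path, columns, fcScale = c("ratio", "log2"),
                             sep = "\t") {
    fcScale <- match.arg(fcScale)
    columns <- unlist(columns)
    raw <- read.delim(path, stringsAsFactors = FALSE, sep = sep,
                      check.names = FALSE, comment.char = "",
                      colClasses = "character")
    idFields <- intersect(c("gene", "uniprot"), names(columns))
    idFields <- idFields[columns[idFields] %in% colnames(raw)]
    if (length(idFields) == 0L)
        stop("schema error in ", path,
             ": no gene or uniprot identifier column found")
    out <- data.frame(row.names = seq_len(nrow(raw)))
    charFields <- c("gene", "uniprot", "direction")
    numFields <- c("fold_change", "p_value", "fdr", "n_peptides",
                   "case_presence")
    for (f in c(charFields, numFields)) {
        col <- if (f %in% names(columns)) columns[[f]] else NA_character_
        if (is.null(col) || is.na(col) || !col %in% colnames(raw)) {
            out[[f]] <- rep(if (f %in% charFields) NA_character_
                            else NA_real_, nrow(raw))
            next
        }
        v <- raw[[col]]
        if (f %in% numFields) {
            blank <- is.na(v) | trimws(v) == "" | toupper(trimws(v)) == "NA"
            num <- suppressWarnings(as.numeric(v))
            badRow <- which(!blank & is.na(num))
            if (length(badRow))
                stop("unparseable numeric value '", v[badRow[1L]],
                     "' in column '", col, "' of ", path,
                     " (line ", badRow[1L] + 1L, ")")
            num[blank] <- NA_real_
            out[[f]] <- num
        } else {
            v[trimws(v) == ""] <- NA_character_
            out[[f]] <- v
        }
    }
    attr(out, "fc_scale") <- fcScale
    out
}

.parseDirection <- function(x) {
    key <- tolower(trimws(as.character(x)))
    up <- c("1", "+1", "up", "increased", "increase", "+")
    down <- c("-1", "down", "decreased", "decrease", "-")
    ifelse(key %in% up, 1L, ifelse(key %in% down, -1L, NA_integer_))
}

#' Harmonize raw protein rows into protein-change records
#'
#' Applies the identifier and filtering rules used to make source studies
#' comparable: multi-valued gene fields are reduced to the first listed
#' symbol and uppercased; UniProt accessions are stripped of isoform
#' suffixes; log2 fold changes are converted to linear ratios; proteins
#' identified by a single peptide are excluded; a missing direction is
#' inferred from the fold change (records with neither are dropped with a
#' warning, except under the lesion presence scheme, which carries no
#' direction); and duplicate gene ids within the comparison are collapsed
#' to the single record with the strongest evidence (smallest p-value, then
#' largest absolute log fold change, then first occurrence).
#'
#' The operation is idempotent and conserves rows: input rows = retained
#' records + drops itemized in the \code{dropLog} attribute.
#'
#' @param raw data.frame from [readProteinTable()] (or any data.frame with
#'   the canonical columns).
#' @param meta a single-row slice of the comparison metadata (or a list
#'   with \code{comparison_id} and \code{dep_scheme}).
#' @param thresholds an [AnalysisThresholds-class] object; only
#'   \code{minPeptides} is used here.
#' @param fcScale fold-change scale of \code{raw}; defaults to the
#'   attribute set by [readProteinTable()], else \code{"ratio"}.
#' @return A data.frame of harmonized records (columns
#'   \code{comparison_id}, \code{gene_id}, \code{uniprot_id},
#'   \code{direction}, \code{fold_change}, \code{p_value}, \code{fdr},
#'   \code{n_peptides}, \code{case_presence}) with a \code{dropLog}
#'   attribute counting rows removed by each rule.
#' @export
harmonizeRecords <- function(raw, meta, thresholds = analysisThresholds(),
                             fcScale = NULL) {
    if (is.null(fcScale))
        fcScale <- attr(raw, "fc_scale") %||% "ratio"
    raw <- as.data.frame(raw)
    # accept both raw-table and already-harmonized column names (idempotence)
    ren <- c(gene_id = "gene", uniprot_id = "uniprot")
    for (i in seq_along(ren))
        if (names(ren)[i] %in% colnames(raw) && !ren[i] %in% colnames(raw))
            colnames(raw)[colnames(raw) == names(ren)[i]] <- ren[i]
    for (f in c("gene", "uniprot", "direction"))
        if (!f %in% colnames(raw)) raw[[f]] <- NA_character_
    for (f in c("fold_change", "p_value", "fdr", "n_peptides",
                "case_presence"))
        if (!f %in% colnames(raw)) raw[[f]] <- NA_real_

    scheme <- if (is.data.frame(meta)) meta$dep_scheme[1L] else meta$dep_scheme
    cid <- if (is.data.frame(meta)) meta$comparison_id[1L] else meta$comparison_id
    drops <- c(unidentifiable = 0L, no_direction = 0L,
               peptide_filter = 0L, duplicate_gene = 0L)

    fc <- as.numeric(raw$fold_change)
    if (identical(fcScale, "log2")) fc <- 2^fc
    gene <- toupper(trimws(vapply(strsplit(as.character(raw$gene), "[;,|]"),
                                  function(x) if (length(x)) x[1L] else NA_character_,
                                  character(1L))))
    gene[gene == "" | gene == "NA"] <- NA_character_
    uni <- toupper(trimws(sub("-[0-9]+$", "", as.character(raw$uniprot))))
    uni[uni == "" | uni == "NA"] <- NA_character_
    gene <- ifelse(is.na(gene), uni, gene)

    dir <- .parseDirection(raw$direction)
    # fold change is authoritative for direction where informative
    hasFC <- !is.na(fc) & fc != 1
    dir[hasFC] <- as.integer(sign(fc[hasFC] - 1))

    rec <- data.frame(comparison_id = cid, gene_id = gene, uniprot_id = uni,
                      direction = dir, fold_change = fc,
                      p_value = as.numeric(raw$p_value),
                      fdr = as.numeric(raw$fdr),
                      n_peptides = as.numeric(raw$n_peptides),
                      case_presence = as.numeric(raw$case_presence),
                      stringsAsFactors = FALSE)

    keep <- !is.na(rec$gene_id)
    drops["unidentifiable"] <- sum(!keep)
    rec <- rec[keep, , drop = FALSE]

    needDir <- !identical(scheme, "PRESENCE_CASES")
    if (needDir) {
        keep <- !is.na(rec$direction)
        drops["no_direction"] <- sum(!keep)
        rec <- rec[keep, , drop = FALSE]
    }

    keep <- is.na(rec$n_peptides) | rec$n_peptides >= thresholds@minPeptides
    drops["peptide_filter"] <- sum(!keep)
    rec <- rec[keep, , drop = FALSE]

    if (nrow(rec)) {
        pKey <- ifelse(is.na(rec$p_value), Inf, rec$p_value)
        fcKey <- ifelse(is.na(rec$fold_change), 0,
                        abs(log(rec$fold_change)))
        ord <- order(rec$gene_id, pKey, -fcKey, seq_len(nrow(rec)))
        rec <- rec[ord, , drop = FALSE]
        dup <- duplicated(rec$gene_id)
        drops["duplicate_gene"] <- sum(dup)
        rec <- rec[!dup, , drop = FALSE]
        rec <- rec[order(rec$gene_id), , drop = FALSE]
    }
    rownames(rec) <- NULL
    if (drops["unidentifiable"] > 0L)
        warning(drops["unidentifiable"], " record(s) in comparison ", cid,
                " had no usable gene or uniprot identifier and were dropped")
    attr(rec, "dropLog") <- as.list(drops)
    rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a ProteinCorpus from metadata and harmonized records
#'
#' Pivots the long record table into a gene x comparison
#' \linkS4class{SummarizedExperiment}, indexing every report by gene and by
#' comparison. Records referencing a comparison absent from the metadata
#' raise a referential-integrity error, as do duplicate (comparison, gene)
#' pairs.
#'
#' @param meta comparison metadata (data.frame as from
#'   [readComparisonMeta()]).
#' @param records a data.frame of harmonized records, or a list of them
#'   (one per comparison) which is row-bound; \code{dropLog} attributes are
#'   summed into the corpus metadata.
#' @param thresholds an [AnalysisThresholds-class] stored with the corpus.
#' @return A [ProteinCorpus-class]. The DEP-call assay is all-NA until
#'   [callDEP()] is run.
#' @examples
#' meta <- data.frame(comparison_id = "C1", publication_id = "P1",
#'                    brain_region = "frontal cortex",
#'                    clinical_stage = "advanced", tissue_fraction = "total",
#'                    sample_type = "bulk", dep_scheme = "FC_AND_P",
#'                    region_class = "vulnerable")
#' rec <- data.frame(comparison_id = "C1", gene_id = "GFAP",
#'                   uniprot_id = "P14136", direction = 1L,
#'                   fold_change = 2, p_value = 0.01, fdr = NA,
#'                   n_peptides = 10, case_presence = NA)
#' buildCorpus(meta, rec)
#' @export
buildCorpus <- function(meta, records, thresholds = analysisThresholds()) {
    validateComparisonMeta(meta)
    dropLog <- list()
    if (is.data.frame(records)) records <- list(records)
    for (r in records) {
        dl <- attr(r, "dropLog")
        if (!is.null(dl))
            for (k in names(dl))
                dropLog[[k]] <- (dropLog[[k]] %||% 0L) + dl[[k]]
    }
    rec <- do.call(rbind, lapply(records, function(r) {
        r <- as.data.frame(r)
        for (f in .RECORD_COLUMNS)
            if (!f %in% colnames(r))
                r[[f]] <- if (f %in% c("comparison_id", "gene_id",
                                       "uniprot_id")) NA_character_
                          else NA_real_
        r[, .RECORD_COLUMNS]
    }))
    if (is.null(rec))
        rec <- as.data.frame(setNames(
            rep(list(character(0)), length(.RECORD_COLUMNS)),
            .RECORD_COLUMNS))
    unknown <- setdiff(unique(rec$comparison_id), meta$comparison_id)
    if (length(unknown))
        stop("records reference unknown comparison_id: ",
             paste(unknown, collapse = ", "))
    key <- paste(rec$comparison_id, rec$gene_id, sep = "\r")
    if (anyDuplicated(key))
        stop("duplicate (comparison_id, gene_id) pairs; run ",
             "harmonizeRecords() per comparison first")

    genes <- sort(unique(rec$gene_id))
    comps <- meta$comparison_id
    mk <- function(v, mode = "numeric") {
        m <- matrix(if (mode == "integer") NA_integer_ else NA_real_,
                    nrow = length(genes), ncol = length(comps),
                    dimnames = list(genes, comps))
        if (nrow(rec))
            m[cbind(match(rec$gene_id, genes),
                    match(rec$comparison_id, comps))] <-
                if (mode == "integer") as.integer(v) else as.numeric(v)
        m
    }
    assays <- list(direction = mk(rec$direction, "integer"),
                   foldChange = mk(rec$fold_change),
                   pValue = mk(rec$p_value),
                   fdr = mk(rec$fdr),
                   nPeptides = mk(rec$n_peptides),
                   casePresence = mk(rec$case_presence),
                   isDEP = mk(rep(NA_real_, nrow(rec))))
    uniByGene <- rep(NA_character_, length(genes))
    if (nrow(rec)) {
        hasUni <- !is.na(rec$uniprot_id)
        first <- rec[hasUni, c("gene_id", "uniprot_id")]
        first <- first[!duplicated(first$gene_id), , drop = FALSE]
        uniByGene[match(first$gene_id, genes)] <- first$uniprot_id
    }
    cd <- S4Vectors::DataFrame(
        meta[, setdiff(.META_COLUMNS, "comparison_id")],
        row.names = comps)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = assays,
        rowData = S4Vectors::DataFrame(uniprot_id = uniByGene,
                                       row.names = genes),
        colData = cd)
    S4Vectors::metadata(se)$thresholds <- thresholds
    S4Vectors::metadata(se)$dropLog <- dropLog
    methods::new("ProteinCorpus", se)
}

#' Long record table of a corpus
#'
#' Reconstructs the one-row-per-protein-change table from the corpus
#' assays, optionally joined with the comparison metadata and restricted
#' to records called as DEPs.
#'
#' @param x a [ProteinCorpus-class].
#' @param withMeta join the comparison metadata columns onto each record.
#' @param depOnly keep only records whose DEP call is TRUE (requires
#'   [callDEP()] to have been run).
#' @param ... unused.
#' @return A data.frame sorted by gene then comparison.
#' @export
setMethod("corpusRecords", "ProteinCorpus",
          function(x, withMeta = FALSE, depOnly = FALSE, ...) {
    a <- function(n) SummarizedExperiment::assay(x, n)
    present <- !is.na(a("direction")) | !is.na(a("casePresence")) |
        !is.na(a("foldChange")) | !is.na(a("pValue")) | !is.na(a("fdr"))
    idx <- which(present, arr.ind = TRUE)
    rec <- data.frame(
        comparison_id = colnames(x)[idx[, 2L]],
        gene_id = rownames(x)[idx[, 1L]],
        uniprot_id = SummarizedExperiment::rowData(x)$uniprot_id[idx[, 1L]],
        direction = a("direction")[idx],
        fold_change = a("foldChange")[idx],
        p_value = a("pValue")[idx],
        fdr = a("fdr")[idx],
        n_peptides = a("nPeptides")[idx],
        case_presence = a("casePresence")[idx],
        is_dep = as.logical(a("isDEP")[idx]),
        stringsAsFactors = FALSE)
    rec <- rec[order(rec$gene_id, rec$comparison_id), , drop = FALSE]
    rownames(rec) <- NULL
    if (depOnly)
        rec <- rec[!is.na(rec$is_dep) & rec$is_dep, , drop = FALSE]
    if (withMeta)
        rec <- merge(rec, comparisonMeta(x), by = "comparison_id",
                     sort = FALSE)
    rec
})

#' Export / import the corpus as a single long TSV
#'
#' The export mirrors the meta-analysis download format: one row per
#' protein-change record with its comparison metadata, sorted by gene then
#' comparison for diff-stability. `importCorpusExport()` ingests such a
#' file back (or a compatible third-party export via a column mapping),
#' reapplying harmonization per comparison.
#'
#' @param x a [ProteinCorpus-class].
#' @param path output (input) TSV path.
#' @return `exportCorpus()` returns `path` invisibly; the import returns a
#'   [ProteinCorpus-class].
#' @export
exportCorpus <- function(x, path) {
    rec <- corpusRecords(x, withMeta = TRUE)
    rec <- rec[, c("gene_id", "uniprot_id", "comparison_id",
                   setdiff(.META_COLUMNS, "comparison_id"),
                   "direction", "fold_change", "p_value", "fdr",
                   "n_peptides", "case_presence")]
    rec <- rec[order(rec$gene_id, rec$comparison_id), , drop = FALSE]
    num <- vapply(rec, is.numeric, logical(1L))
    rec[num] <- lapply(rec[num], signif, digits = 6L)
    write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
    invisible(path)
}

#' @rdname exportCorpus
#' @param columns column mapping from canonical names (the record fields of
#'   [readProteinTable()] plus \code{comparison_id} and the metadata
#'   columns) to the file's column names; defaults to the names
#'   `exportCorpus()` writes.
#' @param fcScale scale of the fold-change column in the file.
#' @param thresholds an [AnalysisThresholds-class] for the rebuilt corpus.
#' @export
importCorpusExport <- function(path, columns = NULL,
                               fcScale = c("ratio", "log2"),
                               thresholds = analysisThresholds()) {
    fcScale <- match.arg(fcScale)
    defaults <- c(comparison_id = "comparison_id",
                  publication_id = "publication_id",
                  brain_region = "brain_region",
                  clinical_stage = "clinical_stage",
                  tissue_fraction = "tissue_fraction",
                  sample_type = "sample_type",
                  dep_scheme = "dep_scheme",
                  region_class = "region_class",
                  gene = "gene_id", uniprot = "uniprot_id",
                  direction = "direction", fold_change = "fold_change",
                  p_value = "p_value", fdr = "fdr",
                  n_peptides = "n_peptides", case_presence = "case_presence")
    columns <- c(unlist(columns),
                 defaults[setdiff(names(defaults), names(columns))])
    tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                      comment.char = "")
    if (!columns[["comparison_id"]] %in% colnames(tab))
        stop("export ", path, " lacks a comparison_id column")
    metaCols <- setdiff(.META_COLUMNS, "comparison_id")
    haveMeta <- all(columns[metaCols] %in% colnames(tab))
    if (!haveMeta)
        stop("export ", path, " lacks comparison metadata column(s): ",
             paste(metaCols[!columns[metaCols] %in% colnames(tab)],
                   collapse = ", "))
    cid <- as.character(tab[[columns[["comparison_id"]]]])
    meta <- unique(data.frame(
        comparison_id = cid,
        publication_id = as.character(tab[[columns[["publication_id"]]]]),
        brain_region = as.character(tab[[columns[["brain_region"]]]]),
        clinical_stage = as.character(tab[[columns[["clinical_stage"]]]]),
        tissue_fraction = as.character(tab[[columns[["tissue_fraction"]]]]),
        sample_type = as.character(tab[[columns[["sample_type"]]]]),
        dep_scheme = as.character(tab[[columns[["dep_scheme"]]]]),
        region_class = as.character(tab[[columns[["region_class"]]]]),
        stringsAsFactors = FALSE))
    if (anyDuplicated(meta$comparison_id))
        stop("inconsistent metadata for one comparison_id in ", path)
    recFields <- c("gene", "uniprot", "direction", "fold_change", "p_value",
                   "fdr", "n_peptides", "case_presence")
    records <- lapply(meta$comparison_id, function(ci) {
        sub <- tab[cid == ci, , drop = FALSE]
        raw <- data.frame(row.names = seq_len(nrow(sub)))
        for (f in recFields) {
            col <- columns[[f]]
            raw[[f]] <- if (!is.null(col) && col %in% colnames(sub))
                sub[[col]]
            else if (f %in% c("gene", "uniprot", "direction")) NA_character_
            else NA_real_
        }
        attr(raw, "fc_scale") <- fcScale
        harmonizeRecords(raw, meta[meta$comparison_id == ci, ], thresholds)
    })
    buildCorpus(meta, records, thresholds)
}
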