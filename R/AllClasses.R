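#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' ProteinEvidence: per-protein spectral counts with peptide support
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' `spectralCounts` assay (proteins x samples, non-negative integers),
#' per-protein peptide support in `rowData` (`nPeptides`, `singlePeptide`,
#' `manuallyValidated`) and sample annotations (at least a `group` column)
#' in `colData`. A spectral count is the number of accepted peptide-spectrum
#' matches assigned to a protein in one sample, the label-free abundance
#' proxy used throughout the discovery stage.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @seealso [assembleProteins()], [collapseEvidence()], [spectralCounts()]
#' @exportClass ProteinEvidence
setClass("ProteinEvidence", contains = "SummarizedExperiment")

setValidity("ProteinEvidence", function(object) {
    msg <- character()
    if (!"spectralCounts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'spectralCounts' is required")
    else {
        sc <- SummarizedExperiment::assay(object, "spectralCounts")
        if (any(sc < 0) || any(sc != round(sc)))
            msg <- c(msg, "spectral counts must be non-negative integers")
    }
    rd <- SummarizedExperiment::rowData(object)
    need <- c("nPeptides", "singlePeptide", "manuallyValidated")
    miss <- setdiff(need, colnames(rd))
    if (length(miss))
        msg <- c(msg, paste("missing rowData column(s):",
                            paste(miss, collapse = ", ")))
    if (!length(msg) && nrow(rd) > 0 &&
        !identical(as.logical(rd$singlePeptide), rd$nPeptides == 1L))
        msg <- c(msg, "singlePeptide must be TRUE exactly when nPeptides == 1")
    if (length(msg)) msg else TRUE
})

#' Construct a ProteinEvidence object
#'
#' @param counts integer matrix of spectral counts, proteins in rows
#'   (rownames are accessions), samples in columns.
#' @param nPeptides integer vector, distinct accepted peptides per protein.
#' @param singlePeptide logical vector; must equal `nPeptides == 1`.
#' @param manuallyValidated logical vector; whether a single-peptide
#'   identification had its spectrum manually validated.
#' @param colData `DataFrame` (or data.frame) of sample annotations; a
#'   `group` column is expected by the differential stage.
#' @return A `ProteinEvidence` object.
#' @examples
#' m <- matrix(c(3L, 0L, 1L, 2L), 2, dimnames = list(c("P1", "P2"), c("s1", "s2")))
#' pe <- ProteinEvidence(m, nPeptides = c(2L, 1L),
#'                       singlePeptide = c(FALSE, TRUE),
#'                       manuallyValidated = c(FALSE, TRUE))
#' spectralCounts(pe)
#' @export
ProteinEvidence <- function(counts, nPeptides,
                            singlePeptide = nPeptides == 1L,
                            manuallyValidated = logical(nrow(counts)),
                            colData = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (is.null(colData)) {
        colData <- S4Vectors::DataFrame(row.names = colnames(counts))
    } else {
        colData <- S4Vectors::DataFrame(colData)
        if (!is.null(rownames(colData)) &&
            all(colnames(counts) %in% rownames(colData)))
            colData <- colData[colnames(counts), , drop = FALSE]
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(spectralCounts = counts),
        rowData = S4Vectors::DataFrame(
            nPeptides = as.integer(nPeptides),
            singlePeptide = as.logical(singlePeptide),
            manuallyValidated = as.logical(manuallyValidated),
            row.names = rownames(counts)),
        colData = colData)
    new("ProteinEvidence", se)
}

#' SequenceClusterSet: a greedy identity-threshold partition of sequences
#'
#' Result of CD-HIT-style greedy incremental clustering: every accession is
#' assigned to exactly one cluster, named after its representative (the
#' longest member, ties broken by lexicographically smallest accession).
#'
#' @slot membership named character vector: accession -> representative.
#' @slot identity named numeric vector: accession -> identity to its
#'   representative (1 for the representative itself).
#' @slot threshold numeric, the identity threshold used.
#' @seealso [clusterSequences()]
#' @exportClass SequenceClusterSet
setClass("SequenceClusterSet",
    representation(membership = "character", identity = "numeric",
                   threshold = "numeric"))

setValidity("SequenceClusterSet", function(object) {
    msg <- character()
    if (is.null(names(object@membership)))
        msg <- c(msg, "membership must be named by accession")
    if (anyDuplicated(names(object@membership)))
        msg <- c(msg, "duplicate accessions in membership")
    reps <- unique(object@membership)
    if (!all(reps %in% names(object@membership)))
        msg <- c(msg, "every representative must itself be a member")
    ok <- object@identity[names(object@membership)] >= object@threshold |
        names(object@membership) == object@membership
    if (!all(ok))
        msg <- c(msg, "non-representative member below threshold identity")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SequenceClusterSet", function(object) {
    cat("SequenceClusterSet:", length(object@membership), "sequences in",
        length(unique(object@membership)), "clusters at >=",
        format(object@threshold), "identity\n")
})

#' TissueCompendium: gene expression across brain and other tissues
#'
#' Holds one gene-by-tissue matrix per data source (oligonucleotide
#' microarray intensities, EST tag counts, SAGE tag counts). Each matrix
#' must contain a brain column; the remaining columns are the "other"
#' normal tissues against which brain enrichment is judged.
#'
#' @slot microarray,est,sage numeric matrices, genes x tissues.
#' @slot brainTissue name of the brain column (default `"brain"`).
#' @seealso [compositeScore()], [buildBrainList()]
#' @exportClass TissueCompendium
setClass("TissueCompendium",
    representation(microarray = "matrix", est = "matrix", sage = "matrix",
                   brainTissue = "character"))

setValidity("TissueCompendium", function(object) {
    msg <- character()
    for (src in c("microarray", "est", "sage")) {
        m <- slot(object, src)
        if (nrow(m) == 0) next
        if (!object@brainTissue %in% colnames(m))
            msg <- c(msg, paste0(src, ": no '", object@brainTissue,
                                 "' tissue column"))
        if (ncol(m) < 2)
            msg <- c(msg, paste0(src, ": needs at least one non-brain tissue"))
        if (any(m < 0))
            msg <- c(msg, paste0(src, ": negative expression values"))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a TissueCompendium
#'
#' @param microarray,est,sage numeric gene-by-tissue matrices with gene
#'   symbols as rownames and tissue names as colnames. A source with no
#'   data may be an empty (0-row) matrix.
#' @param brainTissue column name identifying brain (default "brain").
#' @return A `TissueCompendium`.
#' @export
TissueCompendium <- function(microarray = matrix(0, 0, 0),
                             est = matrix(0, 0, 0),
                             sage = matrix(0, 0, 0),
                             brainTissue = "brain") {
    new("TissueCompendium", microarray = as.matrix(microarray),
        est = as.matrix(est), sage = as.matrix(sage),
        brainTissue = brainTissue)
}

setMethod("show", "TissueCompendium", function(object) {
    cat("TissueCompendium (brain tissue: '", object@brainTissue, "')\n",
        sep = "")
    for (src in c("microarray", "est", "sage")) {
        m <- slot(object, src)
        cat(sprintf("  %-10s %d genes x %d tissues\n", src, nrow(m), ncol(m)))
    }
})

#' CalibrationCurve: fitted four-parameter logistic standard curve
#'
#' Signal model `y = lower + (upper - lower) / (1 + (x / inflection)^-slope)`
#' for an increasing sandwich-immunoassay response, with the assay's lower
#' limits of quantification (LLOQ) and detection (LOD) attached.
#'
#' @slot lower,upper asymptotic signals at zero and saturating analyte.
#' @slot inflection concentration (ng/mL) at the curve midpoint.
#' @slot slope Hill slope (positive for an increasing curve).
#' @slot lloq,lod limits in ng/mL, `lod < lloq`.
#' @slot standards data.frame of the standards used for the fit
#'   (`concentration`, `signal`).
#' @seealso [fitCalibration()], [backCalculate()]
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
    representation(lower = "numeric", upper = "numeric",
                   inflection = "numeric", slope = "numeric",
                   lloq = "numeric", lod = "numeric",
                   standards = "data.frame"))

setValidity("CalibrationCurve", function(object) {
    msg <- character()
    if (object@lower >= object@upper)
        msg <- c(msg, "lower asymptote must be below upper asymptote")
    if (object@inflection <= 0) msg <- c(msg, "inflection must be positive")
    if (object@slope <= 0) msg <- c(msg, "slope must be positive")
    if (object@lod >= object@lloq) msg <- c(msg, "lod must be below lloq")
    if (length(msg)) msg else TRUE
})

setMethod("show", "CalibrationCurve", function(object) {
    cat("CalibrationCurve (4PL):\n")
    cat(sprintf("  asymptotes %.4g .. %.4g, inflection %.4g ng/mL, slope %.4g\n",
                object@lower, object@upper, object@inflection, object@slope))
    cat(sprintf("  LLOQ %.3g ng/mL, LOD %.3g ng/mL, %d standards\n",
                object@lloq, object@lod, nrow(object@standards)))
})
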