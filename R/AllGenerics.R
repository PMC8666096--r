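#' Extract the spectral-count matrix
#'
#' @param x a [ProteinEvidence] object.
#' @return integer matrix, proteins x samples.
#' @export
setGeneric("spectralCounts", function(x) standardGeneric("spectralCounts"))

#' @rdname spectralCounts
#' @export
setMethod("spectralCounts", "ProteinEvidence", function(x)
    SummarizedExperiment::assay(x, "spectralCounts"))

#' Peptide support accessors
#'
#' `nPeptides()` returns the number of distinct accepted peptides per
#' protein; `singlePeptide()` flags proteins supported by a single peptide
#' (these require manual spectrum validation downstream);
#' `manuallyValidated()` reports that validation status.
#'
#' @param x a [ProteinEvidence] object.
#' @return named integer or logical vector along proteins.
#' @export
setGeneric("nPeptides", function(x) standardGeneric("nPeptides"))

#' @rdname nPeptides
#' @export
setMethod("nPeptides", "ProteinEvidence", function(x)
    stats::setNames(SummarizedExperiment::rowData(x)$nPeptides, rownames(x)))

#' @rdname nPeptides
#' @export
setGeneric("singlePeptide", function(x) standardGeneric("singlePeptide"))

#' @rdname nPeptides
#' @export
setMethod("singlePeptide", "ProteinEvidence", function(x)
    stats::setNames(SummarizedExperiment::rowData(x)$singlePeptide, rownames(x)))

#' @rdname nPeptides
#' @export
setGeneric("manuallyValidated", function(x)
    standardGeneric("manuallyValidated"))

#' @rdname nPeptides
#' @export
setMethod("manuallyValidated", "ProteinEvidence", function(x)
    stats::setNames(SummarizedExperiment::rowData(x)$manuallyValidated,
                    rownames(x)))

#' Cluster accessors
#'
#' `representatives()` returns the representative accession of each cluster;
#' `membership()` the accession -> representative map; `clusterMembers()` a
#' list of member accessions per cluster, representatives first.
#'
#' @param x a [SequenceClusterSet].
#' @return character vector or list, see details.
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' @rdname representatives
#' @export
setMethod("representatives", "SequenceClusterSet", function(x)
    unique(unname(x@membership)))

#' @rdname representatives
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname representatives
#' @export
setMethod("membership", "SequenceClusterSet", function(x) x@membership)

#' @rdname representatives
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))

#' @rdname representatives
#' @export
setMethod("clusterMembers", "SequenceClusterSet", function(x) {
    reps <- representatives(x)
    lapply(stats::setNames(reps, reps), function(r) {
        m <- names(x@membership)[x@membership == r]
        c(r, setdiff(m, r))
    })
})
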