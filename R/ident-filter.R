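#' Read a peptide-spectrum-match (PSM) table
#'
#' Reads the tab-separated search-engine output consumed by the discovery
#' pipeline. Required columns: `sample_id`, `accession`, `peptide`,
#' `charge`, `probability`, `mowse`, `spectrum_id`. Rows whose numeric
#' fields fail to parse are reported with their line numbers.
#'
#' @param path path to a TSV file with a header row.
#' @return data.frame of typed PSM records.
#' @export
readPSMTable <- function(path) {
    need <- c("sample_id", "accession", "peptide", "charge", "probability",
              "mowse", "spectrum_id")
    df <- utils::read.delim(path, colClasses = "character",
                            stringsAsFactors = FALSE, check.names = FALSE)
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("PSM table ", path, " is missing required column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    df <- df[need]
    numify <- function(col, as) {
        v <- suppressWarnings(as(df[[col]]))
        bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
        if (length(bad))
            stop("malformed '", col, "' in ", path, " at line(s) ",
                 paste(bad + 1L, collapse = ", "),  # +1 for the header row
                 call. = FALSE)
        v
    }
    df$charge <- numify("charge", as.integer)
    df$probability <- numify("probability", as.numeric)
    df$mowse <- numify("mowse", as.numeric)
    if (nrow(df) > 0 && (any(df$probability < 0) || any(df$probability > 1)))
        stop("probability outside [0, 1] in ", path, call. = FALSE)
    df
}

#' Write a PSM table to TSV
#'
#' @param psms PSM data.frame as returned by [readPSMTable()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePSMTable <- function(psms, path) {
    utils::write.table(psms, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Peptide-spectrum-match acceptance rule
#'
#' A PSM is accepted when its identification probability and Mowse score
#' strictly exceed their thresholds and its charge is at least `minCharge`.
#' Defaults encode the discovery criteria: probability > 0.95, Mowse > 35
#' (p < 0.05) and charge state 2+ or higher (tryptic peptides are
#' predominantly 2+, so the charge rule is read as an inclusive >=2).
#'
#' @param psms PSM data.frame (columns `probability`, `mowse`, `charge`).
#' @param minProbability probability threshold, strict (default 0.95).
#' @param minMowse Mowse score threshold, strict (default 35).
#' @param minCharge minimum charge state, inclusive (default 2).
#' @return logical vector along rows of `psms`.
#' @examples
#' psm <- data.frame(probability = c(0.96, 0.95), mowse = c(40, 40),
#'                   charge = c(2L, 2L))
#' acceptPSM(psm)  # TRUE FALSE (0.95 exactly fails the strict rule)
#' @export
acceptPSM <- function(psms, minProbability = 0.95, minMowse = 35,
                      minCharge = 2) {
    psms$probability > minProbability &
        psms$mowse > minMowse &
        psms$charge >= minCharge
}

#' Assemble per-protein spectral counts from accepted PSMs
#'
#' Groups accepted PSMs by protein, counts accepted PSMs per (protein,
#' sample) as the spectral count, and records peptide support. A peptide is
#' *confirmed* when it is identified by at least `minSpectraPerPeptide`
#' spectra across all samples; proteins none of whose peptides are
#' confirmed are retained but must pass the single-peptide
#' manual-validation route before final reporting (see [filterEvidence()]).
#'
#' @param psms accepted PSM data.frame (apply [acceptPSM()] first).
#' @param minSpectraPerPeptide spectra needed to confirm a peptide
#'   (default 2).
#' @param samples optional character vector fixing the sample (column)
#'   universe; defaults to the samples present in `psms`.
#' @param validatedAccessions accessions whose single-peptide spectra have
#'   been manually validated.
#' @param colData optional sample annotation `DataFrame`/data.frame with
#'   rownames matching `samples` (a `group` column enables the
#'   differential stage).
#' @return A [ProteinEvidence] with rowData columns `nPeptides`,
#'   `singlePeptide`, `manuallyValidated` and `hasConfirmedPeptide`.
#' @export
assembleProteins <- function(psms, minSpectraPerPeptide = 2, samples = NULL,
                             validatedAccessions = character(),
                             colData = NULL) {
    if (is.null(samples))
        samples <- sort(unique(psms$sample_id))
    samples <- as.character(samples)
    if (nrow(psms) > 0 && !all(psms$sample_id %in% samples))
        stop("PSM samples not covered by 'samples'", call. = FALSE)
    accs <- sort(unique(psms$accession))
    counts <- matrix(0L, length(accs), length(samples),
                     dimnames = list(accs, samples))
    if (nrow(psms) > 0) {
        tab <- table(factor(psms$accession, levels = accs),
                     factor(psms$sample_id, levels = samples))
        counts[] <- as.integer(tab)
    }
    # peptide spectra pooled across samples decide confirmation
    pepSpectra <- table(psms$peptide)
    confirmedPep <- names(pepSpectra)[pepSpectra >= minSpectraPerPeptide]
    byAcc <- split(psms$peptide, factor(psms$accession, levels = accs))
    nPep <- vapply(byAcc, function(p) length(unique(p)), integer(1))
    hasConf <- vapply(byAcc, function(p) any(unique(p) %in% confirmedPep),
                      logical(1))
    if (!is.null(colData)) {
        colData <- S4Vectors::DataFrame(colData)
        if (!all(samples %in% rownames(colData)))
            stop("colData does not annotate every sample", call. = FALSE)
        colData <- colData[samples, , drop = FALSE]
    }
    pe <- ProteinEvidence(counts, nPeptides = nPep,
                          singlePeptide = nPep == 1L,
                          manuallyValidated = accs %in% validatedAccessions,
                          colData = colData)
    SummarizedExperiment::rowData(pe)$hasConfirmedPeptide <- unname(hasConf)
    pe
}

#' Drop unvalidated single-peptide proteins
#'
#' Final reports keep a protein supported by a single peptide without a
#' confirmed (multi-spectrum) peptide only if its spectrum was manually
#' validated. With `requireManualValidation = FALSE` everything passes.
#'
#' @param evidence a [ProteinEvidence].
#' @param requireManualValidation logical (default TRUE).
#' @return the filtered [ProteinEvidence].
#' @export
filterEvidence <- function(evidence, requireManualValidation = TRUE) {
    if (!requireManualValidation) return(evidence)
    rd <- SummarizedExperiment::rowData(evidence)
    conf <- if ("hasConfirmedPeptide" %in% colnames(rd))
        rd$hasConfirmedPeptide else rep(TRUE, nrow(rd))
    keep <- conf | !rd$singlePeptide | rd$manuallyValidated
    evidence[keep, ]
}

#' Write / read protein evidence as a wide TSV
#'
#' Wide layout: one row per protein, one column per sample spectral count,
#' plus the peptide-support flag columns. `readEvidence()` restores the
#' [ProteinEvidence] (sample annotations are supplied separately).
#'
#' @param evidence a [ProteinEvidence].
#' @param path TSV path.
#' @param colData optional sample annotations for `readEvidence()`.
#' @return `writeEvidence()`: `path` invisibly; `readEvidence()`: a
#'   [ProteinEvidence].
#' @export
writeEvidence <- function(evidence, path) {
    sc <- spectralCounts(evidence)
    rd <- SummarizedExperiment::rowData(evidence)
    df <- data.frame(accession = rownames(sc),
                     nPeptides = rd$nPeptides,
                     singlePeptide = rd$singlePeptide,
                     manuallyValidated = rd$manuallyValidated,
                     sc, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeEvidence
#' @export
readEvidence <- function(path, colData = NULL) {
    df <- utils::read.delim(path, check.names = FALSE)
    meta <- c("accession", "nPeptides", "singlePeptide", "manuallyValidated")
    sc <- as.matrix(df[setdiff(colnames(df), meta)])
    rownames(sc) <- df$accession
    ProteinEvidence(sc, nPeptides = df$nPeptides,
                    singlePeptide = df$singlePeptide,
                    manuallyValidated = df$manuallyValidated,
                    colData = colData)
}
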