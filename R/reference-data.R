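#' Bundled reference tables from the sickle-cell discovery study
#'
#' `referenceDifferential()` returns the published 23-protein differential
#' spectral-count table (per-group detected-sample counts, average
#' spectral counts and the reported one-decimal ratio).
#' `referenceBrainProteins()` returns the published brain-enriched plasma
#' protein report (25 proteins detected in the sickle-cell groups and 2
#' detected only in controls, with cellular component, average spectral
#' count and single-peptide status). `referenceVennCounts()` returns the
#' published three-group proteome region counts.
#'
#' @return data.frame (`referenceDifferential()`,
#'   `referenceBrainProteins()`) or named numeric vector
#'   (`referenceVennCounts()`, regions plus `scd_total`).
#' @export
referenceDifferential <- function() {
    utils::read.delim(system.file("extdata", "sci_differential_counts.tsv",
                                  package = "scdproteome"))
}

#' @rdname referenceDifferential
#' @export
referenceBrainProteins <- function() {
    utils::read.delim(system.file("extdata", "scd_brain_proteins.tsv",
                                  package = "scdproteome"))
}

#' @rdname referenceDifferential
#' @export
referenceVennCounts <- function() {
    j <- jsonlite::read_json(system.file("extdata",
                                         "proteome_venn_counts.json",
                                         package = "scdproteome"))
    unlist(j[c("pos_only", "neg_only", "pos_neg", "control_only",
               "scd_total")])
}

#' Materialise detection sets with prescribed Venn region counts
#'
#' Builds three synthetic accession sets whose seven-region partition has
#' the given cardinalities, for exercising [vennPartition()] against
#' published region counts. Unprinted SCD-and-control overlap is placed in
#' the triple region (`scd_total` minus the three SCD-exclusive regions);
#' the derived percentages do not depend on that placement.
#'
#' @param counts named numeric vector with `pos_only`, `neg_only`,
#'   `pos_neg`, `control_only` and `scd_total` (see
#'   [referenceVennCounts()]).
#' @return list of accession vectors `setPos`, `setNeg`, `setControl`.
#' @export
vennSetsFromCounts <- function(counts = referenceVennCounts()) {
    triple <- counts[["scd_total"]] - counts[["pos_only"]] -
        counts[["neg_only"]] - counts[["pos_neg"]]
    stopIfNot(triple >= 0, "region counts exceed scd_total")
    mk <- function(n, tag) if (n > 0) sprintf("%s%04d", tag, seq_len(n))
                           else character()
    p <- mk(counts[["pos_only"]], "P")
    n <- mk(counts[["neg_only"]], "N")
    c0 <- mk(counts[["control_only"]], "C")
    pn <- mk(counts[["pos_neg"]], "PN")
    t3 <- mk(triple, "T")
    list(setPos = c(p, pn, t3), setNeg = c(n, pn, t3),
         setControl = c(c0, t3))
}

#' Summarise a brain-protein plasma report
#'
#' Headline descriptive statistics of a brain-enriched protein report:
#' list size, the maximum average spectral count and the protein holding
#' it, the fraction of proteins annotated solely as membrane-bound, and
#' the fraction identified at the single-peptide level. Percentages are
#' rounded half-up to the nearest integer.
#'
#' @param report data.frame with columns `accession`, `avg_sc` and
#'   `single_peptide`, optionally `cellular_component` and `gene`.
#' @return list: `n`, `maxSC`, `maxSCAccession`, `maxSCGene` (NA when no
#'   `gene` column), `pctMembrane` (NA when no component column),
#'   `pctSinglePeptide`.
#' @export
brainReportSummary <- function(report) {
    stopIfNot(nrow(report) > 0, "empty brain-protein report")
    top <- which.max(report$avg_sc)
    pctMembrane <- if ("cellular_component" %in% colnames(report))
        roundHalfUp(100 * mean(report$cellular_component == "Membrane"), 0)
    else NA_real_
    list(n = nrow(report),
         maxSC = report$avg_sc[top],
         maxSCAccession = report$accession[top],
         maxSCGene = if ("gene" %in% colnames(report))
             report$gene[top] else NA_character_,
         pctMembrane = pctMembrane,
         pctSinglePeptide = roundHalfUp(
             100 * mean(report$single_peptide), 0))
}
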