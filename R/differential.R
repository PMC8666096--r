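#' Per-group detection sets
#'
#' A protein is *detected* in a group when its spectral count exceeds zero
#' in at least one sample of that group.
#'
#' @param evidence a [ProteinEvidence] whose `colData` has a `group`
#'   column covering every sample.
#' @param groups group labels to report (default the three study groups).
#' @return named list of accession character vectors, one per group.
#' @export
detectionSets <- function(evidence,
                          groups = c("sci_positive", "sci_negative",
                                     "control")) {
    ann <- SummarizedExperiment::colData(evidence)$group
    if (is.null(ann) || anyNA(ann))
        stop("every sample must be annotated with a group", call. = FALSE)
    sc <- spectralCounts(evidence)
    lapply(stats::setNames(groups, groups), function(g) {
        cols <- which(ann == g)
        if (!length(cols)) return(character())
        rownames(sc)[rowSums(sc[, cols, drop = FALSE] > 0) > 0]
    })
}

#' Three-set Venn partition of detected proteomes
#'
#' Splits the union of the three detection sets into the seven exclusive
#' regions of a three-set Venn diagram and reports the counts used in
#' proteome comparisons: proteins unique to each SCD group, common to both
#' SCD groups but absent from controls, and control-only, each as a
#' percentage of the SCD proteome (proteins detected in either SCD group),
#' rounded half-up to the nearest integer.
#'
#' @param setPos,setNeg,setControl accession character vectors (detected in
#'   SCI-positive, SCI-negative, control).
#' @return list with `regions` (seven named counts), `scdTotal`, and
#'   `percentages` (`uniquePos`, `uniqueNeg`, `commonScd`, of `scdTotal`).
#' @examples
#' vennPartition(c("a", "b"), c("b", "c"), "d")$regions
#' @export
vennPartition <- function(setPos, setNeg, setControl) {
    setPos <- unique(setPos); setNeg <- unique(setNeg)
    setControl <- unique(setControl)
    inP <- function(x) x %in% setPos
    inN <- function(x) x %in% setNeg
    inC <- function(x) x %in% setControl
    u <- unique(c(setPos, setNeg, setControl))
    key <- paste0(ifelse(inP(u), "P", ""), ifelse(inN(u), "N", ""),
                  ifelse(inC(u), "C", ""))
    cnt <- function(k) sum(key == k)
    regions <- c(pos_only = cnt("P"), neg_only = cnt("N"),
                 control_only = cnt("C"), pos_neg = cnt("PN"),
                 pos_control = cnt("PC"), neg_control = cnt("NC"),
                 triple = cnt("PNC"))
    scdTotal <- sum(regions[c("pos_only", "neg_only", "pos_neg",
                              "pos_control", "neg_control", "triple")])
    pct <- function(n) if (scdTotal > 0) roundHalfUp(100 * n / scdTotal, 0)
                       else NA_real_
    list(regions = regions, scdTotal = scdTotal,
         percentages = c(uniquePos = pct(regions[["pos_only"]]),
                         uniqueNeg = pct(regions[["neg_only"]]),
                         commonScd = pct(regions[["pos_neg"]])))
}

#' Average spectral count over detected samples
#'
#' Mean spectral count of each protein across the samples of one group in
#' which it was detected (SC > 0); 0 when never detected. Averaging over
#' detected samples (rather than all group samples) pairs naturally with
#' reporting the number of samples in which each protein was seen.
#'
#' @param evidence a [ProteinEvidence] with `group` annotations.
#' @param group group label.
#' @param overAllSamples average over all group samples instead (default
#'   FALSE).
#' @return named numeric vector along proteins.
#' @export
averageSC <- function(evidence, group, overAllSamples = FALSE) {
    ann <- SummarizedExperiment::colData(evidence)$group
    sc <- spectralCounts(evidence)[, which(ann == group), drop = FALSE]
    if (ncol(sc) == 0)
        stop("no samples in group '", group, "'", call. = FALSE)
    nDet <- rowSums(sc > 0)
    denom <- if (overAllSamples) ncol(sc) else pmax(nDet, 1L)
    stats::setNames(rowSums(sc) / denom, rownames(sc))
}

#' Build the per-protein differential table
#'
#' For every protein, the number of SCD samples in which it was detected
#' and its average spectral count in the SCI-negative and SCI-positive
#' groups, plus the SC ratio (SCI-negative / SCI-positive).
#'
#' @param evidence a [ProteinEvidence] with `group` annotations.
#' @param posGroup,negGroup group labels (defaults `"sci_positive"`,
#'   `"sci_negative"`).
#' @param overAllSamples see [averageSC()].
#' @return data.frame with columns `accession`, `n_detected_neg`,
#'   `n_detected_pos`, `avg_sc_neg`, `avg_sc_pos`.
#' @export
differentialTable <- function(evidence, posGroup = "sci_positive",
                              negGroup = "sci_negative",
                              overAllSamples = FALSE) {
    ann <- SummarizedExperiment::colData(evidence)$group
    sc <- spectralCounts(evidence)
    nDet <- function(g) rowSums(sc[, which(ann == g), drop = FALSE] > 0)
    data.frame(accession = rownames(sc),
               n_detected_neg = nDet(negGroup),
               n_detected_pos = nDet(posGroup),
               avg_sc_neg = unname(averageSC(evidence, negGroup,
                                             overAllSamples)),
               avg_sc_pos = unname(averageSC(evidence, posGroup,
                                             overAllSamples)),
               row.names = NULL)
}

#' Two-fold spectral-count screen
#'
#' Flags proteins detected in at least `minSamples` individuals of *each*
#' SCD group whose spectral-count ratio (SCI-negative average over
#' SCI-positive average) is at least `highCut` or at most `lowCut` after
#' rounding half-up to `roundDigits` decimals. The threshold is applied to
#' the *rounded* ratio: published spectral-count tables report one-decimal
#' ratios and include boundary entries (e.g. 305.0/153.0 = 1.9935 reported
#' and screened as 2.0), so only the rounded-ratio convention reproduces
#' their membership.
#'
#' @param records data.frame as from [differentialTable()].
#' @param minSamples minimum detected samples per SCD group (default 2).
#' @param highCut,lowCut inclusive ratio cuts (defaults 2.0 and 0.5);
#'   `lowCut` must equal `1 / highCut`.
#' @param roundDigits decimals for the reported ratio (default 1).
#' @return `records` with added columns `ratio` (rounded; `Inf` when the
#'   SCI-positive average is 0) and `passes`.
#' @export
foldChangeScreen <- function(records, minSamples = 2, highCut = 2.0,
                             lowCut = 0.5, roundDigits = 1) {
    stopIfNot(isTRUE(all.equal(lowCut, 1 / highCut)),
              "lowCut must equal 1/highCut")
    raw <- ifelse(records$avg_sc_pos > 0,
                  records$avg_sc_neg / records$avg_sc_pos,
                  ifelse(records$avg_sc_neg > 0, Inf, NaN))
    ratio <- ifelse(is.finite(raw), roundHalfUp(raw, roundDigits), raw)
    detected <- records$n_detected_neg >= minSamples &
        records$n_detected_pos >= minSamples
    passes <- detected & !is.nan(ratio) &
        (ratio >= highCut | ratio <= lowCut)
    records$ratio <- ratio
    records$passes <- passes
    records
}
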