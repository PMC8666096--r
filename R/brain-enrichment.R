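#' Microarray brain-enrichment point
#'
#' Awards 1 when brain expression strictly exceeds `foldCut` times the
#' baseline, where baseline summarises the non-brain tissues (median by
#' default, robust against co-expression in a single other tissue). A zero
#' baseline with positive brain expression counts as enriched; an all-zero
#' profile scores 0 with a warning.
#'
#' @param values named numeric vector of expression over tissues
#'   (including the brain tissue).
#' @param brainTissue name of the brain entry (default "brain").
#' @param foldCut fold-change threshold, strict (default 10).
#' @param baselineFun `"median"` (default) or `"mean"`.
#' @return 0 or 1.
#' @export
scoreMicroarray <- function(values, brainTissue = "brain", foldCut = 10,
                            baselineFun = c("median", "mean")) {
    baselineFun <- match.arg(baselineFun)
    stopIfNot(brainTissue %in% names(values), "no brain tissue in profile")
    brain <- values[[brainTissue]]
    other <- values[names(values) != brainTissue]
    stopIfNot(length(other) >= 1, "profile needs at least one other tissue")
    if (all(values == 0)) {
        warning("all-zero expression profile", call. = FALSE)
        return(0L)
    }
    baseline <- if (baselineFun == "median") stats::median(other)
                else mean(other)
    if (baseline == 0) return(as.integer(brain > 0))
    as.integer(brain > foldCut * baseline)
}

#' EST/SAGE tag-presence brain-enrichment point
#'
#' Awards 1 when the transcript is present in brain (at least
#' `presenceCut` tags) and present in fewer than `maxOtherTissues` other
#' tissues -- i.e. in 0 or 1 other tissue at the defaults.
#'
#' @inheritParams scoreMicroarray
#' @param presenceCut tag count defining presence (default 1).
#' @param maxOtherTissues strict upper bound on other tissues with
#'   presence (default 2).
#' @return 0 or 1.
#' @export
scoreTagPresence <- function(values, brainTissue = "brain", presenceCut = 1,
                             maxOtherTissues = 2) {
    stopIfNot(brainTissue %in% names(values), "no brain tissue in profile")
    brain <- values[[brainTissue]]
    other <- values[names(values) != brainTissue]
    as.integer(brain >= presenceCut &
               sum(other >= presenceCut) < maxOtherTissues)
}

#' Composite 0-3 brain-enrichment score
#'
#' One point per data source meeting its criterion: microarray fold
#' enrichment, EST tag restriction, SAGE tag restriction. Sources without
#' data for the gene contribute 0. Maximum score 3 when all three
#' categories are met.
#'
#' @param gene gene symbol.
#' @param compendium a [TissueCompendium].
#' @param foldCut,baselineFun passed to [scoreMicroarray()].
#' @param presenceCut,maxOtherTissues passed to [scoreTagPresence()].
#' @return data.frame row: `gene`, `microarray`, `est`, `sage`, `total`.
#' @export
compositeScore <- function(gene, compendium, foldCut = 10,
                           baselineFun = "median", presenceCut = 1,
                           maxOtherTissues = 2) {
    present <- vapply(c("microarray", "est", "sage"),
                      function(s) gene %in% rownames(slot(compendium, s)),
                      logical(1))
    if (!any(present))
        stop("gene '", gene, "' absent from every source", call. = FALSE)
    pt <- function(src, f) {
        m <- slot(compendium, src)
        if (!gene %in% rownames(m)) return(0L)
        f(stats::setNames(m[gene, ], colnames(m)))
    }
    ma <- pt("microarray", function(v)
        scoreMicroarray(v, compendium@brainTissue, foldCut, baselineFun))
    es <- pt("est", function(v)
        scoreTagPresence(v, compendium@brainTissue, presenceCut,
                         maxOtherTissues))
    sa <- pt("sage", function(v)
        scoreTagPresence(v, compendium@brainTissue, presenceCut,
                         maxOtherTissues))
    data.frame(gene = gene, microarray = ma, est = es, sage = sa,
               total = ma + es + sa)
}

#' Score every gene in a compendium
#'
#' @inheritParams compositeScore
#' @return data.frame of [compositeScore()] rows over the union of genes,
#'   sorted by decreasing total then gene symbol.
#' @export
brainScores <- function(compendium, foldCut = 10, baselineFun = "median",
                        presenceCut = 1, maxOtherTissues = 2) {
    genes <- sort(unique(c(rownames(compendium@microarray),
                           rownames(compendium@est),
                           rownames(compendium@sage))))
    if (!length(genes))
        return(data.frame(gene = character(), microarray = integer(),
                          est = integer(), sage = integer(),
                          total = integer()))
    out <- do.call(rbind, lapply(genes, compositeScore, compendium,
                                 foldCut, baselineFun, presenceCut,
                                 maxOtherTissues))
    out[order(-out$total, out$gene), , drop = FALSE]
}

#' Build the brain-enriched gene list
#'
#' Genes whose composite score reaches `minTotal`. The default of 1 admits
#' mixed evidence levels (any single source suffices); raise to 3 to keep
#' only genes meeting all three criteria.
#'
#' @inheritParams compositeScore
#' @param minTotal membership threshold in 1..3 (default 1).
#' @return data.frame of scored member genes (see [brainScores()]); the
#'   gene set is its `gene` column.
#' @export
buildBrainList <- function(compendium, minTotal = 1, foldCut = 10,
                           baselineFun = "median", presenceCut = 1,
                           maxOtherTissues = 2) {
    stopIfNot(minTotal %in% 1:3, "minTotal must be 1, 2 or 3")
    sc <- brainScores(compendium, foldCut, baselineFun, presenceCut,
                      maxOtherTissues)
    sc[sc$total >= minTotal, , drop = FALSE]
}

#' Intersect the plasma proteome with the brain-enriched list
#'
#' Produces the two headline reports of the brain-protein stage: brain
#' proteins detected in either SCD group but not in controls, and brain
#' proteins detected only in controls. Optional per-accession annotation
#' columns (average spectral count, single-peptide flag, cellular
#' component) are carried through when supplied.
#'
#' @param detected named list of detection sets (from [detectionSets()]):
#'   `sci_positive`, `sci_negative`, `control`.
#' @param brainGenes character vector of brain-enriched gene symbols.
#' @param accessionToGene data.frame with columns `accession`, `gene`;
#'   detected accessions without a mapping are dropped with a message.
#' @param info optional data.frame keyed by `accession` with annotation
#'   columns to join (e.g. `avg_sc`, `single_peptide`).
#' @return list of two data.frames, `scdNotControl` and `controlNotScd`,
#'   sorted by decreasing `avg_sc` when available.
#' @export
filterPlasmaBrain <- function(detected, brainGenes, accessionToGene,
                              info = NULL) {
    scd <- union(detected$sci_positive, detected$sci_negative)
    ctrl <- detected$control
    unmapped <- setdiff(union(scd, ctrl), accessionToGene$accession)
    if (length(unmapped))
        message(length(unmapped), " detected accession(s) without a gene",
                " mapping were skipped")
    build <- function(accs) {
        df <- accessionToGene[accessionToGene$accession %in% accs &
                              accessionToGene$gene %in% brainGenes,
                              c("accession", "gene"), drop = FALSE]
        if (!is.null(info))
            df <- merge(df, info, by = "accession", all.x = TRUE,
                        sort = FALSE)
        if ("avg_sc" %in% colnames(df))
            df <- df[order(-df$avg_sc, df$accession), , drop = FALSE]
        else df <- df[order(df$accession), , drop = FALSE]
        rownames(df) <- NULL
        df
    }
    list(scdNotControl = build(setdiff(scd, ctrl)),
         controlNotScd = build(setdiff(ctrl, scd)))
}
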