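#' Pipeline run configuration
#'
#' Collects every tunable threshold of the workflow in one object, with
#' defaults set to the study acceptance criteria: PSM probability > 0.95,
#' Mowse > 35, charge >= 2, >= 2 spectra to confirm a peptide, 90%
#' clustering identity, fold screen at >= 2 samples per group and
#' two-fold on the one-decimal ratio, 10-fold microarray enrichment,
#' presence in < 2 other tissues, composite score >= 1, duplicate CV% >
#' 20 repeat rule, LLOQ 0.039 / LOD 0.012 ng/mL, and the 4-day
#' processing-time sensitivity cut. The configuration is serialised into
#' every report for provenance.
#'
#' @param inputDir,outputDir directories for pipeline inputs and reports.
#' @param minProbability,minMowse,minCharge PSM acceptance thresholds.
#' @param minSpectraPerPeptide peptide confirmation threshold.
#' @param requireManualValidation drop unvalidated single-peptide
#'   proteins from final reports (default TRUE).
#' @param identityThreshold clustering identity threshold.
#' @param minSamples,highCut,lowCut,roundDigits fold-screen parameters.
#' @param foldCut,maxOtherTissues,presenceCut,minTotal brain-enrichment
#'   parameters.
#' @param cvThreshold,lloq,lod,maxDays,belowLodPolicy immunoassay
#'   parameters.
#' @param seed integer seed governing all randomness of a run.
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(inputDir = ".", outputDir = ".",
                      minProbability = 0.95, minMowse = 35, minCharge = 2,
                      minSpectraPerPeptide = 2,
                      requireManualValidation = TRUE,
                      identityThreshold = 0.90,
                      minSamples = 2, highCut = 2.0, lowCut = 0.5,
                      roundDigits = 1,
                      foldCut = 10, maxOtherTissues = 2, presenceCut = 1,
                      minTotal = 1,
                      cvThreshold = 20, lloq = 0.039, lod = 0.012,
                      maxDays = 4, belowLodPolicy = "half_lod",
                      seed = 1) {
    cfg <- as.list(environment())
    structure(cfg, class = "RunConfig")
}

#' @export
print.RunConfig <- function(x, ...) {
    cat("RunConfig:\n")
    for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm,
                                     paste(format(x[[nm]]), collapse = " ")))
    invisible(x)
}

bundlePaths <- function(dir) {
    file.path(dir, c(cohort = "cohort.tsv", fasta = "sequences.fasta",
                     psms = "psms.tsv", compendium = "compendium.tsv",
                     geneMap = "accession_to_gene.tsv",
                     plates = "plates.tsv", standards = "standards.tsv",
                     truth = "planted_truth.json")) |>
        stats::setNames(c("cohort", "fasta", "psms", "compendium",
                          "geneMap", "plates", "standards", "truth"))
}

writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

compendiumToLong <- function(compendium) {
    do.call(rbind, lapply(c("microarray", "est", "sage"), function(src) {
        m <- slot(compendium, src)
        if (!nrow(m)) return(NULL)
        data.frame(gene = rep(rownames(m), times = ncol(m)),
                   source = src,
                   tissue = rep(colnames(m), each = nrow(m)),
                   value = as.vector(m))
    }))
}

longToCompendium <- function(df, brainTissue = "brain") {
    mk <- function(src) {
        d <- df[df$source == src, , drop = FALSE]
        if (!nrow(d)) return(matrix(0, 0, 0))
        genes <- unique(d$gene); tissues <- unique(d$tissue)
        m <- matrix(0, length(genes), length(tissues),
                    dimnames = list(genes, tissues))
        m[cbind(match(d$gene, genes), match(d$tissue, tissues))] <- d$value
        m
    }
    TissueCompendium(microarray = mk("microarray"), est = mk("est"),
                     sage = mk("sage"), brainTissue = brainTissue)
}

#' Generate and write the synthetic input bundle
#'
#' Runs [simulateStudy()] under the configuration seed and writes every
#' pipeline input to `outputDir`: cohort TSV, FASTA sequences, PSM TSV,
#' long-format compendium TSV, accession-to-gene TSV, plate and standard
#' TSVs, and the planted truth as JSON.
#'
#' @param config a [runConfig()].
#' @param ... forwarded to [simulateStudy()].
#' @return invisibly, the list of written paths.
#' @export
runSimulate <- function(config = runConfig(), ...) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    bundle <- simulateStudy(seed = config$seed, ...)
    p <- bundlePaths(config$outputDir)
    writeTsv(bundle$cohort, p["cohort"])
    Biostrings::writeXStringSet(bundle$sequences, p["fasta"])
    writeTsv(bundle$psms, p["psms"])
    writeTsv(compendiumToLong(bundle$compendium), p["compendium"])
    writeTsv(bundle$accessionToGene, p["geneMap"])
    writeTsv(bundle$plates, p["plates"])
    writeTsv(bundle$standards, p["standards"])
    jsonlite::write_json(
        list(brainGenes = bundle$truth$brainGenes,
             scdOnly = bundle$truth$scdOnly,
             foldMap = as.list(bundle$truth$foldMap),
             assayGroupMedians = as.list(bundle$truth$assayGroupMedians),
             labels = as.list(bundle$labels)),
        p["truth"], auto_unbox = TRUE, digits = NA)
    invisible(as.list(p))
}

#' Run the discovery pipeline
#'
#' Reads the input bundle from `config$inputDir` and executes
#' identification filtering, redundancy clustering, the differential
#' spectral-count screen and brain-enrichment filtering; writes
#' protein-evidence, cluster, differential, Venn and brain-protein
#' reports (TSV + JSON) to `config$outputDir`.
#'
#' @param config a [runConfig()].
#' @return invisibly, a list with the in-memory results: `evidence`,
#'   `clusters`, `collapsed`, `differential`, `venn`, `brainList`,
#'   `brainReport`.
#' @export
runDiscovery <- function(config = runConfig()) {
    p <- bundlePaths(config$inputDir)
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    cohort <- utils::read.delim(p["cohort"])
    psms <- readPSMTable(p["psms"])
    keep <- acceptPSM(psms, config$minProbability, config$minMowse,
                      config$minCharge)
    accepted <- psms[keep, , drop = FALSE]
    ann <- S4Vectors::DataFrame(group = cohort$group,
                                row.names = cohort$sample_id)
    evidence <- assembleProteins(accepted, config$minSpectraPerPeptide,
                                 samples = cohort$sample_id, colData = ann)
    seqs <- Biostrings::readAAStringSet(p["fasta"])
    names(seqs) <- sub("\\s.*", "", names(seqs))
    clusters <- clusterSequences(seqs, config$identityThreshold)
    collapsed <- collapseEvidence(evidence, clusters, psms = accepted)
    collapsed <- filterEvidence(collapsed, config$requireManualValidation)
    det <- detectionSets(collapsed)
    venn <- vennPartition(det$sci_positive, det$sci_negative, det$control)
    diff <- foldChangeScreen(differentialTable(collapsed),
                             config$minSamples, config$highCut,
                             config$lowCut, config$roundDigits)
    compendium <- longToCompendium(utils::read.delim(p["compendium"]))
    brainList <- buildBrainList(compendium, config$minTotal,
                                config$foldCut,
                                presenceCut = config$presenceCut,
                                maxOtherTissues = config$maxOtherTissues)
    geneMap <- utils::read.delim(p["geneMap"])
    accs <- rownames(collapsed)
    if (is.null(accs)) accs <- character()
    scdAvg <- pmax(averageSC(collapsed, "sci_positive"),
                   averageSC(collapsed, "sci_negative"))
    info <- data.frame(accession = accs,
                       avg_sc = if (length(accs)) unname(scdAvg)
                                else numeric(),
                       single_peptide = if (length(accs))
                           unname(singlePeptide(collapsed)) else logical())
    brainReport <- filterPlasmaBrain(det, brainList$gene, geneMap, info)
    out <- config$outputDir
    writeEvidence(collapsed, file.path(out, "evidence.tsv"))
    writeClstr(clusters, seqs, file.path(out, "clusters.clstr"),
               file.path(out, "cluster_map.tsv"))
    writeTsv(diff, file.path(out, "differential.tsv"))
    writeTsv(brainList, file.path(out, "brain_list.tsv"))
    writeTsv(brainReport$scdNotControl,
             file.path(out, "brain_proteins_scd.tsv"))
    writeTsv(brainReport$controlNotScd,
             file.path(out, "brain_proteins_control.tsv"))
    jsonlite::write_json(
        list(config = unclass(config),
             venn = as.list(venn$regions), scdTotal = venn$scdTotal,
             percentages = as.list(venn$percentages),
             nDifferential = sum(diff$passes),
             nBrainScd = nrow(brainReport$scdNotControl),
             nBrainControl = nrow(brainReport$controlNotScd)),
        file.path(out, "discovery_summary.json"), auto_unbox = TRUE,
        digits = NA)
    invisible(list(evidence = evidence, clusters = clusters,
                   collapsed = collapsed, differential = diff, venn = venn,
                   brainList = brainList, brainReport = brainReport))
}

#' Run the immunoassay verification pipeline
#'
#' Reads plates and standards from `config$inputDir`, processes them
#' (calibration, duplicate QC, censoring), compares the SCD and control
#' groups on initial-visit samples, repeats the comparison after the
#' processing-time sensitivity filter, and writes the concentration table,
#' a long-format export and a JSON comparison report.
#'
#' @param config a [runConfig()].
#' @return invisibly, a list: `measurements`, `comparison`,
#'   `sensitivityComparison` (NULL with a warning when no sample
#'   survives the filter).
#' @export
runVerification <- function(config = runConfig()) {
    p <- bundlePaths(config$inputDir)
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    plates <- utils::read.delim(p["plates"])
    standards <- utils::read.delim(p["standards"])
    proc <- processPlates(plates, standards, lloq = config$lloq,
                          lod = config$lod,
                          cvThreshold = config$cvThreshold,
                          belowLodPolicy = config$belowLodPolicy)
    meas <- proc$measurements
    initial <- meas[meas$visit_month == min(meas$visit_month), ]
    scd <- initial$concentration[initial$group != "control"]
    ctl <- initial$concentration[initial$group == "control"]
    cmp <- compareGroups(scd, ctl, labels = c("scd", "control"))
    sens <- sensitivityFilter(initial, config$maxDays)
    sensCmp <- NULL
    scdS <- sens$concentration[sens$group != "control"]
    ctlS <- sens$concentration[sens$group == "control"]
    if (length(scdS) >= 2 && length(ctlS) >= 2) {
        sensCmp <- compareGroups(scdS, ctlS, labels = c("scd", "control"))
    } else {
        warning("sensitivity analysis has fewer than two values per group",
                call. = FALSE)
    }
    out <- config$outputDir
    writeTsv(meas, file.path(out, "concentrations.tsv"))
    writeTsv(longFormat(meas), file.path(out, "concentrations_long.tsv"))
    asJson <- function(x) if (is.null(x)) NULL else
        lapply(x, function(v) if (is.null(names(v))) v else as.list(v))
    jsonlite::write_json(
        list(config = unclass(config), primary = asJson(cmp),
             sensitivity = asJson(sensCmp)),
        file.path(out, "verification_summary.json"), auto_unbox = TRUE,
        digits = NA)
    invisible(list(measurements = meas, comparison = cmp,
                   sensitivityComparison = sensCmp))
}
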