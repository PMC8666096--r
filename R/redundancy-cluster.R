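#' @importFrom Biostrings AAStringSet pairwiseAlignment nmatch width
NULL

aaAlphabet <- function() c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

identitySubstitutionMatrix <- function() {
    ab <- aaAlphabet()
    m <- matrix(0, length(ab), length(ab), dimnames = list(ab, ab))
    diag(m) <- 1
    m
}

#' Pairwise global-alignment sequence identity
#'
#' Fraction of identical aligned residue pairs in the optimal global
#' (Needleman-Wunsch) alignment, normalised by the length of the shorter
#' sequence -- the CD-HIT convention. Alignment scoring is match = 1,
#' mismatch = 0, linear gap = -1; identity is counted from the traceback.
#'
#' @param a,b amino-acid strings (or length-1 `AAStringSet`s), uppercase
#'   20-letter alphabet plus X.
#' @return identity fraction in `[0, 1]`; symmetric in its arguments.
#' @examples
#' sequenceIdentity("ACDEFGHIKL", "ACDEFGHIKV")  # 0.9
#' @export
sequenceIdentity <- function(a, b) {
    a <- as.character(a)[1]; b <- as.character(b)[1]
    if (!nzchar(a) || !nzchar(b))
        stop("empty sequence", call. = FALSE)
    aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(a), Biostrings::AAStringSet(b),
        type = "global",
        substitutionMatrix = identitySubstitutionMatrix(),
        gapOpening = 0, gapExtension = 1)
    Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

#' Greedy incremental clustering at an identity threshold
#'
#' CD-HIT-style redundancy collapse: sequences are sorted by decreasing
#' length (ties by lexicographically smallest accession); each sequence
#' joins the first existing cluster whose *representative* it matches at
#' `>= threshold` identity (per [sequenceIdentity()]), otherwise it founds
#' a new cluster. Because sorting is by length, every representative is the
#' longest member of its cluster, and the output is deterministic.
#'
#' @param records named character vector or `AAStringSet` of protein
#'   sequences; names are accessions and must be unique.
#' @param threshold identity threshold in `(0.5, 1]` (default 0.90).
#' @return A [SequenceClusterSet].
#' @export
clusterSequences <- function(records, threshold = 0.90) {
    seqs <- as.character(records)
    if (is.null(names(seqs))) names(seqs) <- names(records)
    if (is.null(names(seqs)) || !all(nzchar(names(seqs))))
        stop("sequences must be named by accession", call. = FALSE)
    if (anyDuplicated(names(seqs)))
        stop("duplicate accessions", call. = FALSE)
    stopIfNot(threshold > 0.5 && threshold <= 1,
              "threshold must be in (0.5, 1]")
    ord <- order(-nchar(seqs), names(seqs))
    seqs <- seqs[ord]
    reps <- character()
    memb <- character(); ident <- numeric()
    for (acc in names(seqs)) {
        assigned <- NA_character_; idn <- 1
        for (r in reps) {
            id <- sequenceIdentity(seqs[[acc]], seqs[[r]])
            if (id >= threshold) { assigned <- r; idn <- id; break }
        }
        if (is.na(assigned)) {
            reps <- c(reps, acc)
            assigned <- acc; idn <- 1
        }
        memb[acc] <- assigned
        ident[acc] <- idn
    }
    new("SequenceClusterSet", membership = memb, identity = ident,
        threshold = threshold)
}

#' Collapse protein evidence onto cluster representatives
#'
#' Re-keys a [ProteinEvidence] so each cluster contributes one record under
#' its representative accession: per-sample spectral counts are summed over
#' members (total spectral count is conserved), peptide support is pooled
#' (distinct peptides over members when the accepted PSM table is supplied,
#' otherwise the sum of member peptide counts), and a member's manual
#' validation carries over. Accessions without a sequence (absent from the
#' clustering) pass through unclustered, with a message.
#'
#' @param evidence a [ProteinEvidence].
#' @param clusters a [SequenceClusterSet] covering the sequenced accessions.
#' @param psms optional accepted-PSM data.frame used to recount distinct
#'   peptides exactly across cluster members.
#' @return a collapsed [ProteinEvidence].
#' @export
collapseEvidence <- function(evidence, clusters, psms = NULL) {
    memb <- membership(clusters)
    accs <- rownames(evidence)
    unclustered <- setdiff(accs, names(memb))
    if (length(unclustered))
        message(length(unclustered),
                " accession(s) without sequences pass through unclustered")
    rep <- ifelse(accs %in% names(memb), memb[accs], accs)
    sc <- spectralCounts(evidence)
    grp <- factor(rep, levels = unique(rep))
    collapsed <- rowsum(sc, grp)
    collapsed <- collapsed[levels(grp), , drop = FALSE]
    rd <- SummarizedExperiment::rowData(evidence)
    nPep <- as.integer(rowsum(as.integer(rd$nPeptides), grp)[levels(grp), 1])
    if (!is.null(psms)) {
        pepRep <- ifelse(psms$accession %in% names(memb),
                         memb[psms$accession], psms$accession)
        cnt <- vapply(split(psms$peptide, factor(pepRep, levels(grp))),
                      function(p) length(unique(p)), integer(1))
        nPep <- ifelse(levels(grp) %in% names(cnt), cnt[levels(grp)], nPep)
    }
    val <- as.logical(rowsum(as.integer(rd$manuallyValidated),
                             grp)[levels(grp), 1] > 0)
    pe <- ProteinEvidence(collapsed, nPeptides = nPep,
                          singlePeptide = nPep == 1L,
                          manuallyValidated = val,
                          colData = SummarizedExperiment::colData(evidence))
    if ("hasConfirmedPeptide" %in% colnames(rd)) {
        conf <- as.logical(rowsum(as.integer(rd$hasConfirmedPeptide),
                                  grp)[levels(grp), 1] > 0)
        SummarizedExperiment::rowData(pe)$hasConfirmedPeptide <- conf
    }
    pe
}

#' Write clusters in CD-HIT-like .clstr layout and as a TSV map
#'
#' @param clusters a [SequenceClusterSet].
#' @param records the clustered sequences (for member lengths).
#' @param clstrPath output path for the `.clstr`-style text file.
#' @param mapPath optional path for an accession -> representative TSV.
#' @return `clstrPath`, invisibly.
#' @export
writeClstr <- function(clusters, records, clstrPath, mapPath = NULL) {
    seqs <- as.character(records)
    members <- clusterMembers(clusters)
    con <- file(clstrPath, "w"); on.exit(close(con))
    for (i in seq_along(members)) {
        cat(sprintf(">Cluster %d\n", i - 1L), file = con)
        for (j in seq_along(members[[i]])) {
            acc <- members[[i]][j]
            tag <- if (acc == names(members)[i]) "*"
                   else sprintf("at %.2f%%", 100 * clusters@identity[[acc]])
            cat(sprintf("%d\t%daa, >%s... %s\n", j - 1L,
                        nchar(seqs[[acc]]), acc, tag), file = con)
        }
    }
    if (!is.null(mapPath)) {
        memb <- membership(clusters)
        utils::write.table(
            data.frame(accession = names(memb), representative = unname(memb)),
            mapPath, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(clstrPath)
}
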