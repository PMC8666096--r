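#' Simulate a discovery/verification cohort annotation table
#'
#' One row per sample with group label, demographics and a sample
#' processing time in days. Defaults mirror the discovery cohort
#' (7 SCI-positive, 8 SCI-negative children with sickle cell disease, 6
#' healthy controls); ages are drawn from the per-group means/SDs of that
#' cohort and processing time is uniform on 0..6 days. Covariates other
#' than `group` and `processing_days` are for realism only; no statistic
#' under test consumes them. The output is a pure function of the
#' arguments: identical calls give identical tables.
#'
#' @param nSciPos,nSciNeg,nControl non-negative group sizes (defaults
#'   7, 8, 6).
#' @param seed integer RNG seed.
#' @return data.frame: `sample_id`, `group`, `age_months`, `sex`,
#'   `wbc`, `processing_days`.
#' @export
simulateCohort <- function(nSciPos = 7, nSciNeg = 8, nControl = 6,
                           seed = 1) {
    stopIfNot(nSciPos >= 0 && nSciNeg >= 0 && nControl >= 0,
              "group sizes must be non-negative")
    withSeed(seed, {
        grp <- rep(c("sci_positive", "sci_negative", "control"),
                   c(nSciPos, nSciNeg, nControl))
        n <- length(grp)
        ageMean <- c(sci_positive = 9.8, sci_negative = 9.0,
                     control = 11.5) * 12
        ageSd <- c(sci_positive = 2.4, sci_negative = 3.1,
                   control = 2.1) * 12
        wbcMed <- c(sci_positive = 13, sci_negative = 12.8, control = 4.9)
        data.frame(
            sample_id = sprintf("S%03d", seq_len(n)),
            group = grp,
            age_months = if (n) round(pmax(
                stats::rnorm(n, ageMean[grp], ageSd[grp]), 12)) else integer(),
            sex = if (n) sample(c("M", "F"), n, replace = TRUE)
                  else character(),
            wbc = if (n) round(stats::rlnorm(n, log(wbcMed[grp]), 0.25), 1)
                  else numeric(),
            processing_days = if (n) sample(0:6, n, replace = TRUE)
                              else integer(),
            row.names = NULL)
    })
}

#' Simulate protein sequences with planted identity clusters
#'
#' Each cluster derives its members from a random founder sequence by
#' substituting at most `floor((1 - withinIdentity) / 2 * L)` positions, so
#' every *pairwise* within-cluster identity is at least `withinIdentity` by
#' the triangle bound. Founders are sampled uniformly over the 20-letter
#' alphabet, which keeps between-cluster identities far below 0.5 with
#' overwhelming probability (asserted in the test suite, not assumed).
#'
#' @param nClusters,variantsPerCluster counts (>= 1).
#' @param lengthRange founder length interval in residues (each >= 20).
#' @param withinIdentity minimum pairwise member identity, in `[0.9, 1]`
#'   (lower values would contradict the 90% redundancy threshold the
#'   planted truth is meant to exercise).
#' @param seed integer RNG seed.
#' @return list: `sequences` (named [Biostrings::AAStringSet]), `labels`
#'   (named character: accession -> planted cluster id).
#' @export
simulateSequences <- function(nClusters = 5, variantsPerCluster = 3,
                              lengthRange = c(100, 200),
                              withinIdentity = 0.95, seed = 1) {
    stopIfNot(withinIdentity >= 0.9 && withinIdentity <= 1,
              "withinIdentity must be in [0.9, 1]")
    stopIfNot(min(lengthRange) >= 20, "sequence lengths must be >= 20")
    alphabet <- setdiff(aaAlphabet(), "X")
    withSeed(seed, {
        seqs <- character(); labels <- character()
        for (k in seq_len(nClusters)) {
            L <- sample(lengthRange[1]:lengthRange[2], 1)
            founder <- sample(alphabet, L, replace = TRUE)
            maxMut <- floor((1 - withinIdentity) / 2 * L)
            for (v in seq_len(variantsPerCluster)) {
                s <- founder
                if (v > 1 && maxMut > 0) {
                    pos <- sample(L, maxMut)
                    for (p in pos)
                        s[p] <- sample(setdiff(alphabet, s[p]), 1)
                }
                acc <- sprintf("C%02dV%d", k, v)
                seqs[acc] <- paste(s, collapse = "")
                labels[acc] <- sprintf("C%02d", k)
            }
        }
        list(sequences = Biostrings::AAStringSet(seqs), labels = labels)
    })
}

#' Construct a planted-truth object
#'
#' Ground truth the synthetic generators embed and downstream stages are
#' expected to recover: the brain-enriched gene set, accessions restricted
#' to sickle-cell samples, the expected SCI-negative/SCI-positive
#' spectral-count ratio per protein, and the per-group assay concentration
#' medians (defaults 0.28 ng/mL for sickle-cell disease, 0.12 ng/mL for
#' controls).
#'
#' @param brainGenes character vector of planted brain-enriched genes.
#' @param scdOnly accessions never emitted for control samples.
#' @param foldMap named numeric vector (accession -> expected ratio, > 0).
#' @param assayGroupMedians named ng/mL medians per cohort group.
#' @return list of class `PlantedTruth`.
#' @export
plantedTruth <- function(brainGenes = character(),
                         scdOnly = character(),
                         foldMap = numeric(),
                         assayGroupMedians = c(sci_positive = 0.28,
                                               sci_negative = 0.28,
                                               control = 0.12)) {
    stopIfNot(all(foldMap > 0), "foldMap values must be positive")
    structure(list(brainGenes = brainGenes, scdOnly = scdOnly,
                   foldMap = foldMap,
                   assayGroupMedians = assayGroupMedians),
              class = "PlantedTruth")
}

#' Simulate a peptide-spectrum-match table
#'
#' Emits one row per spectrum. Per sample and protein, detection is
#' Bernoulli with a group-specific probability; a detected protein's
#' spectrum count is `1 + NB(mu - 1, size)` so its expected count over
#' detected samples equals `mu` exactly, where `mu` is the group mean
#' times the protein's planted fold factor (applied to the SCI-negative
#' group). PSM attributes (probability, Mowse score, charge) are drawn so
#' a configurable fraction of rows fails each acceptance rule; proteins in
#' the planted SCD-only set are never emitted for control samples.
#'
#' @param cohort cohort data.frame from [simulateCohort()].
#' @param proteins character vector of accessions.
#' @param truth a [plantedTruth()] object (`foldMap`, `scdOnly`).
#' @param detectionProb named per-group detection probabilities in `[0,1]`.
#' @param meanSC named per-group expected spectral count of a detected
#'   protein (before the fold factor).
#' @param dispersion negative-binomial size parameter (> 0); counts are
#'   overdispersed relative to Poisson, the standard spectral-count
#'   assumption.
#' @param failFrac fraction of rows planted to fail each of the
#'   probability, Mowse and charge rules (default 0).
#' @param peptidesPerProtein size of each protein's peptide repertoire.
#' @param seed integer RNG seed.
#' @return PSM data.frame (columns of [readPSMTable()]).
#' @export
simulatePSMTable <- function(cohort, proteins, truth = plantedTruth(),
                             detectionProb = c(sci_positive = 0.6,
                                               sci_negative = 0.6,
                                               control = 0.6),
                             meanSC = c(sci_positive = 8,
                                        sci_negative = 8,
                                        control = 8),
                             dispersion = 5, failFrac = 0,
                             peptidesPerProtein = 3, seed = 1) {
    stopIfNot(all(detectionProb >= 0 & detectionProb <= 1),
              "detection probabilities must be in [0, 1]")
    stopIfNot(dispersion > 0, "dispersion must be positive")
    withSeed(seed, {
        alphabet <- setdiff(aaAlphabet(), "X")
        peptides <- lapply(stats::setNames(proteins, proteins), function(p)
            vapply(seq_len(peptidesPerProtein), function(i)
                paste(sample(alphabet, sample(8:15, 1), replace = TRUE),
                      collapse = ""), character(1)))
        rows <- vector("list", 0)
        for (i in seq_len(nrow(cohort))) {
            smp <- cohort$sample_id[i]; grp <- cohort$group[i]
            for (p in proteins) {
                if (grp == "control" && p %in% truth$scdOnly) next
                if (stats::runif(1) > detectionProb[[grp]]) next
                fold <- if (grp == "sci_negative" && p %in% names(truth$foldMap))
                    truth$foldMap[[p]] else 1
                mu <- meanSC[[grp]] * fold
                n <- 1L + stats::rnbinom(1, mu = max(mu - 1, 1e-6),
                                         size = dispersion)
                fail <- function() stats::runif(n) < failFrac
                prob <- ifelse(fail(), stats::runif(n, 0.5, 0.95),
                               stats::runif(n, 0.9501, 1))
                mowse <- ifelse(fail(), stats::runif(n, 10, 35),
                                stats::runif(n, 35.5, 90))
                charge <- ifelse(fail(), 1L, sample(2:3, n, replace = TRUE))
                rows[[length(rows) + 1L]] <- data.frame(
                    sample_id = smp, accession = p,
                    peptide = sample(peptides[[p]], n, replace = TRUE),
                    charge = charge,
                    probability = round(prob, 4),
                    mowse = round(mowse, 1),
                    spectrum_id = sprintf("%s.%s.%04d", smp, p, seq_len(n)))
            }
        }
        if (!length(rows))
            return(data.frame(sample_id = character(),
                              accession = character(),
                              peptide = character(), charge = integer(),
                              probability = numeric(), mowse = numeric(),
                              spectrum_id = character()))
        do.call(rbind, rows)
    })
}

#' Simulate a three-source tissue expression compendium
#'
#' Builds microarray, EST and SAGE gene-by-tissue matrices over brain plus
#' `nOtherTissues` other tissues. Planted brain genes satisfy all three
#' enrichment criteria (microarray brain expression > 10x the non-brain
#' baseline; EST and SAGE tags in brain and fewer than two other tissues);
#' `partialGenes` satisfy only the microarray criterion; all remaining
#' genes are uniformly expressed and satisfy none.
#'
#' @param genes all gene symbols.
#' @param brainGenes planted fully brain-enriched genes (subset of
#'   `genes`).
#' @param partialGenes genes passing only the microarray rule; must not
#'   overlap `brainGenes`.
#' @param nOtherTissues number of non-brain tissues (default 27).
#' @param seed integer RNG seed.
#' @return a [TissueCompendium-class].
#' @export
simulateCompendium <- function(genes, brainGenes,
                               partialGenes = character(),
                               nOtherTissues = 27, seed = 1) {
    stopIfNot(nOtherTissues >= 1, "need at least one other tissue")
    if (length(intersect(brainGenes, partialGenes)))
        stop("planted and partial gene sets overlap", call. = FALSE)
    stopIfNot(all(c(brainGenes, partialGenes) %in% genes),
              "planted genes must be drawn from 'genes'")
    withSeed(seed, {
        tissues <- c("brain", sprintf("tissue%02d", seq_len(nOtherTissues)))
        G <- length(genes)
        base <- matrix(stats::runif(G * length(tissues), 8, 12), G,
                       dimnames = list(genes, tissues))
        ma <- base
        enriched <- union(brainGenes, partialGenes)
        ma[enriched, "brain"] <-
            ma[enriched, "brain"] * stats::runif(length(enriched), 20, 30)
        tagMatrix <- function() {
            m <- matrix(stats::rpois(G * length(tissues), 4) + 1L, G,
                        dimnames = list(genes, tissues))
            # restricted genes: tags in brain and at most one other tissue
            m[brainGenes, ] <- 0L
            m[brainGenes, "brain"] <- 5L
            if (length(brainGenes)) {
                oneOther <- sample(tissues[-1], length(brainGenes),
                                   replace = TRUE)
                keep <- stats::runif(length(brainGenes)) < 0.5
                for (i in which(keep)) m[brainGenes[i], oneOther[i]] <- 2L
            }
            m
        }
        TissueCompendium(microarray = ma, est = tagMatrix(),
                         sage = tagMatrix())
    })
}

#' Simulate immunoassay plates and standards
#'
#' Standards follow a known 4PL response over a factor-3 serial dilution
#' from 40 down to 0.055 ng/mL. Subject concentrations are log-normal
#' around the planted group median (log-sd defaults derived from the
#' reported group IQRs); a configurable fraction is planted between the
#' LOD and LLOQ and below the LOD. Duplicate signals are perturbed with
#' multiplicative Gaussian noise of coefficient `duplicateCV`.
#'
#' @param cohort cohort data.frame ( `sample_id`, `group`,
#'   `processing_days`).
#' @param truth a [plantedTruth()] with `assayGroupMedians` (ng/mL).
#' @param duplicateCV duplicate noise coefficient of variation for subject
#'   wells (>= 0).
#' @param standardCV signal noise coefficient for calibrator wells
#'   (default 0.02; calibrators are pipetted from one serial-dilution
#'   series and read with low technical noise).
#' @param lloq,lod assay limits in ng/mL (`lod < lloq`).
#' @param timepoints visit months (default 0 only).
#' @param sdLog named per-group log-sd of concentrations.
#' @param betweenLimitsFrac,belowLodFrac fractions of subject-visits
#'   planted in (lod, lloq) and at/below lod.
#' @param curveParams named list of true 4PL parameters.
#' @param seed integer RNG seed.
#' @return list: `plates` (data.frame for [processPlates()]), `standards`
#'   (duplicate signals per standard), `trueConcentration` (named by
#'   subject-visit), `curveParams`.
#' @export
simulateAssayPlates <- function(cohort, truth = plantedTruth(),
                                duplicateCV = 0.08, standardCV = 0.02,
                                lloq = 0.039,
                                lod = 0.012, timepoints = 0,
                                sdLog = c(sci_positive = 1.5,
                                          sci_negative = 1.5,
                                          control = 0.4),
                                betweenLimitsFrac = 0, belowLodFrac = 0,
                                curveParams = list(lower = 60,
                                                   upper = 32000,
                                                   inflection = 2.5,
                                                   slope = 1.1),
                                seed = 1) {
    stopIfNot(lod < lloq, "lod must be below lloq")
    stopIfNot(duplicateCV >= 0 && standardCV >= 0,
              "noise coefficients must be >= 0")
    withSeed(seed, {
        cp <- curveParams
        stdConc <- 40 / 3^(0:6)  # serial 1:3 dilution, 40 -> 0.055 ng/mL
        noisy <- function(x, cv = duplicateCV) {
            y <- fourPL(x, cp$lower, cp$upper, cp$inflection, cp$slope)
            y * (1 + stats::rnorm(length(y), 0, cv))
        }
        stdCV <- if (duplicateCV == 0) 0 else standardCV
        standards <- data.frame(
            concentration = rep(stdConc, each = 2),
            signal = as.vector(rbind(noisy(stdConc, stdCV),
                                     noisy(stdConc, stdCV))))
        grid <- expand.grid(i = seq_len(nrow(cohort)),
                            visit_month = timepoints)
        n <- nrow(grid)
        grp <- cohort$group[grid$i]
        med <- truth$assayGroupMedians[grp]
        conc <- stats::rlnorm(n, log(med), sdLog[grp])
        planted <- sample(c("none", "between", "below"), n, replace = TRUE,
                          prob = c(1 - betweenLimitsFrac - belowLodFrac,
                                   betweenLimitsFrac, belowLodFrac))
        conc[planted == "between"] <- stats::runif(sum(planted == "between"),
                                                   lod * 1.05, lloq * 0.95)
        conc[planted == "below"] <- stats::runif(sum(planted == "below"),
                                                 lod * 0.1, lod * 0.8)
        plates <- data.frame(
            subject_id = cohort$sample_id[grid$i],
            group = grp,
            visit_month = grid$visit_month,
            dup_signal_1 = noisy(conc),
            dup_signal_2 = noisy(conc),
            processing_days = cohort$processing_days[grid$i],
            row.names = NULL)
        names(conc) <- paste(plates$subject_id, plates$visit_month,
                             sep = ".")
        list(plates = plates, standards = standards,
             trueConcentration = conc, curveParams = cp)
    })
}

#' Simulate the complete study input bundle
#'
#' Convenience wrapper producing every input the pipeline consumes with a
#' shared planted truth: cohort annotations, clustered protein sequences,
#' PSM table, tissue compendium, accession-to-gene map and immunoassay
#' plates. Component seeds are derived deterministically from `seed`.
#'
#' @param seed integer RNG seed.
#' @param nSciPos,nSciNeg,nControl discovery cohort sizes (defaults
#'   7/8/6).
#' @param nClusters,variantsPerCluster sequence-set shape.
#' @param nGenes compendium size; the first `nBrainGenes` planted.
#' @param nBrainGenes number of planted brain-enriched genes.
#' @param foldMap named expected spectral-count ratios (accession ->
#'   SCI-negative / SCI-positive).
#' @param ... further arguments forwarded to [simulatePSMTable()].
#' @return list: `cohort`, `sequences`, `labels`, `psms`, `compendium`,
#'   `accessionToGene`, `plates`, `standards`, `truth`.
#' @export
simulateStudy <- function(seed = 1, nSciPos = 7, nSciNeg = 8, nControl = 6,
                          nClusters = 12, variantsPerCluster = 2,
                          nGenes = 40, nBrainGenes = 8,
                          foldMap = NULL, ...) {
    cohort <- simulateCohort(nSciPos, nSciNeg, nControl, seed = seed)
    sq <- simulateSequences(nClusters, variantsPerCluster,
                            withinIdentity = 0.95, seed = seed + 1)
    reps <- unique(sq$labels)
    accs <- names(sq$labels)
    genes <- sprintf("GENE%03d", seq_len(nGenes))
    brainGenes <- genes[seq_len(nBrainGenes)]
    # representatives map onto the gene universe; planted brain genes first
    geneOf <- stats::setNames(genes[seq_along(reps)], reps)
    accessionToGene <- data.frame(accession = accs,
                                  gene = unname(geneOf[sq$labels]))
    if (is.null(foldMap)) {
        # whole planted clusters carry the fold so collapsed evidence
        # preserves the expected ratio
        up <- accs[sq$labels == reps[min(2, length(reps))]]
        dn <- accs[sq$labels == reps[min(3, length(reps))]]
        foldMap <- stats::setNames(c(rep(6.5, length(up)),
                                     rep(0.5, length(dn))), c(up, dn))
    }
    scdOnly <- accs[sq$labels == reps[1]]
    truth <- plantedTruth(brainGenes = brainGenes, scdOnly = scdOnly,
                          foldMap = foldMap)
    psms <- simulatePSMTable(cohort, accs, truth, seed = seed + 2, ...)
    compendium <- simulateCompendium(genes, brainGenes, seed = seed + 3)
    assay <- simulateAssayPlates(cohort, truth, seed = seed + 4)
    list(cohort = cohort, sequences = sq$sequences, labels = sq$labels,
         psms = psms, compendium = compendium,
         accessionToGene = accessionToGene,
         plates = assay$plates, standards = assay$standards, truth = truth)
}
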