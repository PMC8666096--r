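test_that("cohort generator honours group sizes, seed and empty case", {
    co <- simulateCohort(7, 8, 6, seed = 1)
    expect_equal(nrow(co), 21)
    expect_equal(as.integer(table(co$group)[c("sci_positive",
                                              "sci_negative", "control")]),
                 c(7L, 8L, 6L))
    expect_true(all(co$processing_days %in% 0:6))
    expect_identical(co, simulateCohort(7, 8, 6, seed = 1))
    expect_false(identical(co, simulateCohort(7, 8, 6, seed = 2)))
    expect_equal(nrow(simulateCohort(0, 0, 0, seed = 1)), 0)
    expect_error(simulateCohort(-1, 8, 6), "non-negative")
})

test_that("sequence generator plants clusters with guaranteed identities", {
    sq <- simulateSequences(5, 3, c(100, 200), withinIdentity = 0.95,
                            seed = 7)
    expect_length(sq$sequences, 15)
    expect_length(unique(sq$labels), 5)
    seqs <- as.character(sq$sequences)
    # pairwise within-cluster identity at or above the configured floor
    for (cl in unique(sq$labels)) {
        mem <- names(sq$labels)[sq$labels == cl]
        for (i in seq_along(mem)) for (j in seq_len(i - 1))
            expect_gte(sequenceIdentity(seqs[[mem[i]]], seqs[[mem[j]]]),
                       0.95)
    }
    # between-cluster identity far below the clustering threshold
    reps <- names(sq$labels)[!duplicated(sq$labels)]
    for (i in seq_along(reps)) for (j in seq_len(i - 1))
        expect_lt(sequenceIdentity(seqs[[reps[i]]], seqs[[reps[j]]]), 0.5)
    expect_error(simulateSequences(2, 2, withinIdentity = 0.8),
                 "withinIdentity")
    sing <- simulateSequences(4, 1, seed = 3)
    expect_length(unique(sing$labels), 4)
})

test_that("PSM generator respects planted structure", {
    co <- simulateCohort(4, 4, 4, seed = 2)
    truth <- plantedTruth(scdOnly = "P1",
                          foldMap = c(P2 = 2))
    psms <- simulatePSMTable(co, c("P1", "P2", "P3"), truth,
                             detectionProb = c(sci_positive = 1,
                                               sci_negative = 1,
                                               control = 1),
                             seed = 5)
    ctrl <- co$sample_id[co$group == "control"]
    expect_equal(sum(psms$accession == "P1" & psms$sample_id %in% ctrl), 0)
    expect_identical(psms, simulatePSMTable(co, c("P1", "P2", "P3"), truth,
                                            detectionProb = c(
                                                sci_positive = 1,
                                                sci_negative = 1,
                                                control = 1),
                                            seed = 5))
    expect_error(simulatePSMTable(co, "P1", truth, dispersion = 0),
                 "dispersion")
})

test_that("planted spectral-count fold is recovered by Monte Carlo", {
    co <- simulateCohort(8, 8, 0, seed = 3)
    truth <- plantedTruth(foldMap = c(PX = 6.5))
    avgs <- vapply(1:200, function(r) {
        psms <- simulatePSMTable(co, "PX", truth,
                                 detectionProb = c(sci_positive = 1,
                                                   sci_negative = 1,
                                                   control = 1),
                                 meanSC = c(sci_positive = 8,
                                            sci_negative = 8,
                                            control = 8),
                                 seed = 1000 + r)
        ev <- assembleProteins(psms, samples = co$sample_id,
                               colData = S4Vectors::DataFrame(
                                   group = co$group,
                                   row.names = co$sample_id))
        c(averageSC(ev, "sci_negative")[["PX"]],
          averageSC(ev, "sci_positive")[["PX"]])
    }, numeric(2))
    # ratio of Monte-Carlo mean group averages estimates the planted fold
    expect_equal(mean(avgs[1, ]) / mean(avgs[2, ]), 6.5, tolerance = 0.03)
})

test_that("null fold and full detection give ratio near 1", {
    co <- simulateCohort(8, 8, 0, seed = 4)
    avgs <- vapply(1:100, function(r) {
        psms <- simulatePSMTable(co, "PN", plantedTruth(),
                                 detectionProb = c(sci_positive = 1,
                                                   sci_negative = 1,
                                                   control = 1),
                                 meanSC = c(sci_positive = 20,
                                            sci_negative = 20,
                                            control = 20),
                                 seed = 2000 + r)
        ev <- assembleProteins(psms, samples = co$sample_id,
                               colData = S4Vectors::DataFrame(
                                   group = co$group,
                                   row.names = co$sample_id))
        c(averageSC(ev, "sci_negative")[["PN"]],
          averageSC(ev, "sci_positive")[["PN"]])
    }, numeric(2))
    expect_equal(mean(avgs[1, ]) / mean(avgs[2, ]), 1, tolerance = 0.03)
})

test_that("compendium plants full, partial and null enrichment", {
    genes <- sprintf("G%02d", 1:20)
    comp <- simulateCompendium(genes, brainGenes = genes[1:5],
                               partialGenes = genes[6:8], seed = 9)
    sc <- brainScores(comp)
    expect_true(all(sc$total[match(genes[1:5], sc$gene)] == 3))
    expect_true(all(sc$total[match(genes[6:8], sc$gene)] == 1))
    expect_true(all(sc$microarray[match(genes[6:8], sc$gene)] == 1))
    expect_true(all(sc$total[match(genes[9:20], sc$gene)] == 0))
    expect_error(simulateCompendium(genes, genes[1:3],
                                    partialGenes = genes[3:4]),
                 "overlap")
})

test_that("assay plate generator: standards, duplicates, censoring", {
    co <- simulateCohort(5, 5, 5, seed = 6)
    pl <- simulateAssayPlates(co, duplicateCV = 0, seed = 6)
    # factor-3 serial dilution spans 40 down to ~0.055 ng/mL
    conc <- sort(unique(pl$standards$concentration))
    expect_equal(max(conc), 40)
    expect_equal(min(conc), 40 / 3^6, tolerance = 1e-12)
    expect_equal(min(conc), 0.055, tolerance = 0.01)
    means <- tapply(pl$standards$signal, pl$standards$concentration, mean)
    expect_true(all(diff(means[order(as.numeric(names(means)))]) > 0))
    # zero duplicate noise -> identical duplicates -> CV exactly 0
    expect_equal(pl$plates$dup_signal_1, pl$plates$dup_signal_2)
    expect_error(simulateAssayPlates(co, lloq = 0.01, lod = 0.02),
                 "lod")
    pl2 <- simulateAssayPlates(co, duplicateCV = 0, seed = 6)
    expect_identical(pl, pl2)
})
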