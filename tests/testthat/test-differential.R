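test_that("detection sets follow SC > 0 in at least one group sample", {
    counts <- matrix(c(2L, 0L, 0L,   0L, 0L, 0L,   0L, 3L, 0L,
                       0L, 0L, 1L), nrow = 3,
                     dimnames = list(c("P1", "P2", "P3"),
                                     c("p1", "p2", "n1", "c1")))
    ev <- makeEvidence(counts, c("sci_positive", "sci_positive",
                                 "sci_negative", "control"))
    det <- detectionSets(ev)
    expect_equal(det$sci_positive, "P1")
    expect_equal(det$sci_negative, "P2")
    expect_equal(det$control, "P3")
    empty <- makeEvidence(counts[0, , drop = FALSE],
                          c("sci_positive", "sci_positive",
                            "sci_negative", "control"),
                          nPeptides = integer())
    expect_true(all(lengths(detectionSets(empty)) == 0))
    ev2 <- makeEvidence(counts, c("sci_positive", NA, "sci_negative",
                                  "control"))
    expect_error(detectionSets(ev2), "annotated")
})

test_that("venn partition is exact on disjoint sets and conserves the union", {
    v <- vennPartition("a", "b", "c")
    expect_equal(unname(v$regions[c("pos_only", "neg_only",
                                    "control_only")]), c(1, 1, 1))
    expect_equal(sum(v$regions), 3)
    set.seed(13)
    for (i in 1:25) {
        u <- sprintf("x%02d", 1:40)
        sp <- sample(u, sample(0:30, 1))
        sn <- sample(u, sample(0:30, 1))
        sc <- sample(u, sample(0:30, 1))
        v <- vennPartition(sp, sn, sc)
        expect_equal(sum(v$regions), length(unique(c(sp, sn, sc))))
        expect_equal(v$scdTotal, length(unique(c(sp, sn))))
    }
})

test_that("published region counts give the published percentages", {
    sets <- vennSetsFromCounts(referenceVennCounts())
    v <- vennPartition(sets$setPos, sets$setNeg, sets$setControl)
    expect_equal(v$scdTotal, 1172)
    expect_equal(unname(v$percentages["uniquePos"]), 25)
    expect_equal(unname(v$percentages["uniqueNeg"]), 29)
    expect_equal(unname(v$percentages["commonScd"]), 13)
    expect_equal(unname(v$regions["control_only"]), 239)
})

test_that("average SC is the mean over detected samples", {
    counts <- matrix(0L, 2, 8,
                     dimnames = list(c("P", "Q"), sprintf("n%d", 1:8)))
    counts["P", 1:7] <- c(52L, 52L, 52L, 52L, 52L, 52L, 51L)  # sums to 363
    counts["Q", 1] <- 4L
    ev <- makeEvidence(counts, rep("sci_negative", 8))
    expect_equal(unname(averageSC(ev, "sci_negative")["P"]), 363 / 7)
    expect_equal(roundHalfUp(averageSC(ev, "sci_negative")[["P"]], 1), 51.9)
    expect_equal(unname(averageSC(ev, "sci_negative")["Q"]), 4)
    # never detected -> 0; over-all-samples variant divides by group size
    counts2 <- rbind(counts, R = 0L)
    ev2 <- makeEvidence(counts2, rep("sci_negative", 8))
    expect_equal(unname(averageSC(ev2, "sci_negative")["R"]), 0)
    expect_equal(unname(averageSC(ev2, "sci_negative",
                                  overAllSamples = TRUE)["P"]), 363 / 8)
})

test_that("fold screen rounds before thresholding and handles zeros", {
    rec <- data.frame(accession = c("T3", "FGG", "EQ", "DIV", "NONE"),
                      n_detected_neg = c(7, 8, 5, 3, 2),
                      n_detected_pos = c(3, 7, 5, 2, 2),
                      avg_sc_neg = c(51.9, 92.1, 10, 6, 0),
                      avg_sc_pos = c(8.0, 185.9, 10, 0, 0))
    out <- foldChangeScreen(rec)
    expect_equal(out$ratio[1:3], c(6.5, 0.5, 1.0))
    expect_equal(out$passes[1:3], c(TRUE, TRUE, FALSE))
    expect_equal(out$ratio[4], Inf)   # zero denominator, passes high side
    expect_true(out$passes[4])
    expect_false(out$passes[5])       # never detected
    # detection floor: below minSamples fails regardless of ratio
    rec2 <- data.frame(accession = "X", n_detected_neg = 1,
                       n_detected_pos = 5, avg_sc_neg = 50,
                       avg_sc_pos = 5)
    expect_false(foldChangeScreen(rec2)$passes)
    expect_error(foldChangeScreen(rec, highCut = 2, lowCut = 0.4),
                 "lowCut")
})

test_that("boundary ratios round onto the screen thresholds", {
    rec <- data.frame(accession = c("AMI", "HALF"),
                      n_detected_neg = c(8, 8), n_detected_pos = c(7, 7),
                      avg_sc_neg = c(305.0, 92.1),
                      avg_sc_pos = c(153.0, 185.9))
    out <- foldChangeScreen(rec)
    expect_equal(out$ratio, c(2.0, 0.5))  # 1.9935 and 0.4954 before rounding
    expect_true(all(out$passes))
})

test_that("swapping group labels inverts ratios and preserves the passing set", {
    set.seed(29)
    for (i in 1:20) {
        n <- 15
        rec <- data.frame(accession = sprintf("P%02d", 1:n),
                          n_detected_neg = sample(0:8, n, TRUE),
                          n_detected_pos = sample(0:8, n, TRUE),
                          avg_sc_neg = round(runif(n, 1, 300), 1),
                          avg_sc_pos = round(runif(n, 1, 300), 1))
        # high precision keeps rounding out of the algebraic property
        fwd <- foldChangeScreen(rec, roundDigits = 8)
        swapped <- data.frame(accession = rec$accession,
                              n_detected_neg = rec$n_detected_pos,
                              n_detected_pos = rec$n_detected_neg,
                              avg_sc_neg = rec$avg_sc_pos,
                              avg_sc_pos = rec$avg_sc_neg)
        rev <- foldChangeScreen(swapped, roundDigits = 8)
        expect_equal(rev$ratio, 1 / fwd$ratio, tolerance = 1e-6)
        expect_equal(rev$passes, fwd$passes)
    }
})
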