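truePars <- list(lower = 60, upper = 32000, inflection = 2.5, slope = 1.1)
stdConc <- 40 / 3^(0:6)

cleanStandards <- function() {
    sig <- fourPL(stdConc, truePars$lower, truePars$upper,
                  truePars$inflection, truePars$slope)
    data.frame(concentration = rep(stdConc, each = 2),
               signal = rep(sig, each = 2))
}

test_that("4PL forward/inverse round-trip and fixed points", {
    p <- truePars
    x <- c(0.06, 0.5, 1, 5, 38)
    y <- fourPL(x, p$lower, p$upper, p$inflection, p$slope)
    expect_equal(fourPLInverse(y, p$lower, p$upper, p$inflection, p$slope),
                 x, tolerance = 1e-9)
    # signal at the inflection -> concentration equals the inflection
    mid <- (p$lower + p$upper) / 2
    expect_equal(fourPLInverse(mid, p$lower, p$upper, p$inflection,
                               p$slope), p$inflection, tolerance = 1e-12)
    expect_true(is.na(fourPLInverse(p$lower, p$lower, p$upper,
                                    p$inflection, p$slope)))
})

test_that("calibration fit recovers generating parameters from clean data", {
    curve <- fitCalibration(cleanStandards())
    expect_equal(curve@lower, truePars$lower, tolerance = 1e-6)
    expect_equal(curve@upper, truePars$upper, tolerance = 1e-6)
    expect_equal(curve@inflection, truePars$inflection, tolerance = 1e-6)
    expect_equal(curve@slope, truePars$slope, tolerance = 1e-6)
    # fitted curve monotone over the standard range
    grid <- exp(seq(log(0.055), log(40), length.out = 50))
    fit <- fourPL(grid, curve@lower, curve@upper, curve@inflection,
                  curve@slope)
    expect_true(all(diff(fit) > 0))
    # back-calculated interior standards within 20% recovery
    back <- backCalculate(fourPL(stdConc[2:6], curve@lower, curve@upper,
                                 curve@inflection, curve@slope), curve)
    expect_true(all(abs(back / stdConc[2:6] - 1) < 0.2))
    bad <- cleanStandards()
    bad$signal <- rev(bad$signal)
    expect_error(fitCalibration(bad), "monotone")
    expect_error(fitCalibration(cleanStandards()[1:4, ]), "5 distinct")
})

test_that("back-calculation flags signals outside the asymptotes", {
    curve <- fitCalibration(cleanStandards())
    res <- backCalculate(c(curve@lower, 5000, curve@upper + 1), curve)
    expect_equal(attr(res, "flag"),
                 c("below_range", "ok", "above_range"))
    expect_true(is.na(res[1]) && is.na(res[3]))
    expect_equal(fourPL(res[2], curve@lower, curve@upper,
                        curve@inflection, curve@slope), 5000,
                 tolerance = 1e-6)
})

test_that("duplicate QC flags CV above the threshold, strictly", {
    qc <- qcDuplicates(0.30, 0.30)
    expect_equal(qc$cvPercent, 0)
    expect_equal(qc$mean, 0.30)
    expect_false(qc$repeatRequired)
    # CV ~ 28% -> repeat; exactly at the threshold -> no repeat
    hi <- qcDuplicates(1.2, 0.8)
    expect_gt(hi$cvPercent, 20)
    expect_true(hi$repeatRequired)
    at <- qcDuplicates(1.2, 0.8, cvThreshold = hi$cvPercent)
    expect_false(at$repeatRequired)
    just <- qcDuplicates(1.2, 0.8, cvThreshold = hi$cvPercent - 1e-9)
    expect_true(just$repeatRequired)
    expect_true(qcDuplicates(0, 0)$invalid)
})

test_that("censoring applies the half-LLOQ rule and is idempotent", {
    out <- censorImpute(c(0.25, 0.020, 0.039, 0.012, 0.005))
    expect_equal(out$concentration[1], 0.25)
    expect_equal(out$censorState[1], "quantified")
    expect_equal(out$concentration[2], 0.039 / 2)  # 0.0195 exactly
    expect_equal(out$censorState[2], "between_lod_lloq")
    expect_equal(out$concentration[3], 0.039)      # at LLOQ: quantified
    expect_equal(out$censorState[3], "quantified")
    expect_equal(out$censorState[4], "below_lod")  # at LOD
    expect_equal(out$concentration[5], 0.012 / 2)
    excl <- censorImpute(0.005, belowLodPolicy = "exclude")
    expect_true(is.na(excl$concentration))
    inv <- censorImpute(-0.1)
    expect_equal(inv$censorState, "invalid")
    set.seed(43)
    x <- c(runif(50, 0, 0.1), 0.039, 0.012, 0.0195)
    once <- censorImpute(x)
    twice <- censorImpute(once$concentration)
    expect_equal(twice$concentration, once$concentration)
    expect_equal(twice$censorState, once$censorState)
})

test_that("rank-sum comparison matches brute-force U and quantile reporting", {
    a <- c(1.3, 2.1, 0.7); b <- c(0.2, 1.9, 3.4)
    cmp <- compareGroups(a, b)
    expect_equal(cmp$statistic, bruteForceU(a, b))
    expect_equal(unname(cmp$median), c(median(a), median(b)))
    expect_equal(unname(cmp$q25),
                 unname(c(quantile(a, 0.25), quantile(b, 0.25))))
    set.seed(47)
    for (i in 1:10) {
        x <- round(runif(sample(4:9, 1), 0, 5), 2)
        y <- round(runif(sample(4:9, 1), 0, 5), 2)
        expect_equal(compareGroups(x, y)$statistic, bruteForceU(x, y))
    }
    same <- compareGroups(c(1, 2, 3, 4), c(1, 2, 3, 4))
    expect_equal(same$p.value, 1)
    expect_equal(diff(unname(same$median)), 0)
    expect_error(compareGroups(1, c(1, 2)), "two values")
})

test_that("rank-sum test is invariant under monotone transforms", {
    set.seed(53)
    x <- rlnorm(12, log(0.28), 1.5); y <- rlnorm(8, log(0.12), 0.4)
    base <- compareGroups(x, y)
    for (f in list(log, sqrt, function(v) 3 * v + 1)) {
        tr <- compareGroups(f(x), f(y))
        expect_equal(tr$statistic, base$statistic)
        expect_equal(tr$p.value, base$p.value)
    }
})

test_that("Spearman association matches Pearson on ranks", {
    expect_equal(spearmanAssoc(1:6, c(2, 4, 9, 11, 30, 31))$rho, 1)
    expect_equal(spearmanAssoc(1:6, -(1:6))$rho, -1)
    set.seed(59)
    for (i in 1:10) {
        x <- runif(8); y <- runif(8)
        expect_equal(spearmanAssoc(x, y)$rho,
                     cor(rank(x), rank(y)), tolerance = 1e-12)
    }
    expect_warning(r <- spearmanAssoc(rep(1, 5), 1:5), "constant")
    expect_true(is.na(r$rho))
})

test_that("processing-time filter withholds 4 days or greater", {
    df <- data.frame(subject_id = 1:4,
                     processing_days = c(3, 4, 6, NA))
    expect_warning(kept <- sensitivityFilter(df), "without processing")
    expect_equal(kept$subject_id, c(1, 4))
    expect_equal(nrow(sensitivityFilter(df[0, ])), 0)
})

test_that("plate processing recovers planted concentrations and QC flags", {
    co <- simulateCohort(10, 10, 8, seed = 61)
    sim <- simulateAssayPlates(co, duplicateCV = 0.05,
                               betweenLimitsFrac = 0.1, seed = 61,
                               lloq = 0.039, lod = 0.012)
    proc <- processPlates(sim$plates, sim$standards,
                          lloq = 0.039, lod = 0.012)
    m <- proc$measurements
    expect_equal(nrow(m), nrow(sim$plates))
    # quantified measurements track the planted true concentrations
    q <- m$censorState == "quantified"
    expect_gt(sum(q), 10)
    expect_equal(m$concentration[q],
                 unname(sim$trueConcentration[q]), tolerance = 0.2)
    # censored values sit at exactly half the LLOQ
    btw <- m$censorState == "between_lod_lloq"
    expect_true(all(m$concentration[btw] == 0.039 / 2))
    # zero-noise duplicates never trigger the repeat rule
    sim0 <- simulateAssayPlates(co, duplicateCV = 0, seed = 62)
    proc0 <- processPlates(sim0$plates, sim0$standards)
    expect_true(all(proc0$measurements$cvPercent[
        !is.na(proc0$measurements$cvPercent)] < 1e-6))
    expect_false(any(proc0$measurements$repeatRequired))
})
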