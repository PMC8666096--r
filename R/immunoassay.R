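#' Four-parameter logistic response and its inverse
#'
#' Increasing sandwich-immunoassay signal model
#' `y = lower + (upper - lower) / (1 + (x / inflection)^(-slope))`:
#' `fourPL()` maps analyte concentration to signal, `fourPLInverse()`
#' back-calculates concentration from signal (closed form). The inverse is
#' defined for signals strictly between the asymptotes.
#'
#' @param x concentration (ng/mL), non-negative.
#' @param y signal.
#' @param lower,upper,inflection,slope 4PL parameters (see
#'   [CalibrationCurve-class]).
#' @return numeric vector; `fourPLInverse()` gives `NA` outside the open
#'   signal range.
#' @export
fourPL <- function(x, lower, upper, inflection, slope) {
    lower + (upper - lower) / (1 + (x / inflection)^(-slope))
}

#' @rdname fourPL
#' @export
fourPLInverse <- function(y, lower, upper, inflection, slope) {
    out <- rep(NA_real_, length(y))
    ok <- y > lower & y < upper
    out[ok] <- inflection * ((y[ok] - lower) / (upper - y[ok]))^(1 / slope)
    out
}

#' Fit a four-parameter logistic calibration curve
#'
#' Least-squares 4PL fit (Levenberg-Marquardt) to a standards table, e.g. a
#' factor-3 serial dilution spanning 40 down to 0.055 ng/mL. Mean signal
#' must increase with standard concentration, otherwise the fit is refused.
#'
#' @param standards data.frame with columns `concentration` (ng/mL, > 0)
#'   and `signal`; duplicate rows per concentration are averaged for the
#'   monotonicity check but all points enter the fit.
#' @param lloq,lod assay limits of quantification/detection attached to the
#'   curve (defaults 0.039 and 0.012 ng/mL).
#' @return a [CalibrationCurve-class] object.
#' @export
fitCalibration <- function(standards, lloq = 0.039, lod = 0.012) {
    stopIfNot(all(c("concentration", "signal") %in% colnames(standards)),
              "standards need 'concentration' and 'signal' columns")
    stopIfNot(length(unique(standards$concentration)) >= 5,
              "need at least 5 distinct standard concentrations")
    stopIfNot(all(standards$concentration > 0),
              "standard concentrations must be positive")
    means <- tapply(standards$signal, standards$concentration, mean)
    conc <- as.numeric(names(means))
    means <- means[order(conc)]
    if (any(diff(means) <= 0))
        stop("standard signals are not monotone increasing in concentration",
             call. = FALSE)
    start <- list(lower = min(standards$signal),
                  upper = max(standards$signal) * 1.05,
                  inflection = exp(mean(log(standards$concentration))),
                  slope = 1)
    fit <- minpack.lm::nlsLM(
        signal ~ fourPL(concentration, lower, upper, inflection, slope),
        data = standards, start = start,
        lower = c(-Inf, -Inf, 1e-12, 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    p <- as.list(stats::coef(fit))
    new("CalibrationCurve", lower = p$lower, upper = p$upper,
        inflection = p$inflection, slope = p$slope, lloq = lloq, lod = lod,
        standards = data.frame(concentration = standards$concentration,
                               signal = standards$signal))
}

#' Back-calculate concentration from signal
#'
#' Closed-form inverse of the fitted 4PL. Signals at or below the lower
#' asymptote, or at or above the upper asymptote, cannot be inverted and
#' yield `NA` with a per-element `flag` attribute (`"ok"`,
#' `"below_range"`, `"above_range"`).
#'
#' @param signal numeric vector of signals.
#' @param curve a [CalibrationCurve-class].
#' @return concentration vector (ng/mL) with a `flag` attribute.
#' @export
backCalculate <- function(signal, curve) {
    conc <- fourPLInverse(signal, curve@lower, curve@upper,
                          curve@inflection, curve@slope)
    flag <- rep("ok", length(signal))
    flag[signal <= curve@lower] <- "below_range"
    flag[signal >= curve@upper] <- "above_range"
    attr(conc, "flag") <- flag
    conc
}

#' Duplicate-well quality control
#'
#' Averages back-calculated duplicate concentrations and computes their
#' CV% (100 x sd / mean). Pairs with CV% strictly greater than the
#' threshold are flagged for repeat assay; pairs with a non-positive mean
#' are flagged invalid. A below-range duplicate (`NA`) is treated as zero
#' concentration.
#'
#' @param conc1,conc2 numeric vectors of duplicate concentrations.
#' @param cvThreshold CV% threshold, strict (default 20).
#' @return data.frame: `mean`, `cvPercent`, `repeatRequired`, `invalid`.
#' @export
qcDuplicates <- function(conc1, conc2, cvThreshold = 20) {
    conc1 <- ifelse(is.na(conc1), 0, conc1)
    conc2 <- ifelse(is.na(conc2), 0, conc2)
    m <- (conc1 + conc2) / 2
    s <- abs(conc1 - conc2) / sqrt(2)  # sd of two values
    cv <- ifelse(m > 0, 100 * s / m, NA_real_)
    data.frame(mean = m, cvPercent = cv,
               repeatRequired = !is.na(cv) & cv > cvThreshold,
               invalid = m <= 0)
}

#' Limit-of-quantification censoring
#'
#' Concentrations at or above the LLOQ are reported as quantified;
#' values between LOD and LLOQ are recorded as half the LLOQ
#' (`between_lod_lloq`); values at or below the LOD are recorded per
#' `belowLodPolicy`: half the LOD (default, keeps the sample) or excluded
#' (`NA`). Negative inputs are flagged invalid. The operation is
#' idempotent.
#'
#' @param concentration numeric vector (ng/mL).
#' @param lloq,lod assay limits (defaults 0.039, 0.012; `lod < lloq`).
#' @param belowLodPolicy `"half_lod"` (default) or `"exclude"`.
#' @return data.frame: `concentration`, `censorState` (one of
#'   `quantified`, `between_lod_lloq`, `below_lod`, `invalid`).
#' @examples
#' censorImpute(c(0.25, 0.020, 0.005))
#' @export
censorImpute <- function(concentration, lloq = 0.039, lod = 0.012,
                         belowLodPolicy = c("half_lod", "exclude")) {
    stopIfNot(lod < lloq, "lod must be below lloq")
    belowLodPolicy <- match.arg(belowLodPolicy)
    st <- ifelse(is.na(concentration) | concentration < 0, "invalid",
          ifelse(concentration >= lloq, "quantified",
          ifelse(concentration > lod, "between_lod_lloq", "below_lod")))
    out <- concentration
    out[st == "between_lod_lloq"] <- lloq / 2
    out[st == "below_lod"] <- if (belowLodPolicy == "half_lod") lod / 2
                              else NA_real_
    out[st == "invalid"] <- NA_real_
    data.frame(concentration = out, censorState = st)
}

#' Nonparametric two-group comparison
#'
#' Medians, 25th/75th percentiles (linear-interpolation quantiles) and a
#' two-sided Wilcoxon rank-sum test ([stats::wilcox.test()]; exact for
#' small untied samples, normal approximation with tie correction
#' otherwise). The convention matches reporting concentrations as
#' median (25-75% IQR).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param labels group labels for the report.
#' @return list: `n`, `median`, `q25`, `q75` (each named by group),
#'   `statistic` (Mann-Whitney U for `a` vs `b`), `p.value`.
#' @export
compareGroups <- function(a, b, labels = c("a", "b")) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    stopIfNot(length(a) >= 2 && length(b) >= 2,
              "each group needs at least two values")
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL,
                                              correct = TRUE))
    q <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), type = 7,
                                     names = FALSE)
    qa <- q(a); qb <- q(b)
    list(n = stats::setNames(c(length(a), length(b)), labels),
         median = stats::setNames(c(qa[2], qb[2]), labels),
         q25 = stats::setNames(c(qa[1], qb[1]), labels),
         q75 = stats::setNames(c(qa[3], qb[3]), labels),
         statistic = unname(wt$statistic),
         p.value = wt$p.value)
}

#' Spearman rank correlation
#'
#' Rank-based correlation with average ranks for ties and the asymptotic
#' t approximation for the p-value. Constant input is undefined and
#' returns `NA` with a warning.
#'
#' @param x,y paired numeric vectors, length >= 3.
#' @return list: `rho`, `p.value`, `n`.
#' @export
spearmanAssoc <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    stopIfNot(length(x) >= 3, "need at least 3 complete pairs")
    if (length(unique(x)) < 2 || length(unique(y)) < 2) {
        warning("constant input: Spearman correlation undefined",
                call. = FALSE)
        return(list(rho = NA_real_, p.value = NA_real_, n = length(x)))
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    list(rho = unname(ct$estimate), p.value = ct$p.value, n = length(x))
}

#' Processing-time sensitivity filter
#'
#' Retains measurements whose sample processing time was strictly below
#' `maxDays`; samples processed over `maxDays` days or greater are
#' withheld. Rows with missing processing time are retained with a
#' warning.
#'
#' @param measurements data.frame with a `processing_days` column.
#' @param maxDays withholding threshold in days (default 4).
#' @return the retained subset.
#' @export
sensitivityFilter <- function(measurements, maxDays = 4) {
    if (!nrow(measurements)) return(measurements)
    d <- measurements$processing_days
    if (anyNA(d))
        warning(sum(is.na(d)), " measurement(s) without processing time",
                " retained", call. = FALSE)
    measurements[is.na(d) | d < maxDays, , drop = FALSE]
}

#' Process immunoassay plates end to end
#'
#' Fits the calibration curve from the standards, back-calculates both
#' duplicate signals for every subject-visit, applies duplicate CV% QC,
#' and censors at the assay limits.
#'
#' @param plates data.frame: `subject_id`, `group`, `visit_month`,
#'   `dup_signal_1`, `dup_signal_2`, `processing_days`.
#' @param standards standards data.frame (see [fitCalibration()]).
#' @param lloq,lod assay limits (ng/mL).
#' @param cvThreshold duplicate CV% repeat threshold (default 20).
#' @param belowLodPolicy see [censorImpute()].
#' @return list: `curve` (the [CalibrationCurve-class]) and
#'   `measurements` (per subject-visit data.frame with duplicate
#'   concentrations, `cvPercent`, `repeatRequired`, censored
#'   `concentration` and `censorState`).
#' @export
processPlates <- function(plates, standards, lloq = 0.039, lod = 0.012,
                          cvThreshold = 20,
                          belowLodPolicy = "half_lod") {
    curve <- fitCalibration(standards, lloq = lloq, lod = lod)
    c1 <- backCalculate(plates$dup_signal_1, curve)
    c2 <- backCalculate(plates$dup_signal_2, curve)
    qc <- qcDuplicates(as.numeric(c1), as.numeric(c2), cvThreshold)
    cen <- censorImpute(qc$mean, lloq = lloq, lod = lod,
                        belowLodPolicy = belowLodPolicy)
    out <- data.frame(plates[c("subject_id", "group", "visit_month",
                               "processing_days")],
                      conc_dup1 = as.numeric(c1), conc_dup2 = as.numeric(c2),
                      cvPercent = qc$cvPercent,
                      repeatRequired = qc$repeatRequired,
                      concentration = cen$concentration,
                      censorState = cen$censorState)
    list(curve = curve, measurements = out)
}

#' Export measurements in long format for longitudinal modelling
#'
#' Tidy long-format table (one row per subject-visit with the censored
#' concentration) suitable for fitting multi-level mixed-effects models in
#' external software.
#'
#' @param measurements the `measurements` element of [processPlates()].
#' @return data.frame: `subject_id`, `group`, `visit_month`,
#'   `concentration`, `censorState`.
#' @export
longFormat <- function(measurements) {
    measurements[c("subject_id", "group", "visit_month", "concentration",
                   "censorState")]
}
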