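#' Round half away from zero
#'
#' Spectral-count ratios are reported to one decimal with ties rounded up
#' (so 1.95 -> 2.0), unlike [base::round()]'s round-half-to-even. The
#' two-fold screen compares thresholds against this rounded value, which is
#' the only convention consistent with published spectral-count tables that
#' include boundary ratios such as 2.0 and 0.5.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 1).
#' @return numeric vector rounded half-up.
#' @examples
#' roundHalfUp(1.9935, 1)  # 2.0
#' roundHalfUp(0.45, 1)    # 0.5
#' @export
roundHalfUp <- function(x, digits = 1) {
    p <- 10^digits
    # nudge by an ulp-scale epsilon so binary representation of .5 cases
    # (e.g. 4.45 stored as 4.4499999...) still rounds up
    sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# run `expr` under a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(as.integer(seed))
    expr
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
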