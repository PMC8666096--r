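# Independent oracles, deliberately naive: plain-R dynamic programming and
# brute-force enumeration against which the package implementations are
# checked.

# Needleman-Wunsch (match 1, mismatch 0, linear gap -1) with traceback;
# identity = matched pairs / shorter length
nwIdentityOracle <- function(a, b) {
    x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
    n <- length(x); m <- length(y)
    S <- matrix(0, n + 1, m + 1)
    S[, 1] <- -(0:n); S[1, ] <- -(0:m)
    for (i in seq_len(n)) for (j in seq_len(m)) {
        S[i + 1, j + 1] <- max(S[i, j] + (x[i] == y[j]),
                               S[i, j + 1] - 1, S[i + 1, j] - 1)
    }
    # traceback counting matches (prefer diagonal, as any optimal path's
    # match count realises the identity used here)
    i <- n; j <- m; matches <- 0
    while (i > 0 && j > 0) {
        if (S[i + 1, j + 1] == S[i, j] + (x[i] == y[j])) {
            matches <- matches + (x[i] == y[j]); i <- i - 1; j <- j - 1
        } else if (S[i + 1, j + 1] == S[i, j + 1] - 1) i <- i - 1
        else j <- j - 1
    }
    matches / min(n, m)
}

# replay the greedy clustering rule from the full pairwise identity matrix
greedyClusterOracle <- function(seqs, threshold,
                                identFun = nwIdentityOracle) {
    ord <- order(-nchar(seqs), names(seqs))
    seqs <- seqs[ord]
    reps <- character(); memb <- character()
    for (acc in names(seqs)) {
        hit <- NA_character_
        for (r in reps)
            if (identFun(seqs[[acc]], seqs[[r]]) >= threshold) {
                hit <- r; break
            }
        if (is.na(hit)) { reps <- c(reps, acc); hit <- acc }
        memb[acc] <- hit
    }
    memb
}

# Mann-Whitney U for x vs y by enumerating all pairs (ties count 1/2)
bruteForceU <- function(x, y) {
    u <- 0
    for (xi in x) for (yj in y)
        u <- u + (xi > yj) + 0.5 * (xi == yj)
    u
}

# random amino-acid sequence
randomAASeq <- function(len) {
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
                 replace = TRUE), collapse = "")
}

# minimal evidence object for differential-stage tests
makeEvidence <- function(counts, groups,
                         nPeptides = rep(2L, nrow(counts))) {
    ProteinEvidence(counts, nPeptides = nPeptides,
                    colData = S4Vectors::DataFrame(
                        group = groups,
                        row.names = colnames(counts)))
}
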