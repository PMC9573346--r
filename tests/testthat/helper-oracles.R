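# Independent oracles and fixture builders shared across the suite.
# These deliberately avoid the package's scan/alignment code paths.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Naive per-letter PSSM window score: the definition, summed left to
# right exactly as written (X/B/Z/J/U/O neutral, '*' = -100).
naiveScore <- function(pssm, frame, start) {
    sc <- pssmScores(pssm)
    chars <- strsplit(frame, "", fixed = TRUE)[[1]]
    tot <- 0
    for (i in seq_len(nrow(sc))) {
        ch <- chars[start + i - 1]
        tot <- tot +
            if (ch %in% AA20) unname(sc[i, ch])
            else if (ch == "*") -100
            else 0
    }
    tot
}

# Random PSSM built directly from random column distributions (implied
# probabilities sum to 1 by construction).
randomPSSM <- function(L, motif = "A", group = "rnd",
                       background = blosum62Background()) {
    p <- matrix(rgamma(L * 20, shape = 0.5), nrow = L)
    p <- p / rowSums(p)
    sc <- log2(sweep(p, 2, background, `/`))
    colnames(sc) <- AA20
    new("PSSM", scores = sc, motifLabel = motif, group = group,
        background = setNames(background, AA20), pseudocount = 0.1)
}

randomAA <- function(n, prob = NULL) {
    paste(sample(AA20, n, replace = TRUE, prob = prob), collapse = "")
}

# Gotoh global alignment score with affine gaps (a gap of length k
# costs open + k*ext) and penalised end gaps; small-grid dynamic
# programme, independent of Biostrings.
gotohScore <- function(q, t, open = 11, ext = 1) {
    S <- get(data("BLOSUM62", package = "Biostrings",
                  envir = environment()), envir = environment())
    a <- strsplit(q, "")[[1]]; b <- strsplit(t, "")[[1]]
    n <- length(a); m <- length(b); NEG <- -1e9
    M <- X <- Y <- matrix(NEG, n + 1, m + 1)
    M[1, 1] <- 0
    for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
    for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
    for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
        M[i, j] <- max(M[i-1, j-1], X[i-1, j-1], Y[i-1, j-1]) +
            S[a[i-1], b[j-1]]
        X[i, j] <- max(M[i-1, j] - open - ext, X[i-1, j] - ext,
                       Y[i-1, j] - open - ext)
        Y[i, j] <- max(M[i, j-1] - open - ext, Y[i, j-1] - ext,
                       X[i, j-1] - open - ext)
    }
    max(M[n+1, m+1], X[n+1, m+1], Y[n+1, m+1])
}

# Substitution-only mutant with an exact hamming identity to the
# input; used as a known-identity fixture generator.
mutateToIdentityOracle <- function(seq, targetPct) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    k <- round(length(chars) * (1 - targetPct / 100))
    pos <- sample.int(length(chars), k)
    for (p in pos) {
        repeat {
            r <- sample(AA20, 1)
            if (r != chars[p]) break
        }
        chars[p] <- r
    }
    paste(chars, collapse = "")
}

# Synthetic motif-hit triple for heuristic-ledger unit tests: ABC
# placements with 12-aa motifs at the given V lengths and scores.
syntheticTriple <- function(scores = c(10, 10, 10), v1 = 40, v2 = 25,
                            L = 12) {
    startA <- 1
    startB <- startA + L + v1
    startC <- startB + L + v2
    list(A = list(start = startA, end = startA + L - 1,
                  score = scores[1], L = L),
         B = list(start = startB, end = startB + L - 1,
                  score = scores[2], L = L),
         C = list(start = startC, end = startC + L - 1,
                  score = scores[3], L = L))
}

examplePisuSet <- local({
    sets <- NULL
    function() {
        if (is.null(sets)) sets <<- examplePssmSets()
        sets
    }
})
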