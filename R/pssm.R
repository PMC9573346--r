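#' Build a position-specific scoring matrix from a motif alignment
#'
#' Per alignment column i, the observed frequency of amino acid a is
#' f_ia = count(a in column i) / n_i with gap rows excluded from the
#' denominator (gaps treated as missing data). Frequencies are smoothed
#' with the background by a pseudocount mixture, p_ia = (1 - w) f_ia +
#' w b_a, and scores are log-odds in bits: score[i, a] = log2(p_ia /
#' b_a). With w = 0 an unobserved residue would score -Inf; it is
#' floored at -20 bits instead (unreachable with the default w = 0.1).
#'
#' @param msa aligned motif rows: character vector or \code{AAStringSet},
#'   all the same length (gaps '-' allowed), at least 2 rows, 5-30
#'   columns.
#' @param motifLabel "A", "B" or "C".
#' @param group polymerase group name.
#' @param background 20 background frequencies summing to 1 (default
#'   the BLOSUM62 marginals).
#' @param pseudocount background mixture weight w in [0, 1), default 0.1.
#' @return A \linkS4class{PSSM}.
#' @examples
#' buildPSSM(c("GDD", "GDD", "GDN"), "C", "demo")
#' @export
buildPSSM <- function(msa, motifLabel, group,
                      background = blosum62Background(),
                      pseudocount = 0.1) {
    rows <- toupper(as.character(msa))
    if (length(rows) < 2L) stop("motif alignment needs at least 2 rows")
    L <- nchar(rows[1L])
    if (any(nchar(rows) != L)) stop("ragged motif alignment rows")
    if (L < 5L || L > 30L)
        stop("motif alignment must have 5-30 columns, got ", L)
    if (length(background) != 20L || abs(sum(background) - 1) > 1e-9)
        stop("background must be 20 frequencies summing to 1")
    background <- setNames(as.numeric(background), AA_ORDER)
    if (pseudocount < 0 || pseudocount >= 1)
        stop("pseudocount must be in [0, 1)")
    mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
    bad <- !(mat %in% c(AA_ORDER, "-"))
    if (any(bad))
        stop("motif alignment contains non-standard residue '",
             mat[which(bad)[1L]], "'")
    scores <- matrix(0, nrow = L, ncol = 20L,
                     dimnames = list(NULL, AA_ORDER))
    for (i in seq_len(L)) {
        col <- mat[, i]
        col <- col[col != "-"]
        if (length(col) == 0L)
            stop("column ", i, " of the motif alignment is all gaps")
        f <- tabulate(match(col, AA_ORDER), nbins = 20L) / length(col)
        p <- (1 - pseudocount) * f + pseudocount * background
        sc <- log2(p / background)
        sc[p == 0] <- SCORE_FLOOR
        scores[i, ] <- sc
    }
    new("PSSM", scores = scores, motifLabel = motifLabel, group = group,
        background = background, pseudocount = pseudocount)
}

#' Consensus string of a PSSM
#'
#' The highest-scoring residue of each column (ties: first in
#' alphabetical residue order).
#'
#' @param pssm a \linkS4class{PSSM}.
#' @return Character string of length \code{motifLength(pssm)}.
#' @export
pssmConsensus <- function(pssm) {
    paste(AA_ORDER[apply(pssm@scores, 1L, which.max)], collapse = "")
}

#' Score a PSSM at one position of a translated frame
#'
#' Ungapped log-odds score: the sum over motif columns i of
#' score[i, frame[start + i - 1]]. Ambiguity residues (X, B, Z, J, U, O)
#' contribute 0 bits; a stop codon ('*') contributes -100, vetoing the
#' window. Gaps are not permitted.
#'
#' @param pssm a \linkS4class{PSSM}.
#' @param frame amino-acid string.
#' @param start 1-based window start; must satisfy
#'   \code{1 <= start <= nchar(frame) - motifLength(pssm) + 1}.
#' @return Score in bits.
#' @export
scoreAt <- function(pssm, frame, start) {
    frame <- as.character(frame)
    L <- nrow(pssm@scores)
    if (start < 1L || start > nchar(frame) - L + 1L)
        stop("start out of range")
    idx <- encodeAA(substr(frame, start, start + L - 1L), "frame window")
    .pssmScanC(pssm@scores, idx)[1L]
}

## Scores at every valid start of an encoded frame (integer indices).
scanEncoded <- function(pssm, idx) .pssmScanC(pssm@scores, idx)

#' Best ungapped placement of a PSSM on a frame
#'
#' Scans every window and returns the highest-scoring placement; ties
#' are broken by the smallest start. Returns NULL when the frame is
#' shorter than the motif.
#'
#' @param pssm a \linkS4class{PSSM}.
#' @param frame amino-acid string.
#' @return List with \code{start} (1-based), \code{end}, \code{score}
#'   and \code{L}, or NULL.
#' @export
bestHit <- function(pssm, frame) {
    frame <- as.character(frame)
    L <- nrow(pssm@scores)
    if (nchar(frame) < L) return(NULL)
    sc <- .pssmScanC(pssm@scores, encodeAA(frame, "frame"))
    s <- which.max(sc)
    list(start = s, end = s + L - 1L, score = sc[[s]], L = L)
}

#' Serialise a PSSM to a plain-text file
#'
#' Documented format: a '#' header line carrying group, motif label,
#' column count, pseudocount and the 20 background frequencies, then L
#' rows of 20 tab-separated bit scores (columns in alphabetical residue
#' order). Round-trips through [readPSSM()].
#'
#' @param pssm a \linkS4class{PSSM}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePSSM <- function(pssm, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# palmprintR PSSM\tgroup=%s\tmotif=%s\tL=%d\tw=%.17g",
                       pssm@group, pssm@motifLabel, nrow(pssm@scores),
                       pssm@pseudocount), con)
    writeLines(paste0("# background\t",
                      paste(sprintf("%.17g", pssm@background),
                            collapse = "\t")), con)
    writeLines(paste0("# ", paste(AA_ORDER, collapse = "\t")), con)
    apply(pssm@scores, 1L, function(r)
        writeLines(paste(sprintf("%.17g", r), collapse = "\t"), con))
    invisible(path)
}

#' @rdname writePSSM
#' @export
readPSSM <- function(path) {
    lines <- readLines(path)
    hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    field <- function(key) sub(paste0(key, "="), "",
                               grep(paste0("^", key, "="), hdr, value = TRUE))
    bg <- as.numeric(strsplit(lines[2L], "\t", fixed = TRUE)[[1L]][-1L])
    body <- lines[!startsWith(lines, "#")]
    scores <- do.call(rbind, lapply(strsplit(body, "\t", fixed = TRUE),
                                    as.numeric))
    colnames(scores) <- AA_ORDER
    new("PSSM", scores = scores, motifLabel = field("motif"),
        group = field("group"),
        background = setNames(bg, AA_ORDER),
        pseudocount = as.numeric(field("w")))
}

#' Implied per-column probabilities of a PSSM
#'
#' Recovers the smoothed column distributions from the stored log-odds
#' scores and background (p = b * 2^score), renormalised to absorb the
#' -20 bit floor of zero-pseudocount builds.
#'
#' @param pssm a \linkS4class{PSSM}.
#' @return L x 20 matrix of probabilities, rows summing to 1.
#' @export
pssmProbabilities <- function(pssm) {
    p <- sweep(2^pssm@scores, 2L, pssm@background, `*`)
    p / rowSums(p)
}
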