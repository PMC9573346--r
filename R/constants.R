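#' @useDynLib palmprintR, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rbinom runif setNames
#' @importFrom utils read.delim write.table head
NULL

## Fixed residue order used for all PSSM columns (alphabetical one-letter code).
AA_ORDER <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Residues scored as neutral (0 bits) in ungapped PSSM alignment:
## ambiguity codes and the rare translated residues.
AA_NEUTRAL <- c("X", "B", "Z", "J", "U", "O")

## Stop codons veto a window.
STOP_SCORE <- -100

## Score floor replacing -Inf when a zero-pseudocount column has an
## unobserved residue (unreachable with the default pseudocount of 0.1).
SCORE_FLOOR <- -20

#' Background amino-acid frequencies of the BLOSUM62 substitution model
#'
#' The marginal amino-acid frequencies underlying the BLOSUM62 matrix,
#' used as the default background model when building motif PSSMs.
#' The 20 values sum to 1 exactly.
#'
#' @return Named numeric vector of length 20 (alphabetical one-letter
#'   amino-acid order).
#' @examples
#' sum(blosum62Background())
#' @export
blosum62Background <- function() {
    c(A = 0.074, C = 0.025, D = 0.054, E = 0.054, F = 0.047,
      G = 0.074, H = 0.026, I = 0.068, K = 0.058, L = 0.099,
      M = 0.025, N = 0.045, P = 0.039, Q = 0.034, R = 0.052,
      S = 0.057, T = 0.051, V = 0.073, W = 0.013, Y = 0.032)
}

## Byte-indexed lookup used to encode an amino-acid string for scanning:
## 1..20 = column in the PSSM, 0 = neutral residue, -1 = stop ('*').
.aa_encode_table <- local({
    tab <- rep(NA_integer_, 127)
    tab[utf8ToInt("*")] <- -1L
    for (i in seq_along(AA_ORDER)) tab[utf8ToInt(AA_ORDER[i])] <- i
    tab[vapply(AA_NEUTRAL, utf8ToInt, integer(1))] <- 0L
    tab
})

## Encode an aa string as integer indices for the C scan kernel.
## Unknown characters are an error (caller names the context).
encodeAA <- function(x, context = "sequence") {
    bytes <- as.integer(charToRaw(x))
    idx <- .aa_encode_table[bytes]
    if (anyNA(idx)) {
        bad <- which(is.na(idx))[1L]
        stop(sprintf("invalid amino-acid character '%s' at position %d in %s",
                     substr(x, bad, bad), bad, context))
    }
    idx
}

NT_ALPHABET <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K",
                 "M", "B", "D", "H", "V")

AA_ALPHABET_FULL <- c(AA_ORDER, AA_NEUTRAL, "*", "-")
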