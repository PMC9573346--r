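#' Sample a motif sequence from a PSSM
#'
#' Draws each column's residue from the probability distribution
#' implied by the PSSM scores (p = b * 2^score), sharpened or flattened
#' by a temperature: probabilities are raised to 1/temperature and
#' renormalised, and temperature 0 returns the column argmax, i.e. the
#' consensus, deterministically.
#'
#' @param pssm a \linkS4class{PSSM}.
#' @param n number of draws.
#' @param temperature non-negative sharpening parameter (default 1 =
#'   the implied distribution itself).
#' @return Character vector of \code{n} motif strings. Uses the global
#'   RNG; call \code{set.seed()} for reproducibility.
#' @export
sampleMotif <- function(pssm, n = 1, temperature = 1) {
    probs <- pssmProbabilities(pssm)
    if (temperature == 0)
        return(rep(pssmConsensus(pssm), n))
    probs <- probs^(1 / temperature)
    probs <- probs / rowSums(probs)
    vapply(seq_len(n), function(k)
        paste(vapply(seq_len(nrow(probs)), function(i)
            sample(AA_ORDER, 1L, prob = probs[i, ]), character(1)),
            collapse = ""), character(1))
}

#' Random background amino-acid sequence (decoy)
#'
#' Independent draws from the background frequency model; a stand-in
#' for sequences known not to contain viral RdRP.
#'
#' @param length sequence length (aa).
#' @param background 20 residue frequencies (default BLOSUM62
#'   marginals).
#' @param id record id.
#' @return Named character vector of length 1.
#' @export
makeDecoy <- function(length, background = blosum62Background(),
                      id = "decoy") {
    setNames(paste(sample(AA_ORDER, length, replace = TRUE,
                          prob = background), collapse = ""), id)
}

#' Synthetic motif-bearing positive with known truth
#'
#' Emits flank + motifs in the requested order with background-sampled
#' V1/V2 segments between them + flank, mirroring the palm-domain
#' layout (conserved motifs, variable inter-motif regions), and a truth
#' record of every planted coordinate for recovery tests.
#'
#' @param set the \linkS4class{PssmSet} the motifs are sampled from.
#' @param v1Len,v2Len inter-motif segment lengths (aa).
#' @param order "ABC" (canonical) or "CAB" (permuted).
#' @param flankLens lengths of the leading/trailing background flanks.
#' @param temperature passed to [sampleMotif()] (0 = consensus motifs).
#' @param background background model for flanks and V segments.
#' @param id record id.
#' @return List with \code{seq} (named character) and \code{truth}: a
#'   list with group, order, per-motif start/length, v1_len, v2_len,
#'   pp_start, pp_end.
#' @export
makePositive <- function(set, v1Len = 40, v2Len = 25, order = "ABC",
                         flankLens = c(20, 20), temperature = 0,
                         background = blosum62Background(),
                         id = "positive") {
    stopifnot(order %in% c("ABC", "CAB"), all(flankLens >= 0),
              v1Len >= 0, v2Len >= 0)
    motifs <- lapply(set@pssms, sampleMotif, n = 1,
                     temperature = temperature)
    bg <- function(n) if (n == 0) "" else
        paste(sample(AA_ORDER, n, replace = TRUE, prob = background),
              collapse = "")
    labels <- if (order == "ABC") c("A", "B", "C") else c("C", "A", "B")
    pieces <- c(bg(flankLens[1L]), motifs[[labels[1L]]], bg(v1Len),
                motifs[[labels[2L]]], bg(v2Len), motifs[[labels[3L]]],
                bg(flankLens[2L]))
    seq <- paste(pieces, collapse = "")
    lens <- nchar(unlist(motifs))[labels]
    starts <- flankLens[1L] +
        cumsum(c(1L, lens[1L] + v1Len, lens[2L] + v2Len))
    names(starts) <- labels
    ppStart <- starts[[labels[1L]]]
    ppEnd <- starts[[labels[3L]]] + lens[[3L]] - 1L
    list(seq = setNames(seq, id),
         truth = list(record_id = id, group = set@group, order = order,
                      motif_start = starts[c("A", "B", "C")],
                      motif_len = setNames(nchar(unlist(motifs)),
                                           names(motifs))[c("A","B","C")],
                      v1_len = v1Len, v2_len = v2Len,
                      pp_start = ppStart, pp_end = ppEnd))
}

## Codons per amino acid under the standard genetic code.
.codons_by_aa <- local({
    gc <- Biostrings::GENETIC_CODE
    split(names(gc), gc)
})

#' Reverse-translate an amino-acid sequence into a nucleotide frame
#'
#' Encodes the protein with uniformly sampled synonymous codons
#' (standard code) and pads it so the protein lands in the requested
#' reading frame and strand: [sixFrameTranslate()] recovers the protein
#' in exactly that frame.
#'
#' @param aa amino-acid string (may include '*').
#' @param frame 1, 2 or 3.
#' @param strand "+" or "-".
#' @return Named character vector of length 1 (nucleotide sequence).
#' @export
encodeNt <- function(aa, frame = 1, strand = "+") {
    stopifnot(frame %in% 1:3, strand %in% c("+", "-"))
    id <- if (!is.null(names(aa))) names(aa) else "encoded"
    chars <- strsplit(as.character(aa), "", fixed = TRUE)[[1L]]
    codons <- vapply(chars, function(a) {
        cs <- .codons_by_aa[[a]]
        if (is.null(cs)) stop("cannot reverse-translate residue '", a, "'")
        cs[sample.int(length(cs), 1L)]
    }, character(1))
    pad <- function(n) if (n == 0) "" else
        paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
              collapse = "")
    s <- paste0(pad(frame - 1L), paste(codons, collapse = ""), pad(2L))
    if (strand == "-") s <- reverseComplementNt(s)
    setNames(s, id)
}

## Substitute enough positions to hit a target percent identity
## (substitution-only model: palmprint indels are rare). Replacement
## residues are background draws constrained to differ from the
## original. Realised identity is verified by global alignment and the
## draw repeated until within +/- tol points of the target.
mutateToIdentity <- function(seq, targetPct, background =
                                 blosum62Background(), tol = 2,
                             maxTries = 25) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    k <- round(length(chars) * (1 - targetPct / 100))
    best <- seq; bestErr <- Inf
    for (try in seq_len(maxTries)) {
        mut <- chars
        pos <- sample.int(length(chars), k)
        for (p in pos) {
            repeat {
                r <- sample(AA_ORDER, 1L, prob = background)
                if (r != chars[p]) break
            }
            mut[p] <- r
        }
        cand <- paste(mut, collapse = "")
        err <- abs(percentIdentity(cand, seq) - targetPct)
        if (err < bestErr) { best <- cand; bestErr <- err }
        if (err <= tol) break
    }
    best
}

#' Synthetic labelled species population for clustering tests
#'
#' Generates species centroids that are approximately
#' \code{betweenIdentity} percent identical (or less) to each other,
#' each with members mutated to approximately \code{withinIdentity}
#' percent identity to their centroid (substitutions only); realised
#' identities are verified by global alignment during construction. A
#' synthetic stand-in for a taxonomy-labelled palmprint collection.
#'
#' @param nSpecies number of species.
#' @param membersPerSpecies palmprints per species (the centroid is the
#'   first member).
#' @param withinIdentity,betweenIdentity target percent identities;
#'   must satisfy 0 < between < within <= 100.
#' @param ppLen palmprint length (aa, default 100).
#' @param background residue frequency model.
#' @return List with \code{palmprints} (named character vector) and
#'   \code{labels} (named character vector id -> species).
#' @export
makeSpeciesPopulation <- function(nSpecies, membersPerSpecies,
                                  withinIdentity = 95,
                                  betweenIdentity = 70, ppLen = 100,
                                  background = blosum62Background()) {
    stopifnot(betweenIdentity > 0, betweenIdentity < withinIdentity,
              withinIdentity <= 100)
    ancestor <- paste(sample(AA_ORDER, ppLen, replace = TRUE,
                             prob = background), collapse = "")
    centroids <- character(nSpecies)
    for (i in seq_len(nSpecies)) {
        repeat {
            cand <- mutateToIdentity(ancestor, betweenIdentity, background)
            prev <- centroids[seq_len(i - 1L)]
            ## centroids must be no closer than the between-species target
            if (i == 1L ||
                all(percentIdentity(cand, prev) <= betweenIdentity + 2))
                break
        }
        centroids[i] <- cand
    }
    seqs <- character(0); labels <- character(0)
    for (i in seq_len(nSpecies)) {
        sp <- sprintf("species%02d", i)
        for (m in seq_len(membersPerSpecies)) {
            id <- sprintf("%s_m%02d", sp, m)
            seqs[id] <- if (m == 1L || withinIdentity == 100) centroids[i]
                        else mutateToIdentity(centroids[i], withinIdentity,
                                              background)
            labels[id] <- sp
        }
    }
    list(palmprints = seqs, labels = labels)
}
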