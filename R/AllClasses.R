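#' PSSM: position-specific scoring matrix for one catalytic motif
#'
#' An L x 20 matrix of log-odds scores (bits) describing one of the
#' palm-domain catalytic motifs (A, B or C) of one polymerase group,
#' together with the background amino-acid model and the pseudocount
#' weight it was built with. Columns follow the fixed alphabetical
#' amino-acid order; rows are motif positions.
#'
#' @slot scores numeric matrix, L rows (motif positions) x 20 columns
#'   (amino acids), log-odds in bits.
#' @slot motifLabel one of "A", "B", "C".
#' @slot group polymerase group name (e.g. a phylum-level set).
#' @slot background named numeric vector of 20 background frequencies
#'   summing to 1.
#' @slot pseudocount mixture weight in [0, 1) given to the background
#'   when column probabilities were smoothed.
#'
#' @aliases PSSM-class
#' @exportClass PSSM
setClass("PSSM",
    representation(scores = "matrix", motifLabel = "character",
                   group = "character", background = "numeric",
                   pseudocount = "numeric"),
    validity = function(object) {
        msg <- character(0)
        sc <- object@scores
        if (ncol(sc) != 20L || !identical(colnames(sc), AA_ORDER))
            msg <- c(msg, "scores must have 20 columns in standard aa order")
        if (nrow(sc) < 1L)
            msg <- c(msg, "scores must have at least one row")
        if (!object@motifLabel %in% c("A", "B", "C"))
            msg <- c(msg, "motifLabel must be 'A', 'B' or 'C'")
        if (length(object@background) != 20L ||
            abs(sum(object@background) - 1) > 1e-9)
            msg <- c(msg, "background must be 20 frequencies summing to 1")
        if (object@pseudocount < 0 || object@pseudocount >= 1)
            msg <- c(msg, "pseudocount must be in [0, 1)")
        if (length(msg) == 0L && nrow(sc) > 0L) {
            ## implied column probabilities must be proper distributions
            ## (tolerance admits the -20 bit floor of zero-pseudocount builds)
            p <- sweep(2^sc, 2, object@background, `*`)
            if (any(abs(rowSums(p) - 1) > 1e-6))
                msg <- c(msg, "implied column probabilities do not sum to 1")
        }
        if (length(msg)) msg else TRUE
    })

#' PssmSet: the A, B and C motif models of one polymerase group
#'
#' Bundles exactly one PSSM per motif label for a named group, plus a
#' flag marking reverse-transcriptase sets (hits from which downstream
#' analyses typically exclude).
#'
#' @slot group group name shared by the three motifs.
#' @slot pssms named list with elements "A", "B", "C", each a [PSSM].
#' @slot isRT logical; TRUE for reverse-transcriptase model sets.
#'
#' @aliases PssmSet-class
#' @exportClass PssmSet
setClass("PssmSet",
    representation(group = "character", pssms = "list", isRT = "logical"),
    validity = function(object) {
        msg <- character(0)
        if (!identical(sort(names(object@pssms)), c("A", "B", "C")))
            msg <- c(msg, "pssms must be a named list with elements A, B, C")
        else {
            for (m in c("A", "B", "C")) {
                p <- object@pssms[[m]]
                if (!is(p, "PSSM"))
                    msg <- c(msg, sprintf("pssms$%s is not a PSSM", m))
                else {
                    if (p@motifLabel != m)
                        msg <- c(msg, sprintf("pssms$%s has motifLabel %s",
                                              m, p@motifLabel))
                    if (p@group != object@group)
                        msg <- c(msg, sprintf("pssms$%s group mismatch", m))
                }
            }
        }
        if (length(object@isRT) != 1L || is.na(object@isRT))
            msg <- c(msg, "isRT must be TRUE or FALSE")
        if (length(msg)) msg else TRUE
    })

#' HeuristicConfig: the score-adjustment ledger of the palmprint scanner
#'
#' Holds every tunable constant of the detection heuristics: the
#' per-motif score floor below which a candidate is rejected, the short-V1
#' penalty, the accepted length bands for the V1/V2 inter-motif segments
#' and the whole palmprint, the penalty per out-of-band length, and the
#' high-confidence reporting threshold. All scores are in bits, all
#' lengths in amino acids.
#'
#' @slot minMotifScore reject the candidate if any single motif scores
#'   below this (default 2).
#' @slot v1Min,v1Penalty subtract \code{v1Penalty} (default 5) when V1 is
#'   shorter than \code{v1Min} (default 35).
#' @slot v1Max,v2Min,v2Max,ppMinLen,ppMaxLen accepted length bands.
#' @slot outOfRangePenalty bits subtracted per band violation (default 5).
#' @slot highConfidenceThreshold adjusted score at or above which a hit
#'   is reported as high confidence (default 20).
#'
#' @aliases HeuristicConfig-class
#' @exportClass HeuristicConfig
setClass("HeuristicConfig",
    representation(minMotifScore = "numeric",
                   v1Min = "numeric", v1Penalty = "numeric",
                   v1Max = "numeric", v2Min = "numeric", v2Max = "numeric",
                   ppMinLen = "numeric", ppMaxLen = "numeric",
                   outOfRangePenalty = "numeric",
                   highConfidenceThreshold = "numeric"),
    prototype(minMotifScore = 2, v1Min = 35, v1Penalty = 5,
              v1Max = 120, v2Min = 15, v2Max = 90,
              ppMinLen = 70, ppMaxLen = 160,
              outOfRangePenalty = 5, highConfidenceThreshold = 20),
    validity = function(object) {
        msg <- character(0)
        nonneg <- c("v1Min", "v1Penalty", "v1Max", "v2Min", "v2Max",
                    "ppMinLen", "ppMaxLen", "outOfRangePenalty")
        for (s in nonneg)
            if (slot(object, s) < 0)
                msg <- c(msg, sprintf("%s must be non-negative", s))
        if (object@v1Min > object@v1Max)
            msg <- c(msg, "v1Min must be <= v1Max")
        if (object@v2Min > object@v2Max)
            msg <- c(msg, "v2Min must be <= v2Max")
        if (object@ppMinLen > object@ppMaxLen)
            msg <- c(msg, "ppMinLen must be <= ppMaxLen")
        if (length(msg)) msg else TRUE
    })

#' PalmprintHit: one detected palmprint barcode
#'
#' A complete detection on one query: the winning group, the reading
#' frame and strand (for nucleotide queries), motif coordinates and
#' scores, inter-motif segment lengths, the palmprint boundaries and
#' sequence, the raw and heuristic-adjusted scores, and the confidence
#' call. All amino-acid coordinates are 1-based inclusive positions in
#' the translated frame; nucleotide coordinates are 1-based inclusive on
#' the forward strand.
#'
#' @slot queryId query sequence id.
#' @slot frame integer in -3..3 (amino-acid queries use +1); 0 never occurs.
#' @slot strand "+", "-" or "." (amino-acid query).
#' @slot group winning PSSM set.
#' @slot isRT TRUE when the winning set models reverse transcriptases.
#' @slot motifOrder "ABC" (canonical) or "CAB" (permuted).
#' @slot motifStart,motifEnd,motifScore named (A, B, C) numeric vectors.
#' @slot v1Len,v2Len inter-motif segment lengths (aa).
#' @slot ppStart,ppEnd palmprint boundaries (aa, in frame).
#' @slot ppSeq palmprint amino-acid sequence.
#' @slot rawScore sum of the three motif scores (bits).
#' @slot adjustedScore raw score minus heuristic penalties (bits).
#' @slot confidence "high" or "low".
#' @slot rejectReasons machine-readable reasons; empty for reported hits.
#' @slot ntStart,ntEnd,ntLen forward-strand nucleotide palmprint
#'   coordinates, NA for amino-acid queries.
#'
#' @aliases PalmprintHit-class
#' @exportClass PalmprintHit
setClass("PalmprintHit",
    representation(queryId = "character", frame = "integer",
                   strand = "character", group = "character",
                   isRT = "logical", motifOrder = "character",
                   motifStart = "numeric", motifEnd = "numeric",
                   motifScore = "numeric", v1Len = "numeric",
                   v2Len = "numeric", ppStart = "numeric",
                   ppEnd = "numeric", ppSeq = "character",
                   rawScore = "numeric", adjustedScore = "numeric",
                   confidence = "character", rejectReasons = "character",
                   ntStart = "numeric", ntEnd = "numeric"),
    prototype(ntStart = NA_real_, ntEnd = NA_real_,
              rejectReasons = character(0)),
    validity = function(object) {
        msg <- character(0)
        if (!object@motifOrder %in% c("ABC", "CAB"))
            msg <- c(msg, "motifOrder must be 'ABC' or 'CAB'")
        if (!object@confidence %in% c("high", "low"))
            msg <- c(msg, "confidence must be 'high' or 'low'")
        if (!object@strand %in% c("+", "-", "."))
            msg <- c(msg, "strand must be '+', '-' or '.'")
        for (s in c("motifStart", "motifEnd", "motifScore"))
            if (!identical(sort(names(slot(object, s))), c("A", "B", "C")))
                msg <- c(msg, sprintf("%s must be named A, B, C", s))
        if (length(msg) == 0L) {
            ## the motif and variable segments must tile the palmprint exactly
            lens <- object@motifEnd - object@motifStart + 1
            tiled <- sum(lens) + object@v1Len + object@v2Len
            if (tiled != object@ppEnd - object@ppStart + 1)
                msg <- c(msg, "segments do not tile the palmprint")
            if (nchar(object@ppSeq) != object@ppEnd - object@ppStart + 1)
                msg <- c(msg, "ppSeq length disagrees with boundaries")
        }
        if (length(msg)) msg else TRUE
    })
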