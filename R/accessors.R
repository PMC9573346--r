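#' @name accessors
#' @title Accessors for palmprintR classes
#' @description Small read-only accessors for the S4 containers; slot
#'   access from user code is discouraged.
#' @param object a \linkS4class{PSSM}, \linkS4class{PssmSet} or
#'   \linkS4class{PalmprintHit}.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("pssmScores", function(object) standardGeneric("pssmScores"))
#' @rdname accessors
#' @export
setMethod("pssmScores", "PSSM", function(object) object@scores)

#' @rdname accessors
#' @export
setGeneric("motifLabel", function(object) standardGeneric("motifLabel"))
#' @rdname accessors
#' @export
setMethod("motifLabel", "PSSM", function(object) object@motifLabel)

#' @rdname accessors
#' @export
setGeneric("pssmGroup", function(object) standardGeneric("pssmGroup"))
#' @rdname accessors
#' @export
setMethod("pssmGroup", "PSSM", function(object) object@group)
#' @rdname accessors
#' @export
setMethod("pssmGroup", "PssmSet", function(object) object@group)
#' @rdname accessors
#' @export
setMethod("pssmGroup", "PalmprintHit", function(object) object@group)

#' @rdname accessors
#' @export
setGeneric("motifLength", function(object) standardGeneric("motifLength"))
#' @rdname accessors
#' @export
setMethod("motifLength", "PSSM", function(object) nrow(object@scores))

#' @rdname accessors
#' @export
setGeneric("pssmBackground",
           function(object) standardGeneric("pssmBackground"))
#' @rdname accessors
#' @export
setMethod("pssmBackground", "PSSM", function(object) object@background)

#' @rdname accessors
#' @export
setGeneric("isRT", function(object) standardGeneric("isRT"))
#' @rdname accessors
#' @export
setMethod("isRT", "PssmSet", function(object) object@isRT)
#' @rdname accessors
#' @export
setMethod("isRT", "PalmprintHit", function(object) object@isRT)

#' @rdname accessors
#' @param label motif label "A", "B" or "C".
#' @export
motifPSSM <- function(object, label) {
    stopifnot(is(object, "PssmSet"), label %in% c("A", "B", "C"))
    object@pssms[[label]]
}

#' @rdname accessors
#' @export
setGeneric("motifOrder", function(object) standardGeneric("motifOrder"))
#' @rdname accessors
#' @export
setMethod("motifOrder", "PalmprintHit", function(object) object@motifOrder)

#' @rdname accessors
#' @export
setGeneric("palmprintSeq", function(object) standardGeneric("palmprintSeq"))
#' @rdname accessors
#' @export
setMethod("palmprintSeq", "PalmprintHit", function(object) object@ppSeq)

#' @rdname accessors
#' @export
setGeneric("rawScore", function(object) standardGeneric("rawScore"))
#' @rdname accessors
#' @export
setMethod("rawScore", "PalmprintHit", function(object) object@rawScore)

#' @rdname accessors
#' @export
setGeneric("adjustedScore",
           function(object) standardGeneric("adjustedScore"))
#' @rdname accessors
#' @export
setMethod("adjustedScore", "PalmprintHit",
          function(object) object@adjustedScore)

#' @rdname accessors
#' @export
setGeneric("confidence", function(object) standardGeneric("confidence"))
#' @rdname accessors
#' @export
setMethod("confidence", "PalmprintHit", function(object) object@confidence)

setMethod("show", "PSSM", function(object) {
    cat(sprintf("PSSM motif %s, group %s: %d columns, pseudocount %.3g\n",
                object@motifLabel, object@group, nrow(object@scores),
                object@pseudocount))
    cat("consensus:", pssmConsensus(object), "\n")
})

setMethod("show", "PssmSet", function(object) {
    cat(sprintf("PssmSet '%s'%s: motif lengths A=%d B=%d C=%d\n",
                object@group, if (object@isRT) " (RT)" else "",
                nrow(object@pssms$A@scores), nrow(object@pssms$B@scores),
                nrow(object@pssms$C@scores)))
})

setMethod("show", "PalmprintHit", function(object) {
    cat(sprintf("PalmprintHit %s [%s] group=%s order=%s frame=%+d strand=%s\n",
                object@queryId, object@confidence, object@group,
                object@motifOrder, object@frame, object@strand))
    cat(sprintf("  palmprint %d-%d (%d aa), raw %.2f, adjusted %.2f bits\n",
                object@ppStart, object@ppEnd, nchar(object@ppSeq),
                object@rawScore, object@adjustedScore))
    for (m in c("A", "B", "C"))
        cat(sprintf("  motif %s: %d-%d score %.2f\n", m,
                    object@motifStart[[m]], object@motifEnd[[m]],
                    object@motifScore[[m]]))
})

setMethod("show", "HeuristicConfig", function(object) {
    cat("HeuristicConfig:\n")
    cat(sprintf("  reject if motif score < %g bits\n", object@minMotifScore))
    cat(sprintf("  V1 < %g aa: penalty %g; bands V1<=%g, V2 [%g,%g], palmprint [%g,%g] (penalty %g each)\n",
                object@v1Min, object@v1Penalty, object@v1Max,
                object@v2Min, object@v2Max, object@ppMinLen,
                object@ppMaxLen, object@outOfRangePenalty))
    cat(sprintf("  high confidence at adjusted score >= %g\n",
                object@highConfidenceThreshold))
})

#' Heuristic configuration constructor
#'
#' Builds a \linkS4class{HeuristicConfig} with the default score ledger:
#' per-motif rejection floor 2 bits, V1 shorter than 35 aa penalised 5
#' bits, length bands V1 in [35, 120], V2 in [15, 90], palmprint in
#' [70, 160] aa (5 bits per violation), high-confidence threshold 20.
#'
#' @param ... named overrides of any \linkS4class{HeuristicConfig} slot.
#' @return A validated \linkS4class{HeuristicConfig}.
#' @examples
#' heuristicConfig(highConfidenceThreshold = 30)
#' @export
heuristicConfig <- function(...) new("HeuristicConfig", ...)
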