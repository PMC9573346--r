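#' Best placement of each motif of a set on a frame
#'
#' Places the A, B and C PSSMs of one set independently on the frame
#' (no ordering constraint); motifs longer than the frame are absent
#' from the result.
#'
#' @param frame amino-acid string.
#' @param set a \linkS4class{PssmSet}.
#' @return Named list (subset of A, B, C) of [bestHit()] placements.
#' @export
findMotifs <- function(frame, set) {
    frame <- as.character(frame)
    hits <- lapply(set@pssms, bestHit, frame = frame)
    hits[!vapply(hits, is.null, logical(1))]
}

#' Resolve the catalytic-motif order of three placements
#'
#' The palm-domain motifs must appear either in canonical ABC order or
#' permuted CAB order; any other arrangement (including overlaps)
#' rejects the candidate.
#'
#' @param hits named list of per-motif placements with \code{start} and
#'   \code{end} elements (as from [findMotifs()]).
#' @return List with \code{order} ("ABC", "CAB" or "rejected") and
#'   \code{reasons} (character, empty unless rejected).
#' @export
resolveMotifOrder <- function(hits) {
    missing <- setdiff(c("A", "B", "C"), names(hits))
    if (length(missing))
        return(list(order = "rejected",
                    reasons = paste0("motif_missing:", missing)))
    a <- hits$A; b <- hits$B; c <- hits$C
    if (a$end < b$start && b$end < c$start)
        list(order = "ABC", reasons = character(0))
    else if (c$end < a$start && a$end < b$start)
        list(order = "CAB", reasons = character(0))
    else
        list(order = "rejected", reasons = "bad_motif_order")
}

## V1/V2 lengths and palmprint boundaries implied by an ordered triple.
## Canonical ABC: V1 between A and B, V2 between B and C, palmprint from
## the first letter of A to the last letter of C. Permuted CAB: V1
## between C and A, V2 between A and B, palmprint from the first letter
## of C to the last letter of B.
segmentLayout <- function(hits, order) {
    if (order == "ABC") {
        v1 <- hits$B$start - hits$A$end - 1L
        v2 <- hits$C$start - hits$B$end - 1L
        ppStart <- hits$A$start; ppEnd <- hits$C$end
    } else if (order == "CAB") {
        v1 <- hits$A$start - hits$C$end - 1L
        v2 <- hits$B$start - hits$A$end - 1L
        ppStart <- hits$C$start; ppEnd <- hits$B$end
    } else stop("order must be 'ABC' or 'CAB'")
    list(v1Len = v1, v2Len = v2, ppStart = ppStart, ppEnd = ppEnd,
         ppLen = ppEnd - ppStart + 1L)
}

#' Heuristic palmprint score
#'
#' Starts from the raw score (sum of the three motif log-odds scores)
#' and applies the heuristic ledger: the candidate is rejected outright
#' if any motif scores below \code{minMotifScore} bits; \code{v1Penalty}
#' bits are subtracted when V1 is shorter than \code{v1Min} aa; and
#' \code{outOfRangePenalty} bits are subtracted for each further length
#' band violation (V1 above its maximum, V2 or the palmprint length
#' outside their bands). Rejection is a result, not an error.
#'
#' @param hits named list of A/B/C placements (with \code{start},
#'   \code{end}, \code{score}).
#' @param order "ABC" or "CAB".
#' @param cfg a \linkS4class{HeuristicConfig}.
#' @return List with \code{raw}, \code{adjusted} (NA when rejected),
#'   \code{penalty} (total bits subtracted), \code{reasons} (character)
#'   and the segment layout (\code{v1Len}, \code{v2Len}, \code{ppStart},
#'   \code{ppEnd}, \code{ppLen}).
#' @export
scorePalmprint <- function(hits, order, cfg = heuristicConfig()) {
    stopifnot(order %in% c("ABC", "CAB"))
    seg <- segmentLayout(hits, order)
    raw <- hits$A$score + hits$B$score + hits$C$score
    reasons <- character(0)
    for (m in c("A", "B", "C"))
        if (hits[[m]]$score < cfg@minMotifScore)
            reasons <- c(reasons, paste0("motif_score_below_min:", m))
    if (length(reasons))
        return(c(list(raw = raw, adjusted = NA_real_, penalty = NA_real_,
                      reasons = reasons), seg))
    penalty <- 0
    if (seg$v1Len < cfg@v1Min) penalty <- penalty + cfg@v1Penalty
    if (seg$v1Len > cfg@v1Max) penalty <- penalty + cfg@outOfRangePenalty
    if (seg$v2Len < cfg@v2Min || seg$v2Len > cfg@v2Max)
        penalty <- penalty + cfg@outOfRangePenalty
    if (seg$ppLen < cfg@ppMinLen || seg$ppLen > cfg@ppMaxLen)
        penalty <- penalty + cfg@outOfRangePenalty
    c(list(raw = raw, adjusted = raw - penalty, penalty = penalty,
           reasons = character(0)), seg)
}

## One frame x one set -> scored candidate or NULL (rejected).
## idx is the encoded frame (see encodeAA), shared across sets.
## topK = 1 takes each motif's single best placement (the default
## detection mode); topK > 1 enumerates the top-k placements per motif
## and keeps the best-scoring ordered, non-overlapping combination,
## rescuing queries whose independent optima collide.
scanFrameSet <- function(frame, idx, set, cfg, topK = 1L) {
    placements <- lapply(set@pssms, function(p) {
        L <- nrow(p@scores)
        if (length(idx) < L) return(NULL)
        sc <- .pssmScanC(p@scores, idx)
        ord <- order(-sc)[seq_len(min(topK, length(sc)))]  # stable: ties leftmost
        lapply(ord, function(s)
            list(start = s, end = s + L - 1L, score = sc[[s]], L = L))
    })
    if (any(vapply(placements, is.null, logical(1)))) return(NULL)
    best <- NULL
    for (ia in seq_along(placements$A))
        for (ib in seq_along(placements$B))
            for (ic in seq_along(placements$C)) {
                hits <- list(A = placements$A[[ia]],
                             B = placements$B[[ib]],
                             C = placements$C[[ic]])
                ord <- resolveMotifOrder(hits)
                if (ord$order == "rejected") next
                sc <- scorePalmprint(hits, ord$order, cfg)
                if (length(sc$reasons)) next
                if (is.null(best) || sc$raw > best$score$raw)
                    best <- list(set = set, hits = hits,
                                 order = ord$order, score = sc)
            }
    best
}

## Assemble a PalmprintHit from a winning candidate on one frame.
buildHit <- function(cand, frame, frameNo, strand, queryId, cfg,
                     ntLen = NA_integer_) {
    sc <- cand$score
    hc <- if (sc$adjusted >= cfg@highConfidenceThreshold) "high" else "low"
    ntStart <- NA_real_; ntEnd <- NA_real_
    if (!is.na(ntLen)) {
        iv <- frameToNt(frameNo, sc$ppStart, sc$ppEnd, ntLen)
        ntStart <- iv$start; ntEnd <- iv$end
    }
    new("PalmprintHit",
        queryId = queryId, frame = as.integer(frameNo), strand = strand,
        group = cand$set@group, isRT = cand$set@isRT,
        motifOrder = cand$order,
        motifStart = vapply(cand$hits, `[[`, numeric(1), "start")[c("A","B","C")],
        motifEnd = vapply(cand$hits, `[[`, numeric(1), "end")[c("A","B","C")],
        motifScore = vapply(cand$hits, `[[`, numeric(1), "score")[c("A","B","C")],
        v1Len = sc$v1Len, v2Len = sc$v2Len,
        ppStart = sc$ppStart, ppEnd = sc$ppEnd,
        ppSeq = substr(frame, sc$ppStart, sc$ppEnd),
        rawScore = sc$raw, adjustedScore = sc$adjusted,
        confidence = hc, rejectReasons = character(0),
        ntStart = ntStart, ntEnd = ntEnd)
}

## Best candidate over sets for one frame: highest raw motif-score sum
## among non-rejected candidates; ties by lexicographic group name
## (sets are pre-sorted by group).
bestCandidate <- function(frame, sets, cfg, topK = 1L) {
    idx <- encodeAA(as.character(frame), "query frame")
    best <- NULL
    for (set in sets) {
        cand <- scanFrameSet(frame, idx, set, cfg, topK)
        if (!is.null(cand) &&
            (is.null(best) || cand$score$raw > best$score$raw))
            best <- cand
    }
    best
}

#' Scan an amino-acid sequence for a palmprint
#'
#' Runs every PSSM set over the query: the best placement of each motif
#' is found independently, the motif order is resolved (ABC canonical
#' or CAB permuted, anything else rejected) and the heuristic score
#' ledger is applied. The set with the highest raw motif-score sum
#' among non-rejected candidates wins (ties broken by group name). One
#' hit per query is reported: the global best. Candidates passing the
#' order checks but scoring below the high-confidence threshold are
#' returned with \code{confidence = "low"} rather than dropped, which
#' supports threshold sweeps.
#'
#' @param seq amino-acid sequence (character or \code{AAString}).
#' @param sets list of \linkS4class{PssmSet}.
#' @param cfg a \linkS4class{HeuristicConfig}.
#' @param queryId id used in the report.
#' @param topK number of placements considered per motif. The default
#'   1 pairs each motif's single best placement; larger values switch
#'   to an exhaustive mode that evaluates every ordered,
#'   non-overlapping combination of the top-k placements, which can
#'   rescue queries whose independently best placements collide.
#' @return A \linkS4class{PalmprintHit}, or NULL when every set is
#'   rejected.
#' @export
scanAA <- function(seq, sets, cfg = heuristicConfig(), queryId = "query",
                   topK = 1L) {
    if (length(sets) == 0L) stop("no PSSM sets supplied")
    sets <- sets[order(vapply(sets, pssmGroup, character(1)))]
    frame <- toupper(as.character(seq))
    cand <- bestCandidate(frame, sets, cfg, topK)
    if (is.null(cand)) return(NULL)
    buildHit(cand, frame, 1L, ".", queryId, cfg)
}

#' Scan a nucleotide sequence for a palmprint
#'
#' Six-frame translates the query (standard genetic code) and scans
#' every frame as in [scanAA()]; the frame whose winning candidate has
#' the highest adjusted score is reported (ties broken in frame order
#' +1, +2, +3, -1, -2, -3). The hit carries the palmprint's nucleotide
#' coordinates on the forward strand and the strand sign.
#'
#' @param seq nucleotide sequence (character or \code{DNAString}).
#' @inheritParams scanAA
#' @return A \linkS4class{PalmprintHit} or NULL.
#' @export
scanNT <- function(seq, sets, cfg = heuristicConfig(), queryId = "query",
                   topK = 1L) {
    if (length(sets) == 0L) stop("no PSSM sets supplied")
    sets <- sets[order(vapply(sets, pssmGroup, character(1)))]
    nt <- toupper(as.character(seq))
    minTotal <- min(vapply(sets, function(s)
        sum(vapply(s@pssms, motifLength, numeric(1))), numeric(1)))
    if (nchar(nt) < 3L * minTotal)
        stop("nucleotide query shorter than the smallest possible ",
             "motif triple (", 3L * minTotal, " nt)")
    frames <- sixFrameTranslate(nt)
    best <- NULL; bestFrame <- NULL
    for (fr in frames) {
        cand <- bestCandidate(fr$aa, sets, cfg, topK)
        if (!is.null(cand) &&
            (is.null(best) || cand$score$adjusted > best$score$adjusted)) {
            best <- cand; bestFrame <- fr
        }
    }
    if (is.null(best)) return(NULL)
    buildHit(best, bestFrame$aa, bestFrame$frame,
             if (bestFrame$frame > 0L) "+" else "-",
             queryId, cfg, ntLen = nchar(nt))
}

#' Extract the palmprint barcode segment of a hit
#'
#' @param hit a non-rejected \linkS4class{PalmprintHit}.
#' @return An \code{AAStringSet} of one sequence named
#'   \code{"<query_id>:<pp_start>-<pp_end>:<frame>"}.
#' @export
extractPalmprint <- function(hit) {
    stopifnot(is(hit, "PalmprintHit"))
    if (length(hit@rejectReasons))
        stop("cannot extract a palmprint from a rejected candidate")
    out <- Biostrings::AAStringSet(hit@ppSeq)
    names(out) <- sprintf("%s:%d-%d:%+d", hit@queryId, hit@ppStart,
                          hit@ppEnd, hit@frame)
    out
}

#' Scan a whole sequence set and tabulate the hits
#'
#' Applies [scanAA()] or [scanNT()] (chosen by the container class) to
#' every sequence and returns one report row per hit. Queries with no
#' reportable candidate are absent from the table.
#'
#' @param x an \code{AAStringSet} or \code{DNAStringSet}.
#' @param sets list of \linkS4class{PssmSet}.
#' @param cfg a \linkS4class{HeuristicConfig}.
#' @param topK placements per motif, as in [scanAA()].
#' @return data.frame with fixed columns query_id, frame, strand, group,
#'   is_rt, order, A_start/A_end/A_score (same for B, C), v1_len,
#'   v2_len, pp_start, pp_end, pp_len, raw_score, adjusted_score,
#'   confidence, reject_reasons, nt_start, nt_end (NA for amino-acid
#'   queries), pp_seq.
#' @export
scanFasta <- function(x, sets, cfg = heuristicConfig(), topK = 1L) {
    scanner <- if (is(x, "DNAStringSet")) scanNT else scanAA
    hits <- lapply(seq_along(x), function(i)
        scanner(x[[i]], sets, cfg, queryId = names(x)[i], topK = topK))
    hits <- hits[!vapply(hits, is.null, logical(1))]
    hitTable(hits)
}

#' Tabulate a list of PalmprintHit objects
#'
#' @param hits list of \linkS4class{PalmprintHit}.
#' @return data.frame in the fixed report column order (see
#'   [scanFasta()]); zero rows for an empty list.
#' @export
hitTable <- function(hits) {
    row1 <- function(h) data.frame(
        query_id = h@queryId, frame = h@frame, strand = h@strand,
        group = h@group, is_rt = h@isRT, order = h@motifOrder,
        A_start = h@motifStart[["A"]], A_end = h@motifEnd[["A"]],
        A_score = h@motifScore[["A"]],
        B_start = h@motifStart[["B"]], B_end = h@motifEnd[["B"]],
        B_score = h@motifScore[["B"]],
        C_start = h@motifStart[["C"]], C_end = h@motifEnd[["C"]],
        C_score = h@motifScore[["C"]],
        v1_len = h@v1Len, v2_len = h@v2Len,
        pp_start = h@ppStart, pp_end = h@ppEnd,
        pp_len = h@ppEnd - h@ppStart + 1,
        raw_score = h@rawScore, adjusted_score = h@adjustedScore,
        confidence = h@confidence,
        reject_reasons = paste(h@rejectReasons, collapse = ";"),
        nt_start = h@ntStart, nt_end = h@ntEnd,
        pp_seq = h@ppSeq, stringsAsFactors = FALSE)
    if (length(hits) == 0L)
        return(row1(emptyHitPrototype())[0L, ])
    do.call(rbind, lapply(hits, row1))
}

emptyHitPrototype <- function() {
    new("PalmprintHit", queryId = "x", frame = 1L, strand = ".",
        group = "g", isRT = FALSE, motifOrder = "ABC",
        motifStart = c(A = 1, B = 3, C = 5),
        motifEnd = c(A = 1, B = 3, C = 5),
        motifScore = c(A = 0, B = 0, C = 0),
        v1Len = 1, v2Len = 1, ppStart = 1, ppEnd = 5, ppSeq = "AAAAA",
        rawScore = 0, adjustedScore = 0, confidence = "low")
}

#' Write a scan report as TSV
#'
#' Tab-separated with a header row; missing values are written as '.'.
#'
#' @param report data.frame from [scanFasta()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeScanReport <- function(report, path) {
    out <- report
    for (j in seq_along(out)) {
        v <- out[[j]]
        v <- ifelse(is.na(v) | (is.character(v) & v == ""), ".",
                    as.character(v))
        out[[j]] <- v
    }
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
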