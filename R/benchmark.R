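#' PPV/FDR accuracy summary
#'
#' Positive predictive value is the number of correct predictions over
#' all predictions; the false discovery rate is the number of incorrect
#' predictions over all predictions. Queries with no prediction do not
#' enter either metric, so ppv + fdr = 1 whenever any prediction is
#' made.
#'
#' @param tp,fp counts of correct and incorrect predictions.
#' @return List with \code{tp}, \code{fp}, \code{ppv}, \code{fdr}
#'   (both NA when no prediction was made).
#' @examples
#' accuracySummary(3116, 3)
#' @export
accuracySummary <- function(tp, fp) {
    stopifnot(tp >= 0, fp >= 0)
    tot <- tp + fp
    list(tp = tp, fp = fp,
         ppv = if (tot > 0) tp / tot else NA_real_,
         fdr = if (tot > 0) fp / tot else NA_real_)
}

#' Evaluate the scanner over labelled datasets
#'
#' Scans each dataset and counts high-confidence, non-RT palmprint
#' hits. Hits on RdRP-positive datasets are counted as correct
#' predictions (tp) and hits on negative datasets as incorrect (fp);
#' sensitivity is reported per positive dataset as hits / sequences.
#'
#' @param datasets list of datasets, each a list with \code{name},
#'   \code{polarity} ("Pos" or "Neg"), and either \code{seqs} (an
#'   \code{AAStringSet}/\code{DNAStringSet}) or \code{path} +
#'   \code{alphabet} for a FASTA file.
#' @param sets list of \linkS4class{PssmSet}.
#' @param cfg a \linkS4class{HeuristicConfig}.
#' @return List with \code{per_dataset} (data.frame: name, polarity,
#'   n_sequences, n_palmprints, sensitivity) and \code{summary} from
#'   [accuracySummary()].
#' @export
evaluateDatasets <- function(datasets, sets, cfg = heuristicConfig()) {
    rows <- lapply(datasets, function(d) {
        stopifnot(d$polarity %in% c("Pos", "Neg"))
        seqs <- if (!is.null(d$seqs)) d$seqs else
            tryCatch(readFasta(d$path, d$alphabet),
                     error = function(e)
                         stop("dataset '", d$name, "': ",
                              conditionMessage(e)))
        rep_ <- scanFasta(seqs, sets, cfg)
        nhit <- sum(rep_$confidence == "high" & !rep_$is_rt)
        data.frame(name = d$name, polarity = d$polarity,
                   n_sequences = length(seqs), n_palmprints = nhit,
                   sensitivity = if (d$polarity == "Pos")
                       nhit / length(seqs) else NA_real_,
                   stringsAsFactors = FALSE)
    })
    per <- do.call(rbind, rows)
    list(per_dataset = per,
         summary = accuracySummary(
             tp = sum(per$n_palmprints[per$polarity == "Pos"]),
             fp = sum(per$n_palmprints[per$polarity == "Neg"])))
}

#' Random-nucleotide decoy scan
#'
#' Streams a seeded iid random nucleotide sequence through the scanner
#' in overlapping chunks and counts high-confidence palmprint hits, the
#' false-positive behaviour on sequence with no signal at all. Chunks
#' overlap by twice the maximum palmprint nucleotide length so no hit
#' can be lost at a boundary; duplicate hits in overlaps are removed by
#' their global forward-strand coordinates. The full stream is a
#' deterministic function of the seed alone, so the reported hit set is
#' identical for any chunk length.
#'
#' @param totalNt total number of random bases to scan.
#' @param seed RNG seed for the stream.
#' @param sets list of \linkS4class{PssmSet}.
#' @param cfg a \linkS4class{HeuristicConfig}.
#' @param chunkLen chunk size in bases (default 1e6).
#' @param baseProbs probabilities of A, C, G, T (default uniform; a GC
#'   bias can be supplied).
#' @return List with \code{fp_count} and \code{hits} (data.frame of
#'   global nt_start, nt_end, strand, group, adjusted_score).
#' @export
decoyScan <- function(totalNt, seed, sets, cfg = heuristicConfig(),
                      chunkLen = 1e6, baseProbs = rep(0.25, 4)) {
    stopifnot(totalNt >= chunkLen)
    old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    stream <- sample(c("A", "C", "G", "T"), totalNt, replace = TRUE,
                     prob = baseProbs)
    overlap <- 2L * 3L * as.integer(cfg@ppMaxLen)
    starts <- seq(1L, totalNt, by = as.integer(chunkLen))
    hits <- list()
    for (s in starts) {
        e <- min(totalNt, s + as.integer(chunkLen) + overlap - 1L)
        chunk <- paste(stream[s:e], collapse = "")
        h <- scanNT(chunk, sets, cfg, queryId = "decoy")
        if (!is.null(h) && h@confidence == "high")
            hits[[length(hits) + 1L]] <- data.frame(
                nt_start = s - 1L + h@ntStart, nt_end = s - 1L + h@ntEnd,
                strand = h@strand, group = h@group,
                adjusted_score = h@adjustedScore,
                stringsAsFactors = FALSE)
        if (e == totalNt) break
    }
    hits <- if (length(hits)) unique(do.call(rbind, hits)) else
        data.frame(nt_start = numeric(0), nt_end = numeric(0),
                   strand = character(0), group = character(0),
                   adjusted_score = numeric(0))
    list(fp_count = nrow(hits), hits = hits)
}
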