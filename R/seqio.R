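#' Read a FASTA file into a Biostrings set
#'
#' Reads amino-acid or nucleotide FASTA. Ids are the first
#' whitespace-delimited token of each header; the remainder is kept as a
#' \code{description} metadata column. Sequences are upper-cased on
#' ingest; for nucleotide input U is normalised to T; for amino-acid
#' input alignment gaps ('-') are stripped. Residues outside the
#' alphabet, duplicate ids and empty files are errors.
#'
#' @param path FASTA file.
#' @param alphabet "aa" or "nt".
#' @return An \code{AAStringSet} or \code{DNAStringSet} named by id,
#'   with a \code{description} metadata column.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">q1 demo", "ACGU"), tf)
#' readFasta(tf, "nt")
#' @export
readFasta <- function(path, alphabet = c("aa", "nt")) {
    alphabet <- match.arg(alphabet)
    if (!file.exists(path)) stop("file not found: ", path)
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) == 0L) stop("empty FASTA file: ", path)
    headers <- names(raw)
    ids <- sub("\\s.*$", "", headers)
    desc <- ifelse(grepl("\\s", headers),
                   sub("^\\S+\\s+", "", headers), "")
    if (anyDuplicated(ids))
        stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
    seqs <- toupper(as.character(raw))
    seqs <- vapply(seq_along(seqs), function(i)
        normalizeSeq(seqs[[i]], alphabet, ids[[i]]), character(1))
    out <- if (alphabet == "aa") Biostrings::AAStringSet(seqs)
           else Biostrings::DNAStringSet(seqs)
    names(out) <- ids
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
    out
}

## Upper-case, U->T (nt), strip gaps (aa), and validate the alphabet.
normalizeSeq <- function(seq, alphabet, id) {
    if (alphabet == "nt") {
        seq <- chartr("U", "T", seq)
        allowed <- NT_ALPHABET
    } else {
        seq <- gsub("-", "", seq, fixed = TRUE)
        allowed <- setdiff(AA_ALPHABET_FULL, "-")
    }
    if (nchar(seq) == 0L) stop("empty sequence for record '", id, "'")
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% allowed)
    if (length(bad))
        stop(sprintf("invalid %s residue '%s' at position %d in record '%s'",
                     alphabet, chars[bad[1L]], bad[1L], id))
    seq
}

#' Write sequences to FASTA
#'
#' Writes an \code{XStringSet} (or named character vector) wrapped at 60
#' columns. A non-empty \code{description} metadata column is appended
#' to the header after the id.
#'
#' @param x sequences (\code{AAStringSet}, \code{DNAStringSet} or named
#'   character vector).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(x, path) {
    if (is.character(x)) x <- Biostrings::BStringSet(x)
    hdr <- names(x)
    if (is.null(hdr)) stop("sequences must be named")
    mc <- S4Vectors::mcols(x)
    if (!is.null(mc) && "description" %in% colnames(mc)) {
        d <- as.character(mc$description)
        hdr <- ifelse(is.na(d) | d == "", hdr, paste(hdr, d))
    }
    y <- x
    names(y) <- hdr
    Biostrings::writeXStringSet(y, path, width = 60L)
    invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' Standard complement including IUPAC ambiguity codes; U is accepted
#' and normalised to T first.
#'
#' @param nt nucleotide string.
#' @return The reverse-complemented string.
#' @examples
#' reverseComplementNt("AAAC")  # "GTTT"
#' @export
reverseComplementNt <- function(nt) {
    nt <- normalizeSeq(toupper(nt), "nt", "<input>")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

#' Six-frame translation
#'
#' Translates a nucleotide sequence in all six reading frames under the
#' standard genetic code. Stop codons are emitted as '*' and frames are
#' not split at stops (palmprints may span sequencing errors in
#' metagenomic contigs). Ambiguous codons translate to the amino acid
#' when the code is unambiguous for the pattern, else to 'X'.
#'
#' @param nt nucleotide string (length >= 3) or \code{DNAString}.
#' @return A list of six frames, in fixed order \code{+1,+2,+3,-1,-2,-3};
#'   each element has \code{frame} (integer, sign = strand), \code{aa}
#'   (translated string) and \code{ntOffset} (0-based offset of the
#'   first translated base on the frame's strand).
#' @examples
#' sixFrameTranslate("ATGAAATAA")[["+1"]]$aa  # "MK*"
#' @export
sixFrameTranslate <- function(nt) {
    nt <- as.character(nt)
    nt <- normalizeSeq(toupper(nt), "nt", "<input>")
    n <- nchar(nt)
    if (n < 3L) stop("nucleotide sequence must be at least 3 bases")
    fwd <- nt
    rev <- reverseComplementNt(nt)
    frames <- list()
    for (f in 1:3) {
        for (strand in c(1L, -1L)) {
            s <- if (strand > 0L) fwd else rev
            off <- f - 1L
            naa <- (n - off) %/% 3L
            aa <- if (naa == 0L) "" else as.character(Biostrings::translate(
                Biostrings::DNAString(substr(s, off + 1L, off + 3L * naa)),
                no.init.codon = TRUE, if.fuzzy.codon = "solve"))
            key <- sprintf("%+d", strand * f)
            frames[[key]] <- list(frame = strand * f, aa = aa,
                                  ntOffset = off)
        }
    }
    frames[c("+1", "+2", "+3", "-1", "-2", "-3")]
}

#' Map amino-acid coordinates in a frame to forward-strand nucleotides
#'
#' Converts a 1-based inclusive amino-acid interval in a translation
#' frame to the corresponding 1-based inclusive nucleotide interval on
#' the original forward strand.
#'
#' @param frame integer in \code{c(1,2,3,-1,-2,-3)}.
#' @param aaStart,aaEnd 1-based amino-acid positions in the frame.
#' @param ntLen length of the original nucleotide sequence.
#' @return List with \code{start}, \code{end} (forward strand, start <=
#'   end) and \code{strand} ("+" or "-").
#' @examples
#' frameToNt(1, 1, 3, 30)   # bases 1..9 on '+'
#' frameToNt(-1, 1, 1, 30)  # bases 28..30 on '-'
#' @export
frameToNt <- function(frame, aaStart, aaEnd, ntLen) {
    stopifnot(frame %in% c(1L, 2L, 3L, -1L, -2L, -3L),
              aaStart >= 1, aaEnd >= aaStart)
    off <- abs(frame) - 1L
    s <- off + 3L * (aaStart - 1L) + 1L   # on the frame's strand
    e <- off + 3L * aaEnd
    if (e > ntLen) stop("interval extends past the sequence")
    if (frame > 0L) list(start = s, end = e, strand = "+")
    else list(start = ntLen - e + 1L, end = ntLen - s + 1L, strand = "-")
}
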