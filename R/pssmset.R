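#' Construct a PssmSet from three motif PSSMs
#'
#' @param A,B,C \linkS4class{PSSM} objects for the three motifs, sharing
#'   one group name.
#' @param isRT TRUE when the set models reverse transcriptases rather
#'   than viral RdRP.
#' @return A validated \linkS4class{PssmSet}.
#' @export
pssmSet <- function(A, B, C, isRT = FALSE) {
    new("PssmSet", group = A@group, pssms = list(A = A, B = B, C = C),
        isRT = isRT)
}

#' Read PSSM sets from a directory of motif alignments
#'
#' The directory must contain a \code{sets.tsv} manifest with columns
#' \code{group}, \code{is_rt} and \code{msa_a}, \code{msa_b},
#' \code{msa_c} naming per-motif FASTA alignment files relative to the
#' directory. One PSSM is built per motif per group.
#'
#' @param dir directory containing \code{sets.tsv} and the alignment
#'   FASTA files.
#' @param background,pseudocount passed to [buildPSSM()].
#' @return Named list of \linkS4class{PssmSet} (sorted by group name).
#' @export
readPssmSets <- function(dir, background = blosum62Background(),
                         pseudocount = 0.1) {
    manifest <- file.path(dir, "sets.tsv")
    if (!file.exists(manifest)) stop("no sets.tsv manifest in ", dir)
    man <- read.delim(manifest, stringsAsFactors = FALSE)
    need <- c("group", "is_rt", "msa_a", "msa_b", "msa_c")
    if (!all(need %in% colnames(man)))
        stop("sets.tsv must have columns: ", paste(need, collapse = ", "))
    sets <- lapply(seq_len(nrow(man)), function(i) {
        p <- lapply(setNames(c("msa_a", "msa_b", "msa_c"),
                             c("A", "B", "C")), function(col) {
            msa <- readFasta(file.path(dir, man[[col]][i]), "aa")
            ## readFasta strips gaps from query sequences; re-read raw
            ## rows to preserve alignment columns
            raw <- Biostrings::readBStringSet(file.path(dir, man[[col]][i]))
            buildPSSM(toupper(as.character(raw)),
                      motifLabel = c(msa_a = "A", msa_b = "B",
                                     msa_c = "C")[[col]],
                      group = man$group[i], background = background,
                      pseudocount = pseudocount)
        })
        pssmSet(p$A, p$B, p$C, isRT = as.logical(man$is_rt[i]))
    })
    names(sets) <- man$group
    sets[order(names(sets))]
}

#' Example PSSM sets shipped with the package
#'
#' Three small synthetic motif-model sets built from the example seed
#' alignments under \code{inst/extdata/example_sets}: two canonical
#' RdRP-like phylum sets and one reverse-transcriptase-like set. They
#' have the field-typical shape (motifs of 12-15 aa with conserved
#' catalytic residues: the motif A and C aspartates, the motif B
#' glycine) and exist for demonstrations and tests; they are synthetic
#' and make no claim to represent any curated, trained motif models.
#'
#' @param background,pseudocount passed to [buildPSSM()].
#' @return Named list of \linkS4class{PssmSet}.
#' @examples
#' examplePssmSets()
#' @export
examplePssmSets <- function(background = blosum62Background(),
                            pseudocount = 0.1) {
    dir <- system.file("extdata", "example_sets", package = "palmprintR",
                       mustWork = TRUE)
    readPssmSets(dir, background = background, pseudocount = pseudocount)
}
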