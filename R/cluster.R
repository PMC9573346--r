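#' Global pairwise alignment and percent identity of two palmprints
#'
#' Needleman-Wunsch global alignment with affine gap costs and
#' penalised end gaps (BLOSUM62, gap open 11, gap extend 1 by default).
#' Percent identity is 100 * matches / alignment columns, the
#' denominator counting every column of the end-gap-penalised global
#' alignment; palmprints are same-scale (~100 aa) segments, which is
#' what makes this global convention meaningful.
#'
#' @param q,t amino-acid strings (or \code{AAString}).
#' @param matrix substitution matrix name or matrix (default
#'   "BLOSUM62").
#' @param gapOpen,gapExtend affine gap penalties (a gap of length k
#'   costs gapOpen + k * gapExtend).
#' @return List with \code{query_id}-less alignment fields:
#'   \code{aligned_query}, \code{aligned_target} (equal-length gapped
#'   strings), \code{matches}, \code{columns}, \code{pct_identity} and
#'   \code{score}.
#' @examples
#' globalAlign("MKLV", "MALV")$pct_identity  # 75
#' @export
globalAlign <- function(q, t, matrix = "BLOSUM62", gapOpen = 11,
                        gapExtend = 1) {
    q <- as.character(q); t <- as.character(t)
    if (nchar(q) == 0L || nchar(t) == 0L)
        stop("cannot align an empty sequence")
    ## co-optimal alignments are broken canonically: the
    ## lexicographically smaller sequence is always the DP pattern, so
    ## identity is invariant under swapping query and target
    swap <- q > t
    aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(if (swap) t else q),
        Biostrings::AAString(if (swap) q else t),
        type = "global", substitutionMatrix = matrix,
        gapOpening = gapOpen, gapExtension = gapExtend)
    aq <- as.character(Biostrings::alignedPattern(aln))
    at <- as.character(Biostrings::alignedSubject(aln))
    if (swap) { tmp <- aq; aq <- at; at <- tmp }
    identityFromAligned(aq, at, score = Biostrings::score(aln))
}

identityFromAligned <- function(aq, at, score = NA_real_) {
    cq <- strsplit(aq, "", fixed = TRUE)[[1L]]
    ct <- strsplit(at, "", fixed = TRUE)[[1L]]
    matches <- sum(cq == ct & cq != "-")
    columns <- length(cq)
    list(aligned_query = aq, aligned_target = at, matches = matches,
         columns = columns, pct_identity = 100 * matches / columns,
         score = score)
}

#' Percent identity of one query against many targets
#'
#' Vectorised form of [globalAlign()] identity (one query aligned
#' against each target in a single pass).
#'
#' @param query amino-acid string.
#' @param targets \code{AAStringSet} or character vector.
#' @inheritParams globalAlign
#' @return Numeric vector of percent identities, one per target.
#' @export
percentIdentity <- function(query, targets, matrix = "BLOSUM62",
                            gapOpen = 11, gapExtend = 1) {
    if (length(targets) == 0L) return(numeric(0))
    query <- as.character(query)
    tchr <- as.character(targets)
    ## canonical orientation (see globalAlign): smaller string is the
    ## pattern, making identity symmetric despite co-optimal tracebacks
    pat <- ifelse(tchr <= query, tchr, query)
    sub <- ifelse(tchr <= query, query, tchr)
    aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(pat), Biostrings::AAStringSet(sub),
        type = "global", substitutionMatrix = matrix,
        gapOpening = gapOpen, gapExtension = gapExtend)
    matches <- Biostrings::nmatch(aln)
    aligned <- matches + Biostrings::nmismatch(aln)
    ## every alignment column consumes a residue of the query, the
    ## target, or both: columns = len(q) + len(t) - aligned pairs
    columns <- nchar(pat) + nchar(sub) - aligned
    100 * matches / columns
}

#' Greedy centroid clustering of palmprints into sOTUs
#'
#' Records are processed in length-descending order (ties broken by id);
#' each joins the first already-founded centroid to which its global
#' percent identity is at least the threshold, else founds a new
#' cluster. Centroids are compared in founding order. The default 90%
#' threshold is the species-like identity level at which lumping and
#' splitting of recognised species balance.
#'
#' @param palmprints named \code{AAStringSet} (or named character
#'   vector) of palmprint sequences.
#' @param threshold percent identity in (0, 100].
#' @param idMatrix optional precomputed all-vs-all identity matrix (as
#'   from [identityMatrix()]); avoids re-aligning when the same
#'   collection is clustered at several thresholds.
#' @return data.frame with columns \code{otu_id}, \code{centroid_id},
#'   \code{member_id}, \code{pct_identity} (identity of the member to
#'   its centroid; the centroid itself is a member at 100).
#' @export
clusterGreedy <- function(palmprints, threshold = 90, idMatrix = NULL) {
    stopifnot(threshold > 0, threshold <= 100)
    seqs <- setNames(as.character(palmprints), names(palmprints))
    if (is.null(names(seqs))) stop("palmprints must be named")
    if (length(seqs) == 0L)
        return(data.frame(otu_id = character(0), centroid_id = character(0),
                          member_id = character(0),
                          pct_identity = numeric(0)))
    ord <- order(-nchar(seqs), names(seqs))
    seqs <- seqs[ord]
    centroids <- character(0)       # ids in founding order
    rows <- vector("list", length(seqs))
    for (i in seq_along(seqs)) {
        id <- names(seqs)[i]
        assigned <- NA_character_; pid <- NA_real_
        if (length(centroids)) {
            ids <- if (is.null(idMatrix))
                percentIdentity(seqs[[i]], seqs[centroids])
            else idMatrix[id, centroids]
            j <- which(ids >= threshold)
            if (length(j)) {        # first centroid in founding order
                assigned <- centroids[j[1L]]
                pid <- ids[j[1L]]
            }
        }
        if (is.na(assigned)) {
            centroids <- c(centroids, id)
            assigned <- id; pid <- 100
        }
        rows[[i]] <- data.frame(centroid_id = assigned, member_id = id,
                                pct_identity = pid,
                                stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out$otu_id <- sprintf("OTU%04d", match(out$centroid_id, centroids))
    out[, c("otu_id", "centroid_id", "member_id", "pct_identity")]
}

#' Evaluate clustering thresholds against species labels
#'
#' Clusters the palmprints at each threshold and scores the partition
#' against the labels: a species is \emph{split} when its members
#' occupy more than one cluster, \emph{lumped} when any of its clusters
#' also contains another species, and \emph{pure} when neither. The
#' counts satisfy n_split + n_lumped - n_lumped_and_split + n_pure =
#' n_species.
#'
#' @param palmprints named \code{AAStringSet} or character vector.
#' @param speciesLabels named character vector mapping every palmprint
#'   id to a species.
#' @param thresholds percent identities to sweep (default 97 down
#'   to 85).
#' @return data.frame with one row per threshold: \code{threshold},
#'   \code{n_clusters}, \code{n_split}, \code{n_lumped},
#'   \code{n_lumped_and_split}, \code{n_pure} and
#'   \code{delta_clusters_species} = |n_clusters - n_species|.
#' @export
tuneThreshold <- function(palmprints, speciesLabels, thresholds = 97:85) {
    seqs <- setNames(as.character(palmprints), names(palmprints))
    ids <- names(seqs)
    if (is.null(ids)) stop("palmprints must be named")
    unlab <- setdiff(ids, names(speciesLabels))
    if (length(unlab)) stop("unlabelled palmprint id: ", unlab[1L])
    nSpecies <- length(unique(speciesLabels[ids]))
    im <- identityMatrix(seqs)
    rows <- lapply(thresholds, function(th) {
        cl <- clusterGreedy(seqs, threshold = th, idMatrix = im)
        sp <- speciesLabels[cl$member_id]
        clusterOf <- split(cl$otu_id, sp)
        speciesIn <- split(sp, cl$otu_id)
        split_ <- vapply(clusterOf, function(x)
            length(unique(x)) > 1L, logical(1))
        lumped <- vapply(clusterOf, function(x)
            any(vapply(speciesIn[unique(x)], function(s)
                length(unique(s)) > 1L, logical(1))), logical(1))
        data.frame(threshold = th,
                   n_clusters = length(unique(cl$otu_id)),
                   n_split = sum(split_), n_lumped = sum(lumped),
                   n_lumped_and_split = sum(split_ & lumped),
                   n_pure = sum(!split_ & !lumped),
                   delta_clusters_species =
                       abs(length(unique(cl$otu_id)) - nSpecies))
    })
    do.call(rbind, rows)
}

#' All-vs-all global-alignment identity matrix
#'
#' Symmetric matrix of pairwise percent identities for a palmprint
#' collection (diagonal 100), computed once so that repeated greedy
#' clustering at different thresholds does not re-align pairs.
#'
#' @param palmprints named \code{AAStringSet} or character vector.
#' @inheritParams globalAlign
#' @return Numeric matrix with the palmprint ids as dimnames.
#' @export
identityMatrix <- function(palmprints, matrix = "BLOSUM62",
                           gapOpen = 11, gapExtend = 1) {
    seqs <- setNames(as.character(palmprints), names(palmprints))
    n <- length(seqs)
    m <- diag(100, n)
    dimnames(m) <- list(names(seqs), names(seqs))
    for (j in seq_len(n)[-1L]) {
        pid <- percentIdentity(seqs[[j]], seqs[seq_len(j - 1L)],
                               matrix = matrix, gapOpen = gapOpen,
                               gapExtend = gapExtend)
        m[j, seq_len(j - 1L)] <- pid
        m[seq_len(j - 1L), j] <- pid
    }
    m
}

#' Pick the balanced species threshold from a sweep
#'
#' Selects the threshold whose cluster count best matches the species
#' count (minimum |n_clusters - n_species|); ties are broken by the
#' larger number of pure species, then by the (lower) median of the
#' still-tied thresholds, the robust centre of a flat plateau.
#'
#' @param evals data.frame from [tuneThreshold()].
#' @return The selected threshold (percent).
#' @export
selectBalancedThreshold <- function(evals) {
    cand <- evals[evals$delta_clusters_species ==
                      min(evals$delta_clusters_species), ]
    cand <- cand[cand$n_pure == max(cand$n_pure), ]
    ths <- sort(cand$threshold)
    ths[ceiling(length(ths) / 2)]
}

#' Taxonomic rank band of a palmprint identity
#'
#' Striates percent identity into coarse rank-like bands:
#' species-like above 90, genus-like in (70, 90], family-like in
#' (45, 70], phylum-like at or below 45. Band edges are assigned
#' downward (exactly 90 is genus-like).
#'
#' @param pct percent identity in [0, 100] (vectorised).
#' @return Character vector of band names.
#' @examples
#' rankOfIdentity(c(86.9, 76.8, 90, 91))
#' @export
rankOfIdentity <- function(pct) {
    if (any(pct < 0 | pct > 100)) stop("identity must be in [0, 100]")
    ifelse(pct > 90, "species-like",
    ifelse(pct > 70, "genus-like",
    ifelse(pct > 45, "family-like", "phylum-like")))
}

#' Search a palmprint against a reference collection
#'
#' Aligns the query globally against every reference palmprint and
#' returns hits ranked by percent identity (ties broken by target id),
#' each annotated with its rank band.
#'
#' @param query amino-acid string or \code{AAString}.
#' @param reference named \code{AAStringSet} or character vector.
#' @param maxHits truncate to this many hits (default 500).
#' @param minIdentity drop hits below this percent identity.
#' @return data.frame with \code{target_id}, \code{pct_identity},
#'   \code{rank_band}, sorted by identity descending.
#' @export
searchReference <- function(query, reference, maxHits = 500,
                            minIdentity = 0) {
    if (length(reference) == 0L) stop("reference must be non-empty")
    ids <- names(reference)
    if (is.null(ids)) stop("reference must be named")
    pid <- percentIdentity(query, reference)
    out <- data.frame(target_id = ids, pct_identity = pid,
                      rank_band = rankOfIdentity(pid),
                      stringsAsFactors = FALSE)
    out <- out[out$pct_identity >= minIdentity, ]
    out <- out[order(-out$pct_identity, out$target_id), ]
    head(out, maxHits)
}
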