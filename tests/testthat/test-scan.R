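sets <- examplePisuSet()
pisu <- sets[["ExamplePisu"]]

test_that("independent motif placement recovers planted offsets", {
    set.seed(201)
    consA <- pssmConsensus(motifPSSM(pisu, "A"))
    consB <- pssmConsensus(motifPSSM(pisu, "B"))
    consC <- pssmConsensus(motifPSSM(pisu, "C"))
    frame <- paste0(consA, strrep("G", 40), consB, strrep("G", 30), consC)
    hits <- findMotifs(frame, pisu)
    expect_identical(hits$A$start, 1L)
    expect_identical(hits$B$start, 12L + 40L + 1L)
    expect_identical(hits$C$start, 12L + 40L + 14L + 30L + 1L)

    expect_length(findMotifs(randomAA(10), pisu), 0)   # frame too short

    hx <- findMotifs(strrep("X", 60), pisu)            # neutral residues
    expect_true(all(vapply(hx, `[[`, numeric(1), "score") == 0))
})

test_that("motif order resolution accepts only ABC and CAB", {
    mk <- function(starts, L = 12)
        lapply(starts, function(s) list(start = s, end = s + L - 1))
    expect_identical(resolveMotifOrder(
        mk(list(A = 10, B = 60, C = 110)))$order, "ABC")
    expect_identical(resolveMotifOrder(
        mk(list(C = 10, A = 60, B = 110)))$order, "CAB")
    expect_identical(resolveMotifOrder(
        mk(list(B = 10, A = 60, C = 110)))$order, "rejected")
    # overlapping motifs are rejected even in nominal order
    expect_identical(resolveMotifOrder(
        mk(list(A = 10, B = 15, C = 110)))$order, "rejected")
    r <- resolveMotifOrder(mk(list(A = 10, B = 60)))
    expect_identical(r$order, "rejected")
    expect_identical(r$reasons, "motif_missing:C")
})

test_that("the heuristic score ledger is applied exactly", {
    cfg <- heuristicConfig()

    ok <- scorePalmprint(syntheticTriple(c(10, 10, 10), v1 = 40), "ABC", cfg)
    expect_identical(ok$adjusted, 30)                  # no penalties
    expect_identical(ok$v1Len, 40)
    expect_identical(ok$ppLen, 12 * 3 + 40 + 25)

    low <- scorePalmprint(syntheticTriple(c(10, 10, 1.9)), "ABC", cfg)
    expect_identical(low$reasons, "motif_score_below_min:C")
    expect_true(is.na(low$adjusted))

    short <- scorePalmprint(syntheticTriple(c(10, 10, 10), v1 = 30),
                            "ABC", cfg)
    expect_identical(short$adjusted, 25)               # 30 - 5

    # V1 at the boundary is not penalised
    edge <- scorePalmprint(syntheticTriple(c(10, 10, 10), v1 = 35),
                           "ABC", cfg)
    expect_identical(edge$adjusted, 30)

    # band violations subtract the out-of-range penalty each
    v2small <- scorePalmprint(syntheticTriple(c(10, 10, 10), v2 = 10),
                              "ABC", cfg)
    expect_identical(v2small$adjusted, 25)
    # a long V2 also pushes the palmprint out of its band: two penalties
    v2big <- scorePalmprint(syntheticTriple(c(10, 10, 10), v2 = 95),
                            "ABC", cfg)
    expect_identical(v2big$ppLen, 12 * 3 + 40 + 95)
    expect_identical(v2big$adjusted, 20)
    both <- scorePalmprint(syntheticTriple(c(10, 10, 10), v1 = 125,
                                           v2 = 95), "ABC", cfg)
    # v1 over band + v2 over band + palmprint over band
    expect_identical(both$ppLen, 12 * 3 + 125 + 95)
    expect_identical(both$adjusted, 30 - 15)
})

test_that("amino-acid scan recovers planted palmprints with the right group", {
    set.seed(202)
    pos <- makePositive(pisu, v1Len = 40, v2Len = 25, id = "p1")
    hit <- scanAA(pos$seq, sets, queryId = "p1")
    expect_s4_class(hit, "PalmprintHit")
    expect_identical(pssmGroup(hit), "ExamplePisu")
    expect_false(isRT(hit))
    expect_identical(motifOrder(hit), "ABC")
    expect_equal(unname(hit@motifStart), unname(pos$truth$motif_start))
    expect_equal(hit@v1Len, 40)
    expect_equal(hit@v2Len, 25)
    expect_equal(hit@ppStart, pos$truth$pp_start)
    expect_equal(hit@ppEnd, pos$truth$pp_end)
    expect_identical(confidence(hit), "high")

    # permuted layout: palmprint runs first-of-C to last-of-B
    cab <- makePositive(pisu, order = "CAB", id = "p2")
    hc <- scanAA(cab$seq, sets, queryId = "p2")
    expect_identical(motifOrder(hc), "CAB")
    expect_equal(hc@ppStart, hc@motifStart[["C"]])
    expect_equal(hc@ppEnd, hc@motifEnd[["B"]])

    # RT-modelled fixture is flagged for downstream exclusion
    rt <- makePositive(sets[["ExampleRT"]], id = "p3")
    hr <- scanAA(rt$seq, sets, queryId = "p3")
    expect_identical(pssmGroup(hr), "ExampleRT")
    expect_true(isRT(hr))

    # background decoy yields nothing reportable
    expect_null(scanAA(makeDecoy(500), sets))

    expect_error(scanAA(pos$seq, list()), "no PSSM sets")
})

test_that("confidence flips exactly at the high-confidence threshold", {
    set.seed(203)
    pos <- makePositive(pisu)
    a <- adjustedScore(scanAA(pos$seq, sets))
    at_thr <- scanAA(pos$seq, sets,
                     heuristicConfig(highConfidenceThreshold = a))
    above_thr <- scanAA(pos$seq, sets,
                        heuristicConfig(highConfidenceThreshold = a + 1e-3))
    expect_identical(confidence(at_thr), "high")   # >= is inclusive
    expect_identical(confidence(above_thr), "low")
})

test_that("nucleotide scan agrees with the amino-acid scan in every frame", {
    set.seed(204)
    pos <- makePositive(pisu, id = "ntpos")
    ref <- scanAA(pos$seq, sets, queryId = "ntpos")
    for (f in 1:3) for (st in c("+", "-")) {
        nt <- encodeNt(pos$seq, frame = f, strand = st)
        hit <- scanNT(nt, sets, queryId = "ntpos")
        expect_identical(hit@strand, st)
        expect_identical(abs(hit@frame), f)
        expect_identical(palmprintSeq(hit), palmprintSeq(ref))
        expect_identical(hit@motifScore, ref@motifScore)
        expect_identical(adjustedScore(hit), adjustedScore(ref))
        # nt coordinates decode back to the palmprint
        sub <- substr(nt, hit@ntStart, hit@ntEnd)
        if (st == "-") sub <- reverseComplementNt(sub)
        expect_identical(
            as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                               no.init.codon = TRUE)),
            palmprintSeq(hit))
    }

    expect_error(scanNT("ACGTACGT", sets), "shorter")

    # a stop codon planted inside motif B vetoes high confidence
    chars <- strsplit(unname(pos$seq), "")[[1]]
    bmid <- pos$truth$motif_start[["B"]] + 6
    chars[bmid] <- "*"
    stopped <- paste(chars, collapse = "")
    hs <- scanNT(encodeNt(stopped, 1, "+"), sets)
    expect_true(is.null(hs) || confidence(hs) == "low")
})

test_that("palmprint extraction tiles and re-scans to the same motifs", {
    set.seed(205)
    pos <- makePositive(pisu, v1Len = 40, v2Len = 25,
                        flankLens = c(20, 20), id = "ex")
    hit <- scanAA(pos$seq, sets, queryId = "ex")
    pp <- extractPalmprint(hit)
    expect_identical(names(pp), "ex:21-124:+1")
    expect_identical(Biostrings::width(pp), 12L + 40L + 14L + 25L + 13L)

    # re-scanning the bare palmprint finds the same motifs, shifted
    re <- scanAA(pp[[1]], sets, queryId = "re")
    shift <- hit@ppStart - 1
    expect_equal(re@motifStart, hit@motifStart - shift)
    expect_equal(re@motifScore, hit@motifScore)
    expect_identical(palmprintSeq(re), palmprintSeq(hit))
})

test_that("scan reports are deterministic and threshold-monotone", {
    set.seed(206)
    seqs <- c(
        setNames(vapply(1:8, function(i)
            unname(makePositive(pisu, id = "x")$seq), ""),
            paste0("pos", 1:8)),
        setNames(vapply(1:8, function(i) unname(makeDecoy(300)), ""),
                 paste0("dec", 1:8)))
    aset <- Biostrings::AAStringSet(seqs)
    r1 <- scanFasta(aset, sets)
    r2 <- scanFasta(aset, sets)
    expect_identical(r1, r2)

    counts <- vapply(c(10, 20, 40, 80, 200), function(th) {
        r <- scanFasta(aset, sets,
                       heuristicConfig(highConfidenceThreshold = th))
        sum(r$confidence == "high")
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))

    tf <- withr::local_tempfile(fileext = ".tsv")
    writeScanReport(r1, tf)
    tab <- read.delim(tf)
    expect_identical(nrow(tab), nrow(r1))
    expect_identical(tab$query_id, r1$query_id)
})

test_that("exhaustive top-k placement rescues colliding motif optima", {
    consA <- pssmConsensus(motifPSSM(pisu, "A"))
    consB <- pssmConsensus(motifPSSM(pisu, "B"))
    consC <- pssmConsensus(motifPSSM(pisu, "C"))
    weakA <- consA
    substr(weakA, 2, 4) <- "WWW"   # still scores well, but below consA
    # the best-scoring A placement sits after C, so pairing only the
    # independent optima leaves no valid motif order
    s <- paste0(weakA, strrep("G", 40), consB, strrep("G", 25), consC,
                strrep("G", 5), consA)
    expect_null(scanAA(s, list(pisu)))
    hit <- scanAA(s, list(pisu), topK = 4)
    expect_s4_class(hit, "PalmprintHit")
    expect_identical(motifOrder(hit), "ABC")
    expect_equal(hit@motifStart[["A"]], 1)
    expect_equal(hit@ppEnd, nchar(s) - 5 - nchar(consA))
})
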