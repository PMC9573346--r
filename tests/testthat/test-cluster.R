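test_that("global alignment identity matches the DP oracle and conventions", {
    self <- globalAlign("MKLV", "MKLV")
    expect_identical(self$matches, 4L)
    expect_identical(self$columns, 4L)
    expect_identical(self$pct_identity, 100)

    sub <- globalAlign("MKLV", "MALV")
    expect_identical(sub$pct_identity, 75)

    # end gaps count in the denominator
    ext <- globalAlign("MKLV", "MKLVAA")
    expect_identical(ext$columns, 6L)
    expect_equal(ext$pct_identity, 400 / 6)

    expect_error(globalAlign("", "MKLV"), "empty")

    # alignment scores equal an independent affine-gap Gotoh oracle
    set.seed(301)
    for (i in 1:25) {
        q <- randomAA(sample(5:25, 1))
        t <- randomAA(sample(5:25, 1))
        expect_equal(globalAlign(q, t)$score, gotohScore(q, t))
    }
})

test_that("percent identity is symmetric and consistent across code paths", {
    set.seed(302)
    for (i in 1:200) {
        q <- randomAA(sample(40:120, 1))
        t <- randomAA(sample(40:120, 1))
        pq <- percentIdentity(q, t)
        pt <- percentIdentity(t, q)
        expect_equal(pq, pt)
        expect_equal(pq, globalAlign(q, t)$pct_identity)
    }
})

test_that("greedy centroid clustering honours threshold and founding order", {
    three <- setNames(rep("MKLVDDGAHTPLV", 3), c("s1", "s2", "s3"))
    cl <- clusterGreedy(three, 90)
    expect_identical(length(unique(cl$otu_id)), 1L)
    expect_identical(nrow(cl), 3L)
    expect_true(all(cl$pct_identity == 100))

    set.seed(303)
    far <- c(a = randomAA(60), b = randomAA(60))
    cl2 <- clusterGreedy(far, 90)
    expect_identical(length(unique(cl2$otu_id)), 2L)

    expect_identical(nrow(clusterGreedy(character(0) |>
        setNames(character(0)), 90)), 0L)

    # planted population: exact recovery of the partition
    set.seed(304)
    pop <- makeSpeciesPopulation(8, 5, withinIdentity = 95,
                                 betweenIdentity = 70, ppLen = 100)
    cl3 <- clusterGreedy(pop$palmprints, 90)
    expect_identical(length(unique(cl3$otu_id)), 8L)
    # members cluster with their own species
    sp <- pop$labels[cl3$member_id]
    expect_true(all(tapply(cl3$otu_id, sp, function(x)
        length(unique(x))) == 1))

    # every member is >= threshold to its centroid; centroids are
    # mutually < threshold (brute-force all-vs-all check)
    expect_true(all(cl3$pct_identity >= 90))
    cent <- unique(cl3$centroid_id)
    im <- identityMatrix(pop$palmprints[cent])
    expect_true(all(im[upper.tri(im)] < 90))
})

test_that("threshold tuning counts split, lumped and pure species", {
    # singleton species far apart: pure everywhere
    set.seed(305)
    seqs <- setNames(vapply(1:6, function(i) randomAA(80), ""),
                     paste0("q", 1:6))
    labels <- setNames(paste0("sp", 1:6), names(seqs))
    ev <- tuneThreshold(seqs, labels, thresholds = c(97, 90, 85))
    expect_true(all(ev$n_clusters == 6))
    expect_true(all(ev$n_pure == 6))
    expect_true(all(ev$delta_clusters_species == 0))

    # two species sharing an identical palmprint are lumped
    shared <- c(x1 = randomAA(80), x2 = NA)
    shared["x2"] <- shared["x1"]
    lab2 <- c(x1 = "spA", x2 = "spB")
    ev2 <- tuneThreshold(shared, lab2, thresholds = c(97, 90))
    expect_true(all(ev2$n_lumped == 2))
    expect_true(all(ev2$n_pure == 0))

    expect_error(tuneThreshold(seqs, labels[-1], thresholds = 90),
                 "unlabelled")

    # bookkeeping identity holds on a messy population
    set.seed(306)
    pop <- makeSpeciesPopulation(6, 4, withinIdentity = 92,
                                 betweenIdentity = 75, ppLen = 80)
    ev3 <- tuneThreshold(pop$palmprints, pop$labels, thresholds = 97:85)
    nsp <- length(unique(pop$labels))
    expect_true(all(ev3$n_split + ev3$n_lumped - ev3$n_lumped_and_split +
                        ev3$n_pure == nsp))
    # cluster count is non-increasing as the threshold loosens
    expect_true(all(diff(ev3$n_clusters) <= 0))
})

test_that("identity rank bands partition [0, 100] with declared boundaries", {
    expect_identical(rankOfIdentity(86.9), "genus-like")
    expect_identical(rankOfIdentity(76.8), "genus-like")
    expect_identical(rankOfIdentity(90), "genus-like")
    expect_identical(rankOfIdentity(90.000001), "species-like")
    expect_identical(rankOfIdentity(70), "family-like")
    expect_identical(rankOfIdentity(45), "phylum-like")
    expect_error(rankOfIdentity(101), "0, 100")

    grid <- seq(0, 100, by = 0.1)
    bands <- rankOfIdentity(grid)
    expect_false(anyNA(bands))
    expect_identical(sort(unique(bands)),
                     sort(c("species-like", "genus-like", "family-like",
                            "phylum-like")))
    # bands are contiguous: one change point at each declared boundary
    expect_identical(sum(bands[-1] != bands[-length(bands)]), 3L)
})

test_that("reference search ranks by identity with rank-band annotation", {
    set.seed(307)
    query <- randomAA(100)
    ref <- c(exact = query,
             near = mutateToIdentityOracle(query, 95),
             mid = mutateToIdentityOracle(query, 80),
             far = mutateToIdentityOracle(query, 50))
    hits <- searchReference(query, ref)
    expect_identical(hits$target_id[1], "exact")
    expect_identical(hits$pct_identity[1], 100)
    expect_identical(hits$rank_band[1], "species-like")
    expect_identical(hits$target_id,
                     c("exact", "near", "mid", "far"))
    expect_identical(hits$rank_band[2:4],
                     c("species-like", "genus-like", "family-like"))

    expect_identical(nrow(searchReference(query, ref, maxHits = 1)), 1L)
    expect_error(searchReference(query, character(0)), "non-empty")
})
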