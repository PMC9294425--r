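test_that("candidate scanning matches the spec examples", {
    c1 <- scanCandidates("ATGAAATAA", callerConfig(minLength = 9L))
    expect_equal(nrow(c1), 1L)
    expect_equal(c(c1$start, c1$end), c(1L, 9L))
    expect_equal(c1$start_codon, "ATG")

    expect_equal(nrow(scanCandidates("ATGAAATAA", callerConfig())), 0L)

    cfg9 <- callerConfig(minLength = 9L)
    c2 <- scanCandidates("ATGATGGGGTAA", cfg9)
    expect_equal(nrow(c2), 1L)
    expect_equal(c(c2$start, c2$end), c(1L, 12L))
    c3 <- scanCandidates("ATGATGGGGTAA",
                         callerConfig(minLength = 9L, startPolicy = "all"))
    expect_equal(nrow(c3), 2L)
    expect_equal(c3$start, c(1L, 4L))
    expect_equal(c3$end, c(12L, 12L))

    near <- scanCandidates("CTGAAATGA",
                           callerConfig(startCodons = c("ATG", "CTG", "GTG",
                                                        "TTG"),
                                        minLength = 9L))
    expect_equal(nrow(near), 1L)
    expect_equal(near$start_codon, "CTG")
})

test_that("candidate scanning matches brute-force enumeration", {
    brute <- function(seq, starts, minLen, policy) {
        L <- nchar(seq); res <- list()
        for (s in seq_len(max(L - 5L, 0L))) {
            if (!substr(seq, s, s + 2L) %in% starts) next
            p <- s + 3L; e <- NA_integer_
            while (p + 2L <= L) {
                if (substr(seq, p, p + 2L) %in% c("TAA", "TAG", "TGA")) {
                    e <- p + 2L; break
                }
                p <- p + 3L
            }
            if (is.na(e) || e - s + 1L < minLen) next
            res[[length(res) + 1L]] <- c(s, e)
        }
        if (!length(res))
            return(matrix(integer(0), ncol = 2))
        m <- unique(do.call(rbind, res))
        if (policy == "5prime") {
            keep <- !logical(nrow(m))
            for (e in unique(m[, 2]))
                keep[m[, 2] == e & m[, 1] > min(m[m[, 2] == e, 1])] <- FALSE
            m <- m[keep, , drop = FALSE]
        }
        m[order(m[, 1], m[, 2]), , drop = FALSE]
    }
    set.seed(13)
    for (i in 1:40) {
        seq <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
        starts <- if (i %% 2) "ATG" else c("ATG", "CTG", "GTG", "TTG")
        for (policy in c("5prime", "all")) {
            cfg <- callerConfig(startCodons = starts, minLength = 30L,
                                startPolicy = policy)
            got <- scanCandidates(seq, cfg)
            want <- brute(seq, starts, 30L, policy)
            expect_equal(unname(cbind(got$start, got$end)), unname(want))
        }
    }
})

test_that("every candidate satisfies the ORF invariants", {
    sim <- smallSim()
    cfg <- callerConfig()
    for (tx in sim$transcripts[1:6]) {
        cands <- scanCandidates(txSequence(tx), cfg)
        for (i in seq_len(nrow(cands))) {
            s <- cands$start[i]; e <- cands$end[i]
            expect_equal((e - s + 1L) %% 3L, 0L)
            expect_gte(e - s + 1L, 60L)
            seqs <- substring(txSequence(tx), seq(s, e - 2L, 3L),
                              seq(s + 2L, e, 3L))
            expect_true(seqs[length(seqs)] %in% c("TAA", "TAG", "TGA"))
            expect_false(any(head(seqs, -1) %in% c("TAA", "TAG", "TGA")))
        }
    }
})

test_that("frame splitting partitions the interval", {
    fr <- splitFrames(1:6, 1L, 6L)
    expect_equal(fr$f0, c(1L, 4L))
    expect_equal(fr$f1, c(2L, 5L))
    expect_equal(fr$f2, c(3L, 6L))
    z <- splitFrames(rep(0, 9), 1L, 9L)
    expect_true(all(unlist(z) == 0))
    expect_error(splitFrames(1:10, 1L, 10L), "multiple of 3")
    # concatenation is a permutation of the input slice
    set.seed(2)
    v <- rexp(30)
    fr2 <- splitFrames(v, 4L, 27L)
    expect_equal(sort(unname(unlist(fr2))), sort(v[4:27]))
})

test_that("one-sided t matches the textbook pooled formula", {
    set.seed(17)
    for (i in 1:200) {
        a <- rnorm(sample(2:30, 1)); b <- rexp(sample(2:30, 1))
        expect_equal(oneSidedT(a, b), pooledTOracle(a, b),
                     tolerance = 1e-10)
    }
    x <- c(0.1, 0.4, 0.2)
    expect_equal(oneSidedT(x, x), 0.5)
    expect_lt(oneSidedT(c(0, 0, 0.01, 0), c(0.02, 0.03, 0.02, 0.03)), 0.01)
    expect_error(oneSidedT(1, c(1, 2)), "two values")
    # degenerate zero-variance rules
    expect_equal(oneSidedT(c(0, 0), c(1, 1)), 0)
    expect_equal(oneSidedT(c(1, 1), c(0, 0)), 1)
    expect_equal(oneSidedT(c(1, 1), c(1, 1)), 0.5)
})

test_that("p-value combination follows Fisher's chi-square", {
    expect_equal(combinePvalues(c(1, 1)), 1)
    expect_equal(combinePvalues(c(0.5, 0.5)),
                 pchisq(-2 * (log(0.5) + log(0.5)), df = 4,
                        lower.tail = FALSE))
    expect_equal(combinePvalues(c(0.5, 0.5)), 0.5966, tolerance = 1e-4)
    ps <- seq(0.01, 0.99, length.out = 20)
    single <- vapply(ps, combinePvalues, numeric(1))
    expect_true(all(diff(single) > 0))   # monotone in p
    expect_error(combinePvalues(numeric(0)), "no p-values")
    expect_equal(combinePvalues(c(0, 0.5)),
                 pchisq(-2 * (log(.Machine$double.xmin) + log(0.5)),
                        df = 4, lower.tail = FALSE))
    # Stouffer agrees with the closed normal form
    expect_equal(combinePvalues(c(0.2, 0.3), "stouffer"),
                 pnorm((qnorm(0.8) + qnorm(0.7)) / sqrt(2),
                       lower.tail = FALSE))
})

test_that("usage values assign trained frequencies per triplet", {
    uni <- uniformCodonUsage()
    v <- usageValues("ATGAAACCCGGGTAA", 1L, 15L, 0L, uni)
    expect_equal(v, c(rep(1 / 61, 4), 0))  # TAA is a stop -> 0

    tab <- codonUsageFromCounts(c(ATG = 1, AAA = 1))
    expect_equal(usageValues("ATGAAATAA", 1L, 9L, 0L, tab), c(0.5, 0.5, 0))

    # shifted readings drop the trailing incomplete triplet
    set.seed(4)
    seq <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    for (sh in 0:2)
        expect_length(usageValues(seq, 4L, 33L, sh, uni), (30 - sh) %/% 3)
    # triplets containing N score 0
    expect_equal(usageValues("ATGANATAA", 1L, 9L, 0L, tab), c(0.5, 0, 0))
})

test_that("usage frame test rewards in-frame preferred codons", {
    skew <- codonUsageFromCounts(c(GCT = 40, GAA = 40, AAA = 10, TTT = 10))
    seq <- paste(rep(c("GCT", "GAA"), 15), collapse = "")
    r <- usageFrameTest(seq, 1L, 90L, skew)
    expect_lt(r$p_use_f1, 0.05)
    expect_lt(r$p_use_f2, 0.05)
    expect_equal(r$p_use_f1, pooledTOracle(
        usageValues(seq, 1L, 90L, 1L, skew),
        usageValues(seq, 1L, 90L, 0L, skew)), tolerance = 1e-12)

    # uniform table: all values constant -> zero-variance equal-mean rule
    seqU <- paste(rep("GCA", 20), collapse = "")
    rU <- usageFrameTest(seqU, 1L, 60L, uniformCodonUsage())
    expect_equal(rU$p_use_f1, 0.5)
    expect_equal(rU$p_use_f2, 0.5)

    # frame-0 permutation invariance: reordering codons keeps the p
    codons <- c("GCT", "GAA", "GCT", "GAA", "AAA", "GCT", "GAA", "GCT",
                "GAA", "GCT", "TTT", "GAA", "GCT", "GAA", "GCT", "GAA",
                "GCT", "GAA", "GCT", "GAA")
    s1 <- paste(codons, collapse = "")
    v1 <- usageValues(s1, 1L, 60L, 0L, skew)
    set.seed(9)
    s2 <- paste(sample(codons), collapse = "")
    v2 <- usageValues(s2, 1L, 60L, 0L, skew)
    expect_equal(sort(v1), sort(v2))
})

test_that("diversity frame test follows the wobble-elevation contract", {
    # frame2 uniformly 0.01, frames 0/1 zero: degenerate rule p = 0
    dv <- rep(c(0, 0, 0.01), 20)
    r <- diversityFrameTest(dv, 1L, 60L)
    expect_equal(r$p_div_f0, 0)
    expect_equal(r$p_div_f1, 0)

    expect_error(diversityFrameTest(c(0, 0, 0.1), 1L, 3L), "2 codons")
    # fewer than minInformative positive sites -> untestable
    one <- c(0.3, rep(0, 29))
    expect_null(diversityFrameTest(one, 1L, 30L))

    # null calibration: p approximately uniform when frames share one law
    set.seed(23)
    ps <- replicate(600, {
        d <- ifelse(runif(90) < 0.2, rexp(90, 10), 0)
        t <- diversityFrameTest(d, 1L, 90L)
        if (is.null(t)) NA else t$p_div_f0
    })
    ps <- ps[!is.na(ps)]
    expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("codon-usage training pools codons of passing preliminary ORFs", {
    genome <- Biostrings::DNAStringSet(c(chrT = "ATGAAAAAGTAA"))
    ann <- makeAnnotation(cbind(1L, 12L), seqid = "chrT")
    txs <- buildTranscripts(genome, ann)
    trk <- diversityTrack(data.frame(seqid = "chrT",
                                     pos = c(3L, 6L, 9L, 12L),
                                     pi = c(0.2, 0.3, 0.25, 0.2)))
    cfg <- callerConfig(trainMinLength = 12L)
    tab <- trainCodonUsage(txs, trk, cfg)
    f <- codonFrequencies(tab)
    expect_equal(unname(f[c("ATG", "AAA", "AAG")]), rep(1 / 3, 3))
    expect_equal(unname(f["TAA"]), 0)
    expect_equal(sum(f), 1)

    # two ORFs with disjoint codons pool proportionally
    genome2 <- Biostrings::DNAStringSet(c(
        c1 = "ATGAAAAAGTAA", c2 = "ATGCCCCCGCCACCTTAA"))
    annB <- new("AnnotationSet",
        exons = GenomicRanges::GRangesList(list(
            GenomicRanges::GRanges("c1", IRanges::IRanges(1L, 12L)),
            GenomicRanges::GRanges("c2", IRanges::IRanges(1L, 18L)))),
        cds = GenomicRanges::GRangesList(list(
            GenomicRanges::GRanges(), GenomicRanges::GRanges())),
        tx = data.frame(transcript_id = c("t1", "t2"),
                        gene_id = c("g1", "g2"), seqid = c("c1", "c2"),
                        strand = "+", biotype = "protein_coding",
                        usable = TRUE, stringsAsFactors = FALSE))
    txsB <- buildTranscripts(genome2, annB)
    trkB <- diversityTrack(data.frame(
        seqid = c(rep("c1", 4), rep("c2", 5)),
        pos = c(3L, 6L, 9L, 12L, 3L, 6L, 9L, 12L, 15L),
        pi = c(0.2, 0.3, 0.25, 0.2, 0.2, 0.3, 0.25, 0.2, 0.3)))
    tabB <- trainCodonUsage(txsB, trkB, cfg)
    fB <- codonFrequencies(tabB)
    expect_equal(unname(fB["ATG"]), 2 / 8)   # pooled counts over 8 codons
    expect_equal(unname(fB["AAA"]), 1 / 8)
    expect_equal(unname(fB["CCC"]), 1 / 8)

    # nothing passes -> dedicated training error
    trkNull <- diversityTrack()
    expect_error(trainCodonUsage(txs, trkNull, cfg), "preliminary",
                 class = "orfpiTrainingError")
})

test_that("training recovers a planted codon skew", {
    sim <- smallSim()
    tab <- trainCodonUsage(sim$transcripts, sim$track, callerConfig())
    gen <- sim$manifest$codonFreq
    est <- codonFrequencies(tab)[names(gen)]
    expect_lt(max(abs(est - gen)), 0.02)
})

test_that("prediction recovers planted ORFs exactly and deterministically", {
    sim <- smallSim()
    cfg <- callerConfig()
    tab <- trainCodonUsage(sim$transcripts, sim$track, cfg)
    orfs <- predictOrfs(sim$transcripts, sim$track, tab, cfg)
    keys <- orfIdentity(orfs)
    mains <- manifestKeys(sim$manifest, "main")
    expect_gte(mean(mains %in% keys), 0.95)

    # frame identity: reported blocks reconstruct the transcript interval
    for (i in seq_len(min(nrow(orfs), 10))) {
        expect_equal(ORFpi:::blockLengthSum(orfs$blocks[i]),
                     orfs$length_nt[i])
        expect_equal(orfs$length_nt[i] %% 3L, 0L)
    }

    # determinism: identical rerun
    orfs2 <- predictOrfs(sim$transcripts, sim$track, tab, cfg)
    expect_identical(orfs, orfs2)

    # monotonicity: a stricter alpha nests the prediction set
    strict <- callerConfig(alpha = 0.001)
    orfsS <- predictOrfs(sim$transcripts, sim$track, tab, strict)
    expect_true(all(orfIdentity(orfsS) %in% keys))
    tiny <- callerConfig(alpha = 1e-12)
    orfsT <- predictOrfs(sim$transcripts, sim$track, tab, tiny)
    expect_true(all(orfIdentity(orfsT) %in% orfIdentity(orfsS)))
})

test_that("recovery is non-decreasing in the wobble elevation", {
    recov <- function(wobbleMean, wobbleSeg) {
        p <- simulationParams(nGenes = 15L, seed = 31L,
                              segProb = c(wobble = wobbleSeg,
                                          nonwobble = 0.03, utr = 0.03,
                                          intergenic = 0.03),
                              piMean = c(wobble = wobbleMean,
                                         nonwobble = 0.05, utr = 0.05,
                                         intergenic = 0.05))
        sim <- simulateGenome(p)
        trk <- simulateDiversity(sim$genome, sim$annotation, sim$manifest, p)
        txs <- buildTranscripts(sim$genome, sim$annotation)
        cfg <- callerConfig()
        tab <- tryCatch(trainCodonUsage(txs, trk, cfg),
                        error = function(e) uniformCodonUsage())
        orfs <- predictOrfs(txs, trk, tab, cfg)
        m <- sim$manifest$orfs
        keys <- paste(m$seqid, m$strand, m$blocks, sep = "|")[m$type == "main"]
        mean(keys %in% orfIdentity(orfs))
    }
    r <- mapply(recov, c(0.05, 0.15, 0.45), c(0.03, 0.10, 0.20))
    expect_true(all(diff(r) >= 0))
    expect_gt(r[3], r[1])
})
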