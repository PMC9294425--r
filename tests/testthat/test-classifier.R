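# one coding transcript: 300 nt 5'UTR, CDS 301..600 (stop included),
# 300 nt 3'UTR
classifySetup <- function(biotype = "protein_coding", withCds = TRUE) {
    seqLen <- 900L
    genome <- Biostrings::DNAStringSet(c(chrT = strrep("A", seqLen)))
    ann <- makeAnnotation(cbind(1L, seqLen),
                          cds = if (withCds) cbind(301L, 600L) else NULL,
                          biotype = biotype)
    txs <- buildTranscripts(genome, ann)
    list(ann = ann, txs = txs)
}

orfRow <- function(s, e, tid = "t1", strand = "+", seqid = "chrT") {
    data.frame(transcript_id = tid, seqid = seqid, strand = strand,
               blocks = paste0(s, "-", e), tx_start = s, tx_end = e,
               stringsAsFactors = FALSE)
}

test_that("positional categories follow their definitions", {
    st <- classifySetup()
    lab <- function(s, e) classifyOrf(orfRow(s, e), st$ann, st$txs)
    expect_equal(lab(301L, 600L), "annotated")
    expect_equal(lab(331L, 600L), "truncated")       # in-frame, same stop
    expect_equal(lab(271L, 600L), "extended")        # upstream, same stop
    expect_equal(lab(10L, 90L), "uORF")              # inside 5'UTR
    expect_equal(lab(250L, 360L), "overlapped_uORF") # 5'UTR into CDS
    expect_equal(lab(610L, 690L), "dORF")            # inside 3'UTR
    expect_equal(lab(500L, 640L), "overlapped_dORF") # CDS (out of frame) into 3'UTR
    expect_equal(lab(350L, 499L), "internal_ORF")    # contained, other frame
})

test_that("biotype labels take precedence over position", {
    for (case in list(c("transposable_element", "TE_ORF"),
                      c("pseudogene", "pseudogene_ORF"),
                      c("lncRNA", "ncRNA_ORF"))) {
        st <- classifySetup(biotype = case[1])
        expect_equal(classifyOrf(orfRow(301L, 600L), st$ann, st$txs),
                     case[2])
    }
    # a coding-biotype transcript without CDS hosts ncRNA ORFs
    st <- classifySetup(withCds = FALSE)
    expect_equal(classifyOrf(orfRow(10L, 90L), st$ann, st$txs), "ncRNA_ORF")
})

test_that("missing annotation or missing overlap yields novel", {
    st <- classifySetup()
    expect_equal(classifyOrf(orfRow(301L, 600L), NULL, NULL), "novel")
    # ORF on an unknown transcript but genomically inside t1's exons
    row <- orfRow(331L, 600L, tid = "unknown_tx")
    expect_equal(classifyOrf(row, st$ann, st$txs), "truncated")
    # no genomic overlap with anything annotated
    far <- data.frame(transcript_id = "unknown_tx", seqid = "chrZ",
                      strand = "+", blocks = "5-64", tx_start = 5L,
                      tx_end = 64L, stringsAsFactors = FALSE)
    expect_equal(classifyOrf(far, st$ann, st$txs), "novel")
})

test_that("random fixtures agree with an independent rule evaluation", {
    # independent re-derivation of the category from raw interval and
    # frame arithmetic (biotype fixed to coding, single-exon host)
    oracle <- function(s, e, cdsS, cdsE) {
        inFrame <- (s - cdsS) %% 3L == 0L
        if (s == cdsS && e == cdsE) "annotated"
        else if (e == cdsE && s > cdsS && inFrame) "truncated"
        else if (e == cdsE && s < cdsS && inFrame) "extended"
        else if (e < cdsS) "uORF"
        else if (s < cdsS && e > cdsS) "overlapped_uORF"
        else if (s > cdsE) "dORF"
        else if (s <= cdsE && e > cdsE && !inFrame) "overlapped_dORF"
        else if (s >= cdsS && e <= cdsE) "internal_ORF"
        else NA_character_
    }
    st <- classifySetup()
    set.seed(41)
    n <- 0L
    while (n < 200L) {
        s <- sample(1:880, 1)
        e <- s + 3L * sample(2:60, 1) - 1L
        if (e > 900L) next
        want <- oracle(s, e, 301L, 600L)
        if (is.na(want)) next  # in-frame read-through cannot arise from a scan
        n <- n + 1L
        expect_equal(classifyOrf(orfRow(s, e), st$ann, st$txs), want,
                     info = sprintf("s=%d e=%d", s, e))
    }
})

test_that("classification summarises to a partition", {
    sim <- smallSim()
    cfg <- callerConfig()
    tab <- trainCodonUsage(sim$transcripts, sim$track, cfg)
    orfs <- predictOrfs(sim$transcripts, sim$track, tab, cfg)
    cl <- classifyOrfs(orfs, sim$annotation, sim$transcripts)
    expect_equal(sum(cl$summary), nrow(orfs))
    expect_true(all(cl$orfs$category %in% orfCategories()))

    # permutation invariance of the summary
    perm <- orfs[sample(nrow(orfs)), ]
    cl2 <- classifyOrfs(perm, sim$annotation, sim$transcripts)
    expect_equal(cl2$summary, cl$summary)
    # re-classification is deterministic
    cl3 <- classifyOrfs(cl$orfs, sim$annotation, sim$transcripts)
    expect_equal(cl3$orfs$category, cl$orfs$category)

    # empty input and absent annotation
    cl0 <- classifyOrfs(orfs[0, ], sim$annotation, sim$transcripts)
    expect_equal(sum(cl0$summary), 0L)
    clN <- classifyOrfs(orfs, NULL, NULL)
    expect_true(all(clN$orfs$category == "novel"))
})

test_that("planted uORFs and dORFs are predicted and labelled", {
    p <- simulationParams(nGenes = 25L, seed = 19L, nUorfsPerGene = 1L,
                          nDorfsPerGene = 1L, sorfLen = c(60L, 90L),
                          utr5Len = c(200L, 300L), utr3Len = c(200L, 300L))
    sim <- simulateGenome(p)
    trk <- simulateDiversity(sim$genome, sim$annotation, sim$manifest, p)
    txs <- buildTranscripts(sim$genome, sim$annotation)
    cfg <- callerConfig()
    tab <- trainCodonUsage(txs, trk, cfg)
    orfs <- predictOrfs(txs, trk, tab, cfg)
    cl <- classifyOrfs(orfs, sim$annotation, txs)
    m <- sim$manifest$orfs
    uKeys <- paste(m$seqid, m$strand, m$blocks, sep = "|")[m$type == "uORF"]
    dKeys <- paste(m$seqid, m$strand, m$blocks, sep = "|")[m$type == "dORF"]
    keys <- orfIdentity(cl$orfs)
    hitU <- keys %in% uKeys
    hitD <- keys %in% dKeys
    # sORFs carry much weaker signal than 300+ nt CDSs; some must still
    # be recovered, and every recovered one must be labelled correctly
    expect_gt(sum(hitU), 0L)
    expect_gt(sum(hitD), 0L)
    expect_true(all(cl$orfs$category[hitU] == "uORF"))
    expect_true(all(cl$orfs$category[hitD] == "dORF"))
})
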