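# Shared fixtures, all built in code.

simCache <- new.env(parent = emptyenv())

# one moderate simulated dataset reused across test files
smallSim <- function() {
    if (is.null(simCache$small)) {
        p <- simulationParams(nGenes = 40L, seed = 7L)
        sim <- simulateGenome(p)
        trk <- simulateDiversity(sim$genome, sim$annotation, sim$manifest, p)
        txs <- buildTranscripts(sim$genome, sim$annotation)
        simCache$small <- list(params = p, genome = sim$genome,
                               annotation = sim$annotation,
                               manifest = sim$manifest, track = trk,
                               transcripts = txs)
    }
    simCache$small
}

writeTempFasta <- function(seqs, ext = ".fa") {
    tf <- tempfile(fileext = ext)
    writeLines(unlist(lapply(names(seqs), function(nm)
        c(paste0(">", nm), seqs[[nm]]))), tf)
    tf
}

writeTempGtf <- function(lines) {
    tf <- tempfile(fileext = ".gtf")
    writeLines(lines, tf)
    tf
}

gtfLine <- function(seqid, type, start, end, strand, tid, gid = "g1",
                    biotype = NULL) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
    if (!is.null(biotype))
        attrs <- paste0(attrs, sprintf(' transcript_biotype "%s";', biotype))
    sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\t%s",
            seqid, type, start, end, strand, attrs)
}

writeTempPi <- function(df) {
    tf <- tempfile(fileext = ".pi")
    writeLines(c("CHROM\tPOS\tPI",
                 sprintf("%s\t%d\t%s", df$seqid, df$pos,
                         format(df$pi, scientific = FALSE))), tf)
    tf
}

# in-memory AnnotationSet for one transcript
makeAnnotation <- function(exons, cds = NULL, strand = "+", seqid = "chrT",
                           tid = "t1", gid = "g1",
                           biotype = "protein_coding") {
    exGr <- GenomicRanges::GRanges(seqid,
        IRanges::IRanges(exons[, 1], exons[, 2]), strand = strand)
    cdGr <- if (is.null(cds)) GenomicRanges::GRanges()
            else GenomicRanges::GRanges(seqid,
                IRanges::IRanges(cds[, 1], cds[, 2]), strand = strand)
    new("AnnotationSet",
        exons = GenomicRanges::GRangesList(list(exGr)),
        cds = GenomicRanges::GRangesList(list(cdGr)),
        tx = data.frame(transcript_id = tid, gene_id = gid, seqid = seqid,
                        strand = strand, biotype = biotype, usable = TRUE,
                        stringsAsFactors = FALSE))
}

# a single-exon plus-strand transcript model over its own sequence
makeTxModel <- function(seq, cdsStart = NA_integer_, cdsEnd = NA_integer_,
                        tid = "t1", gid = "g1", seqid = "chrT",
                        biotype = "protein_coding") {
    n <- nchar(seq)
    new("TranscriptModel", transcriptId = tid, geneId = gid, seqid = seqid,
        strand = "+", exons = IRanges::IRanges(1L, n), sequence = seq,
        gpos = seq_len(n), cdsTxStart = as.integer(cdsStart),
        cdsTxEnd = as.integer(cdsEnd), biotype = biotype)
}

# independent textbook pooled-variance one-sided t (oracle)
pooledTOracle <- function(a, b) {
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    tt <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
    pt(tt, na + nb - 2, lower.tail = FALSE)
}

# raw periodogram peak frequency on the same zero-padded grid (oracle)
periodogramPeak <- function(x, zeroPad = 4L) {
    n <- length(x); N <- zeroPad * n
    xc <- x - mean(x)
    sp <- Mod(fft(c(xc, rep(0, N - n)))[2:(N %/% 2 + 1)])^2
    freqs <- (1:(N %/% 2)) / N
    freqs[which.max(sp)]
}

manifestKeys <- function(manifest, type = "main") {
    m <- manifest$orfs
    m <- m[m$type == type, , drop = FALSE]
    paste(m$seqid, m$strand, m$blocks, sep = "|")
}

# the full-size default simulation (acceptance scale), cached
defaultSim <- function() {
    if (is.null(simCache$default)) {
        p <- simulationParams(seed = 1L)   # 200 genes, default conditions
        sim <- simulateGenome(p)
        trk <- simulateDiversity(sim$genome, sim$annotation, sim$manifest, p)
        txs <- buildTranscripts(sim$genome, sim$annotation)
        simCache$default <- list(params = p, genome = sim$genome,
                                 annotation = sim$annotation,
                                 manifest = sim$manifest, track = trk,
                                 transcripts = txs)
    }
    simCache$default
}
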