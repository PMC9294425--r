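#' Construct simulation parameters
#'
#' Defaults describe a small eukaryote-like genome sized for routine
#' testing: 200 multi-exon protein-coding genes with UTRs and intergenic
#' spacers, CDS 300-1500 nt, and per-site diversity elevated at wobble
#' positions (segregating-site probability 0.10 at wobble vs 0.03
#' elsewhere; pi given segregating is exponential with mean 0.15 at wobble
#' vs 0.05 elsewhere).
#'
#' @param nGenes number of genes.
#' @param exonsPerGene,utr5Len,utr3Len,cdsLen,intronLen,spacerLen inclusive
#'   integer ranges c(lo, hi); cdsLen and sorfLen in multiples of 3.
#' @param codonFreq optional named sense-codon frequency vector; NULL draws
#'   a skew once from a symmetric Dirichlet (gamma normalisation) with
#'   concentration `codonSkew`.
#' @param codonSkew Dirichlet concentration for the drawn codon skew.
#' @param segProb,piMean named per-class values (wobble, nonwobble, utr,
#'   intergenic).
#' @param nUorfsPerGene,nDorfsPerGene planted sORFs per gene.
#' @param sorfLen planted sORF length range (multiples of 3).
#' @param seed integer seed.
#' @return a [SimulationParams-class].
#' @export
simulationParams <- function(nGenes = 200L, exonsPerGene = c(1L, 4L),
                             utr5Len = c(80L, 300L), utr3Len = c(80L, 300L),
                             cdsLen = c(300L, 1500L), intronLen = c(60L, 200L),
                             spacerLen = c(200L, 800L), codonFreq = NULL,
                             codonSkew = 1,
                             segProb = c(wobble = 0.10, nonwobble = 0.03,
                                         utr = 0.03, intergenic = 0.03),
                             piMean = c(wobble = 0.15, nonwobble = 0.05,
                                        utr = 0.05, intergenic = 0.05),
                             nUorfsPerGene = 0L, nDorfsPerGene = 0L,
                             sorfLen = c(30L, 90L), seed = 1L) {
    new("SimulationParams", nGenes = as.integer(nGenes),
        exonsPerGene = as.integer(exonsPerGene),
        utr5Len = as.integer(utr5Len), utr3Len = as.integer(utr3Len),
        cdsLen = as.integer(cdsLen), intronLen = as.integer(intronLen),
        spacerLen = as.integer(spacerLen), codonFreq = codonFreq,
        codonSkew = codonSkew, segProb = segProb, piMean = piMean,
        nUorfsPerGene = as.integer(nUorfsPerGene),
        nDorfsPerGene = as.integer(nDorfsPerGene),
        sorfLen = as.integer(sorfLen), seed = as.integer(seed))
}

.sampleRange <- function(rng) {
    if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
}

# random sequence free of the ATG trinucleotide (so UTRs plant no
# spurious starts and main ORFs cannot be extended upstream)
.randomSeqNoAtg <- function(len) {
    if (len == 0L) return("")
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    while (grepl("ATG", s, fixed = TRUE))
        s <- gsub("ATG", "ATC", s, fixed = TRUE)
    s
}

.randomSeq <- function(len) {
    if (len == 0L) return("")
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# an ORF sequence of `len` nt: ATG + sense codons + stop
.randomOrf <- function(len, codons, freq) {
    ncod <- len %/% 3L - 2L
    paste0("ATG",
           paste(sample(codons, ncod, replace = TRUE, prob = freq),
                 collapse = ""),
           sample(stopCodons(), 1L))
}

#' Simulate a genome, annotation and truth manifest
#'
#' Lays out genes separated by intergenic spacers on one chromosome.
#' Each gene is a spliced transcript 5'UTR + CDS + 3'UTR cut into exons by
#' random introns; half the genes sit on the minus strand. CDS codons are
#' drawn from the codon-usage generator; UTRs are generated free of ATG so
#' that every planted start is the 5'-most in its frame. Optional uORFs
#' and dORFs are planted inside the UTRs. Output is reproducible
#' byte-for-byte for a fixed seed.
#'
#' @param params a [SimulationParams-class].
#' @return list with `genome` (DNAStringSet), `annotation`
#'   (AnnotationSet), `manifest` (list: `orfs` data.frame of planted ORFs
#'   with genomic blocks and transcript coordinates, `codonFreq`, `seed`).
#' @export
simulateGenome <- function(params = simulationParams()) {
    set.seed(params@seed)
    codons <- senseCodons()
    freq <- params@codonFreq
    if (is.null(freq)) {
        g <- rgamma(length(codons), shape = params@codonSkew)
        freq <- setNames(g / sum(g), codons)
    } else {
        freq <- freq[codons]
        freq[is.na(freq)] <- 0
        freq <- setNames(freq / sum(freq), codons)
    }
    chromParts <- character(0)
    offset <- 0L
    exl <- list(); cdl <- list(); txrows <- list(); orfrows <- list()
    for (gi in seq_len(params@nGenes)) {
        len5 <- .sampleRange(params@utr5Len)
        len3 <- .sampleRange(params@utr3Len)
        ncods <- params@cdsLen %/% 3L
        lenC <- 3L * .sampleRange(ncods)
        utr5 <- .randomSeqNoAtg(len5)
        utr3 <- .randomSeqNoAtg(len3)
        cds <- .randomOrf(lenC, codons, freq)
        tid <- sprintf("tx%04d", gi); gid <- sprintf("g%04d", gi)
        strand <- if (gi %% 2L == 0L) "-" else "+"
        # plant sORFs into the UTRs (never overlapping each other)
        plant <- function(utr, n, base) {
            placed <- list(); used <- integer(0)
            for (j in seq_len(n)) {
                sl <- 3L * .sampleRange(params@sorfLen %/% 3L)
                if (sl + 6L > nchar(utr)) next
                for (try in 1:20) {
                    p <- sample.int(nchar(utr) - sl + 1L, 1L)
                    if (!any(used %in% p:(p + sl - 1L))) break
                    p <- NA_integer_
                }
                if (is.na(p)) next
                substr(utr, p, p + sl - 1L) <- .randomOrf(sl, codons, freq)
                used <- c(used, p:(p + sl - 1L))
                placed[[length(placed) + 1L]] <- c(start = p, len = sl)
            }
            list(utr = utr, placed = placed)
        }
        u5p <- plant(utr5, params@nUorfsPerGene, 0L)
        utr5 <- u5p$utr
        u3p <- plant(utr3, params@nDorfsPerGene, 0L)
        utr3 <- u3p$utr
        txseq <- paste0(utr5, cds, utr3)
        Lt <- nchar(txseq)
        cs <- len5 + 1L; ce <- len5 + lenC
        # cut into exons
        nEx <- .sampleRange(params@exonsPerGene)
        nEx <- min(nEx, Lt - 1L)
        cuts <- if (nEx > 1L) sort(sample(2:(Lt - 1L), nEx - 1L)) else integer(0)
        ta <- c(1L, cuts); tb <- c(cuts - 1L, Lt)
        # unspliced (transcript-orientation) sequence with introns
        ua <- integer(nEx); ub <- integer(nEx)
        parts <- character(0); upos <- 0L
        for (k in seq_len(nEx)) {
            ua[k] <- upos + 1L
            parts <- c(parts, substr(txseq, ta[k], tb[k]))
            upos <- upos + (tb[k] - ta[k] + 1L)
            ub[k] <- upos
            if (k < nEx) {
                intr <- .randomSeq(.sampleRange(params@intronLen))
                parts <- c(parts, intr)
                upos <- upos + nchar(intr)
            }
        }
        U <- paste(parts, collapse = "")
        Lu <- nchar(U)
        spacer <- .randomSeq(.sampleRange(params@spacerLen))
        chromParts <- c(chromParts, spacer,
                        if (strand == "+") U else revComp(U))
        geneStart <- offset + nchar(spacer) + 1L
        offset <- offset + nchar(spacer) + Lu
        toGenomic <- function(u1, u2) {  # unspliced interval -> genomic
            if (strand == "+") c(geneStart - 1L + u1, geneStart - 1L + u2)
            else c(geneStart + Lu - u2, geneStart + Lu - u1)
        }
        exonBlocks <- t(vapply(seq_len(nEx),
                               function(k) toGenomic(ua[k], ub[k]),
                               integer(2)))
        txToGenomicBlocks <- function(s, e) {
            blocks <- list()
            for (k in seq_len(nEx)) {
                os <- max(s, ta[k]); oe <- min(e, tb[k])
                if (os > oe) next
                blocks[[length(blocks) + 1L]] <-
                    toGenomic(ua[k] + (os - ta[k]), ua[k] + (oe - ta[k]))
            }
            m <- do.call(rbind, blocks)
            m[order(m[, 1]), , drop = FALSE]
        }
        cdsBlocks <- txToGenomicBlocks(cs, ce)
        exl[[gi]] <- GenomicRanges::GRanges(
            "chr1", IRanges::IRanges(exonBlocks[, 1], exonBlocks[, 2]),
            strand = strand)
        cdl[[gi]] <- GenomicRanges::GRanges(
            "chr1", IRanges::IRanges(cdsBlocks[, 1], cdsBlocks[, 2]),
            strand = strand)
        txrows[[gi]] <- data.frame(
            transcript_id = tid, gene_id = gid, seqid = "chr1",
            strand = strand, biotype = "protein_coding", usable = TRUE,
            stringsAsFactors = FALSE)
        mkOrfRow <- function(type, s, e) {
            bl <- txToGenomicBlocks(s, e)
            data.frame(type = type, gene_id = gid, transcript_id = tid,
                       seqid = "chr1", strand = strand,
                       blocks = formatBlocks(unlist(lapply(
                           seq_len(nrow(bl)), function(r) bl[r, 1]:bl[r, 2]))),
                       tx_start = s, tx_end = e, length_nt = e - s + 1L,
                       stringsAsFactors = FALSE)
        }
        orfrows[[length(orfrows) + 1L]] <- mkOrfRow("main", cs, ce)
        for (pl in u5p$placed)
            orfrows[[length(orfrows) + 1L]] <-
                mkOrfRow("uORF", pl["start"], pl["start"] + pl["len"] - 1L)
        for (pl in u3p$placed)
            orfrows[[length(orfrows) + 1L]] <-
                mkOrfRow("dORF", ce + pl["start"],
                         ce + pl["start"] + pl["len"] - 1L)
    }
    chromParts <- c(chromParts, .randomSeq(.sampleRange(params@spacerLen)))
    genome <- Biostrings::DNAStringSet(
        setNames(paste(chromParts, collapse = ""), "chr1"))
    annotation <- if (params@nGenes > 0L)
        new("AnnotationSet", exons = GenomicRanges::GRangesList(exl),
            cds = GenomicRanges::GRangesList(cdl),
            tx = do.call(rbind, txrows))
    else new("AnnotationSet", exons = GenomicRanges::GRangesList(),
             cds = GenomicRanges::GRangesList(),
             tx = data.frame(transcript_id = character(),
                             gene_id = character(), seqid = character(),
                             strand = character(), biotype = character(),
                             usable = logical()))
    manifest <- list(
        orfs = if (length(orfrows)) do.call(rbind, orfrows)
               else data.frame(),
        codonFreq = freq, seed = params@seed)
    list(genome = genome, annotation = annotation, manifest = manifest)
}

#' Simulate a per-site diversity track over a simulated genome
#'
#' Every site segregates independently with its class probability
#' (wobble / nonwobble CDS / UTR / intergenic; introns count as
#' intergenic); segregating sites draw pi from an exponential with the
#' class mean. Wobble positions of planted uORFs/dORFs are elevated like
#' CDS wobble positions. Non-variant sites are omitted from the track.
#'
#' @param genome,annotation,manifest output of [simulateGenome()].
#' @param params the same [SimulationParams-class].
#' @param seed seed for the diversity draw (default params@seed + 1).
#' @return a [DiversityTrack-class].
#' @export
simulateDiversity <- function(genome, annotation, manifest,
                              params = simulationParams(),
                              seed = params@seed + 1L) {
    set.seed(seed)
    txs <- buildTranscripts(genome, annotation)
    CLS_INTERGENIC <- 0L; CLS_UTR <- 1L; CLS_NONWOBBLE <- 2L; CLS_WOBBLE <- 3L
    clsBySeq <- lapply(Biostrings::width(genome), integer)
    names(clsBySeq) <- names(genome)
    mark <- function(seqid, pos, val) {
        cur <- clsBySeq[[seqid]][pos]
        clsBySeq[[seqid]][pos] <<- pmax(cur, val)
    }
    for (tx in txs) {
        L <- length(tx@gpos)
        cls <- rep(CLS_UTR, L)
        if (!is.na(tx@cdsTxStart)) {
            idx <- tx@cdsTxStart:tx@cdsTxEnd
            fr <- (idx - tx@cdsTxStart) %% 3L
            cls[idx] <- ifelse(fr == 2L, CLS_WOBBLE, CLS_NONWOBBLE)
        }
        mark(tx@seqid, tx@gpos, cls)
    }
    morfs <- manifest$orfs
    if (is.data.frame(morfs) && nrow(morfs)) {
        extra <- morfs[morfs$type != "main", , drop = FALSE]
        for (i in seq_len(nrow(extra))) {
            tx <- txs[[extra$transcript_id[i]]]
            idx <- extra$tx_start[i]:extra$tx_end[i]
            fr <- (idx - extra$tx_start[i]) %% 3L
            mark(tx@seqid, tx@gpos[idx],
                 ifelse(fr == 2L, CLS_WOBBLE, CLS_NONWOBBLE))
        }
    }
    pvec <- params@segProb[c("intergenic", "utr", "nonwobble", "wobble")]
    mvec <- params@piMean[c("intergenic", "utr", "nonwobble", "wobble")]
    sites <- list()
    for (sq in names(clsBySeq)) {
        cls <- clsBySeq[[sq]]
        p <- pvec[cls + 1L]
        seg <- runif(length(cls)) < p
        if (!any(seg)) next
        pos <- which(seg)
        piv <- rexp(length(pos), rate = 1 / mvec[cls[pos] + 1L])
        sites[[sq]] <- data.frame(seqid = sq, pos = pos, pi = piv)
    }
    if (!length(sites)) return(diversityTrack())
    diversityTrack(do.call(rbind, sites))
}

#' Thin a diversity track to emulate smaller populations
#'
#' Smaller population samples detect fewer segregating sites; each stored
#' site is retained independently with probability equal to the sampling
#' fraction. Fraction 1 returns the track unchanged; fraction 0 an empty
#' track.
#'
#' @param track a DiversityTrack.
#' @param fractions numeric vector in [0, 1].
#' @param seed integer seed.
#' @return named list of DiversityTracks, one per fraction.
#' @export
subsamplePopulation <- function(track, fractions, seed = 1L) {
    set.seed(seed)
    sites <- trackSites(track)
    out <- lapply(fractions, function(f) {
        if (f >= 1) return(track)
        if (f <= 0 || !nrow(sites)) return(diversityTrack())
        keep <- runif(nrow(sites)) < f
        diversityTrack(sites[keep, , drop = FALSE])
    })
    names(out) <- as.character(fractions)
    out
}

#' Write a simulated dataset to disk
#'
#' Emits genome.fa, annotation.gtf, sites.pi (CHROM/POS/PI dialect) and
#' manifest.json under `dir`.
#'
#' @param sim list from [simulateGenome()].
#' @param track DiversityTrack from [simulateDiversity()].
#' @param dir output directory (created if missing).
#' @return invisible named vector of the four paths.
#' @export
writeSimulation <- function(sim, track, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(genome = file.path(dir, "genome.fa"),
               gtf = file.path(dir, "annotation.gtf"),
               pi = file.path(dir, "sites.pi"),
               manifest = file.path(dir, "manifest.json"))
    writeGenome(sim$genome, paths["genome"])
    writeAnnotationGtf(sim$annotation, paths["gtf"])
    writeSitePi(track, paths["pi"])
    jsonlite::write_json(
        list(orfs = sim$manifest$orfs,
             codonFreq = as.list(sim$manifest$codonFreq),
             seed = sim$manifest$seed),
        paths["manifest"], auto_unbox = TRUE, digits = NA)
    invisible(paths)
}
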