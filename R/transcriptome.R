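#' Build spliced transcript models
#'
#' Splices exon blocks out of the genome and reverse-complements minus
#' strand transcripts. Each model stores the per-position genomic
#' coordinate map used to project diversity and to report predicted ORFs
#' in genomic coordinates. The CDS interval (stop codon included) is
#' converted to transcript coordinates when present; a CDS whose length is
#' not a multiple of 3 is kept but flagged with a warning.
#'
#' @param genome DNAStringSet from [readGenome()].
#' @param annotation AnnotationSet from [readAnnotation()].
#' @return named list of [TranscriptModel-class], keyed by transcript_id.
#' @export
buildTranscripts <- function(genome, annotation) {
    txs <- annotation@tx
    gseq <- as.character(genome)
    out <- vector("list", nrow(txs))
    names(out) <- txs$transcript_id
    for (i in seq_len(nrow(txs))) {
        info <- txs[i, ]
        ex <- annotation@exons[[i]]
        if (!info$seqid %in% names(gseq))
            stop(sprintf("transcript '%s': sequence '%s' absent from genome",
                         info$transcript_id, info$seqid))
        chrlen <- nchar(gseq[[info$seqid]])
        ord <- order(GenomicRanges::start(ex))
        st <- GenomicRanges::start(ex)[ord]; en <- GenomicRanges::end(ex)[ord]
        if (any(en > chrlen) || any(st < 1))
            stop(sprintf("transcript '%s': exon beyond sequence end",
                         info$transcript_id))
        plus <- paste(substring(gseq[[info$seqid]], st, en), collapse = "")
        gpos <- unlist(lapply(seq_along(st),
                              function(j) st[j]:en[j]), use.names = FALSE)
        if (info$strand == "-") {
            seq <- revComp(plus)
            gpos <- rev(gpos)
        } else seq <- plus
        cdsS <- NA_integer_; cdsE <- NA_integer_
        cd <- annotation@cds[[i]]
        if (length(cd) && info$usable) {
            cpos <- unlist(lapply(seq_along(cd), function(j)
                GenomicRanges::start(cd)[j]:GenomicRanges::end(cd)[j]),
                use.names = FALSE)
            tpos <- sort(match(cpos, gpos))
            if (anyNA(tpos)) {
                warning(sprintf(
                    "transcript '%s': CDS positions outside exons; CDS dropped",
                    info$transcript_id))
            } else {
                cdsS <- tpos[1]; cdsE <- tpos[length(tpos)]
                if ((cdsE - cdsS + 1L) %% 3L != 0L)
                    warning(sprintf(
                        "transcript '%s': CDS length not a multiple of 3",
                        info$transcript_id))
            }
        }
        out[[i]] <- new("TranscriptModel",
            transcriptId = info$transcript_id, geneId = info$gene_id,
            seqid = info$seqid, strand = info$strand,
            exons = IRanges::IRanges(st, en), sequence = seq,
            gpos = as.integer(gpos), cdsTxStart = cdsS, cdsTxEnd = cdsE,
            biotype = info$biotype)
    }
    out
}

setMethod("show", "TranscriptModel", function(object) {
    cat(sprintf("TranscriptModel %s (%s, %s%s): %d nt, %d exon(s)%s\n",
                object@transcriptId, object@seqid, object@strand,
                if (object@biotype == "protein_coding") ""
                else paste0(", ", object@biotype),
                length(object@gpos), length(object@exons),
                if (is.na(object@cdsTxStart)) ", no CDS"
                else sprintf(", CDS %d-%d", object@cdsTxStart,
                             object@cdsTxEnd)))
})

#' Spliced sequence of a transcript model
#' @param tx TranscriptModel.
#' @export
txSequence <- function(tx) tx@sequence

#' Genomic position underlying each transcript position
#' @param tx TranscriptModel.
#' @return integer vector, 1-based genomic positions.
#' @export
genomicPositions <- function(tx) tx@gpos

#' CDS interval in transcript coordinates (stop codon included)
#' @param tx TranscriptModel.
#' @return integer c(start, end) or c(NA, NA).
#' @export
cdsTxRange <- function(tx) c(tx@cdsTxStart, tx@cdsTxEnd)

#' Project genomic diversity onto a transcript
#'
#' Value at transcript position t is the pi at the genomic site underlying
#' t; pi is strand-symmetric and absent sites read 0, so the projection is
#' total.
#'
#' @param tx TranscriptModel.
#' @param track DiversityTrack.
#' @return numeric vector, length = transcript length.
#' @export
projectDiversity <- function(tx, track) {
    piAt(track, tx@seqid, tx@gpos)
}

#' Extract fixed-length diversity windows for metagene analysis
#'
#' Per coding transcript: the first `window` nt of the CDS, the `window` nt
#' immediately upstream of the start codon (5'UTR set) and the `window` nt
#' immediately downstream of the stop codon (3'UTR set). A transcript whose
#' region is shorter than `window` is excluded from that set only.
#'
#' @param transcripts list of TranscriptModel.
#' @param track DiversityTrack.
#' @param window window length in nt (default 50).
#' @return list with matrices `CDS`, `UTR5`, `UTR3` (rows = windows).
#' @export
extractMetageneRegions <- function(transcripts, track, window = 50L) {
    stopifnot(window > 0)
    cds <- list(); u5 <- list(); u3 <- list()
    for (tx in transcripts) {
        if (is.na(tx@cdsTxStart)) next
        dv <- projectDiversity(tx, track)
        L <- length(dv)
        s <- tx@cdsTxStart; e <- tx@cdsTxEnd
        if (e - s + 1L >= window)
            cds[[length(cds) + 1L]] <- dv[s:(s + window - 1L)]
        if (s - 1L >= window)
            u5[[length(u5) + 1L]] <- dv[(s - window):(s - 1L)]
        if (L - e >= window)
            u3[[length(u3) + 1L]] <- dv[(e + 1L):(e + window)]
    }
    tomat <- function(lst) {
        if (!length(lst)) matrix(numeric(0), ncol = window)
        else do.call(rbind, lst)
    }
    list(CDS = tomat(cds), UTR5 = tomat(u5), UTR3 = tomat(u3))
}

# genomic spans of annotated genes (union over transcripts, both strands)
geneSpans <- function(annotation) {
    if (!nrow(annotation@tx))
        return(GenomicRanges::GRanges())
    spans <- lapply(seq_len(nrow(annotation@tx)), function(i) {
        ex <- annotation@exons[[i]]
        GenomicRanges::GRanges(annotation@tx$seqid[i],
                               IRanges::IRanges(
                                   min(GenomicRanges::start(ex)),
                                   max(GenomicRanges::end(ex))))
    })
    GenomicRanges::reduce(do.call(c, spans), ignore.strand = TRUE)
}

#' Sample random intergenic diversity windows
#'
#' Intergenic space is the complement of annotated gene spans (both
#' strands) within each sequence. Windows are sampled uniformly with
#' replacement among all fully-intergenic placements; sampling is
#' reproducible for a fixed seed.
#'
#' @param genome DNAStringSet (supplies sequence lengths).
#' @param annotation AnnotationSet.
#' @param track DiversityTrack.
#' @param n number of windows (default 10000).
#' @param width window width in nt (default 50).
#' @param seed integer seed.
#' @return matrix n x width of pi values; attribute "positions" holds a
#'   data.frame of the sampled (seqid, start).
#' @export
sampleIntergenicWindows <- function(genome, annotation, track,
                                    n = 10000L, width = 50L, seed = 1L) {
    spans <- geneSpans(annotation)
    free <- list()
    for (sq in names(genome)) {
        L <- Biostrings::width(genome)[match(sq, names(genome))]
        sub <- sort(spans[as.character(GenomicRanges::seqnames(spans)) == sq])
        gs <- c(1L, GenomicRanges::end(sub) + 1L)
        ge <- c(GenomicRanges::start(sub) - 1L, L)
        keep <- (ge - gs + 1L) >= width
        if (any(keep))
            free[[sq]] <- data.frame(start = gs[keep],
                                     nStarts = ge[keep] - gs[keep] - width + 2L)
    }
    if (!length(free)) stop("no intergenic region of the requested width")
    tab <- do.call(rbind, lapply(names(free), function(sq)
        cbind(seqid = sq, free[[sq]])))
    set.seed(seed)
    iv <- sample.int(nrow(tab), n, replace = TRUE, prob = tab$nStarts)
    off <- floor(runif(n) * tab$nStarts[iv])
    starts <- tab$start[iv] + as.integer(off)
    out <- matrix(0, nrow = n, ncol = width)
    for (i in seq_len(n))
        out[i, ] <- piAt(track, tab$seqid[iv[i]],
                         starts[i]:(starts[i] + width - 1L))
    attr(out, "positions") <- data.frame(seqid = tab$seqid[iv], start = starts)
    out
}
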