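#' The twelve ORF category labels
#'
#' Eleven annotation-relative categories plus "novel" (used for every ORF
#' when no annotation is supplied, and for ORFs overlapping nothing
#' annotated).
#' @return character vector of labels in precedence-display order.
#' @export
orfCategories <- function() {
    c("annotated", "truncated", "extended", "uORF", "overlapped_uORF",
      "dORF", "overlapped_dORF", "ncRNA_ORF", "internal_ORF", "TE_ORF",
      "pseudogene_ORF", "novel")
}

# positional classification of an ORF [s, e] (transcript coords, stop
# included) against the host CDS [cdsS, cdsE] (stop included).
# Precedence: exact > stop-sharing in-frame > UTR-relative > internal.
.classifyPositional <- function(s, e, cdsS, cdsE) {
    if (s == cdsS && e == cdsE) return("annotated")
    if (e == cdsE && s > cdsS && (s - cdsS) %% 3L == 0L) return("truncated")
    if (e == cdsE && s < cdsS && (cdsS - s) %% 3L == 0L) return("extended")
    if (e < cdsS) return("uORF")
    if (s < cdsS) return("overlapped_uORF")   # starts in 5'UTR, enters CDS
    if (s > cdsE) return("dORF")
    if (e > cdsE) return("overlapped_dORF")   # starts in CDS (out of frame)
    "internal_ORF"                            # contained, different frame
}

.biotypeCategory <- function(biotype, hasCds) {
    if (grepl("transposable|transposon|^TE$", biotype, ignore.case = TRUE))
        return("TE_ORF")
    if (grepl("pseudogene", biotype, ignore.case = TRUE))
        return("pseudogene_ORF")
    if (!hasCds || grepl("non.?coding|ncRNA|lncRNA|lincRNA",
                         biotype, ignore.case = TRUE))
        return("ncRNA_ORF")
    NA_character_
}

# try to express an ORF (genomic blocks, strand) in the transcript
# coordinates of `tx`; NULL when the ORF is not exon-contained
.mapToTranscript <- function(blocks, strand, tx) {
    if (strand != tx@strand) return(NULL)
    m <- parseBlocks(blocks)
    gp <- unlist(lapply(seq_len(nrow(m)),
                        function(i) m[i, "start"]:m[i, "end"]))
    tp <- match(gp, tx@gpos)
    if (anyNA(tp)) return(NULL)
    tp <- sort(tp)
    if (any(diff(tp) != 1L)) return(NULL)  # must be contiguous on the tx
    c(tp[1], tp[length(tp)])
}

#' Classify one predicted ORF against the annotation
#'
#' Category precedence: host-biotype labels (TE, pseudogene, ncRNA) first,
#' then exact identity with the annotated CDS, then stop-sharing in-frame
#' (truncated/extended), then UTR-relative (uORF, overlapped uORF, dORF,
#' overlapped dORF), then internal (CDS-contained, different frame).
#' Overlapped dORFs are required to be out of frame with the CDS; an
#' in-frame start inside the CDS necessarily shares the annotated stop and
#' is classified truncated. An ORF on a transcript absent from the
#' annotation is classified through any annotated transcript whose exons
#' contain it; with no such transcript it is "novel".
#'
#' @param orf one-row slice of an ORF table (needs transcript_id, seqid,
#'   strand, blocks, tx_start, tx_end).
#' @param annotation AnnotationSet or NULL (everything "novel").
#' @param transcripts transcript models built from the same annotation
#'   (required when `annotation` is given).
#' @return a category label from [orfCategories()].
#' @export
classifyOrf <- function(orf, annotation, transcripts = NULL) {
    if (is.null(annotation) || !nrow(annotation@tx)) return("novel")
    txid <- orf$transcript_id
    hostIdx <- match(txid, annotation@tx$transcript_id)
    if (!is.na(hostIdx)) {
        tx <- transcripts[[txid]]
        bio <- .biotypeCategory(annotation@tx$biotype[hostIdx],
                                !is.na(tx@cdsTxStart))
        if (!is.na(bio)) return(bio)
        return(.classifyPositional(orf$tx_start, orf$tx_end,
                                   tx@cdsTxStart, tx@cdsTxEnd))
    }
    # unannotated host transcript: classify via genomic containment
    m <- parseBlocks(orf$blocks)
    for (cand in transcripts) {
        if (cand@seqid != orf$seqid) next
        tp <- .mapToTranscript(orf$blocks, orf$strand, cand)
        if (is.null(tp)) next
        idx <- match(cand@transcriptId, annotation@tx$transcript_id)
        bio <- .biotypeCategory(annotation@tx$biotype[idx],
                                !is.na(cand@cdsTxStart))
        if (!is.na(bio)) return(bio)
        return(.classifyPositional(tp[1], tp[2],
                                   cand@cdsTxStart, cand@cdsTxEnd))
    }
    "novel"
}

#' Classify every ORF of a prediction table
#'
#' Fills the `category` column and tabulates per-category counts; counts
#' always sum to the number of rows and are invariant to input order.
#'
#' @param orfs ORF table from [predictOrfs()].
#' @param annotation AnnotationSet or NULL for annotation-free runs.
#' @param transcripts transcript models matching `annotation`.
#' @return list with `orfs` (table with categories filled) and `summary`
#'   (named integer vector over [orfCategories()]).
#' @export
classifyOrfs <- function(orfs, annotation = NULL, transcripts = NULL) {
    labs <- orfCategories()
    if (nrow(orfs)) {
        orfs$category <- vapply(seq_len(nrow(orfs)), function(i)
            classifyOrf(orfs[i, ], annotation, transcripts), character(1))
    }
    summary <- setNames(integer(length(labs)), labs)
    if (nrow(orfs)) {
        tb <- table(factor(orfs$category, levels = labs))
        summary[names(tb)] <- as.integer(tb)
    }
    list(orfs = orfs, summary = summary)
}
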