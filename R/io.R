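#' Read a genome FASTA
#'
#' Loads all records, uppercases residues, and checks that sequence names
#' are unique. Plain or gzip-compressed FASTA is accepted.
#'
#' @param path FASTA path.
#' @return a [Biostrings::DNAStringSet] (names = sequence ids, residues
#'   uppercase).
#' @export
readGenome <- function(path) {
    if (file.size(path) == 0) stop("empty FASTA file (line 1)")
    gs <- Biostrings::readDNAStringSet(path)
    if (!length(gs)) stop("no FASTA records found (line 1)")
    names(gs) <- sub("\\s.*$", "", names(gs))
    if (anyDuplicated(names(gs)))
        stop(sprintf("duplicate FASTA header '%s'",
                     names(gs)[duplicated(names(gs))][1]))
    if (any(Biostrings::width(gs) == 0)) stop("empty FASTA record")
    # uppercase: DNAStringSet normalises case on read
    gs
}

#' Write a genome FASTA
#' @param genome DNAStringSet.
#' @param path output path.
#' @param width line wrap width.
#' @export
writeGenome <- function(genome, path, width = 70L) {
    Biostrings::writeXStringSet(genome, path, width = width)
    invisible(path)
}

.biotypeOf <- function(mc) {
    for (col in c("transcript_biotype", "gene_biotype", "biotype")) {
        if (!is.null(mc[[col]]) && !is.na(mc[[col]][1]))
            return(as.character(mc[[col]][1]))
    }
    "protein_coding"
}

#' Read a GTF annotation
#'
#' Parses exon and CDS features into a transcript-centred hierarchy.
#' GTF coordinates (1-based, closed) are kept as-is internally (the
#' GRanges convention). A transcript whose CDS falls outside its exon
#' union is flagged unusable with a warning, not dropped.
#'
#' @param path GTF path (.gz allowed).
#' @return an [AnnotationSet-class].
#' @export
readAnnotation <- function(path) {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type %in% c("exon", "CDS")]
    if (!length(gr)) stop("no exon/CDS features in GTF")
    if (is.null(gr$transcript_id) || anyNA(gr$transcript_id[gr$type == "exon"]))
        stop("exon feature without transcript_id")
    txids <- unique(gr$transcript_id)
    exl <- list(); cdl <- list(); rows <- vector("list", length(txids))
    for (i in seq_along(txids)) {
        tid <- txids[i]
        sub <- gr[gr$transcript_id == tid]
        ex <- sort(sub[sub$type == "exon"])
        cd <- sort(sub[sub$type == "CDS"])
        if (!length(ex)) stop(sprintf("transcript '%s' has no exons", tid))
        seqid <- as.character(GenomicRanges::seqnames(ex))[1]
        strand <- as.character(GenomicRanges::strand(ex))[1]
        if (length(unique(as.character(GenomicRanges::seqnames(ex)))) > 1 ||
            length(unique(as.character(GenomicRanges::strand(ex)))) > 1)
            stop(sprintf("transcript '%s' spans sequences or strands", tid))
        if (length(GenomicRanges::reduce(ex)) != length(ex) &&
            any(GenomicRanges::countOverlaps(ex, ex) > 1))
            stop(sprintf("transcript '%s' has overlapping exons", tid))
        usable <- TRUE
        if (length(cd)) {
            inside <- S4Vectors::queryHits(GenomicRanges::findOverlaps(
                cd, ex, type = "within"))
            if (length(unique(inside)) != length(cd)) {
                warning(sprintf(
                    "transcript '%s': CDS outside exon union; flagged unusable",
                    tid))
                usable <- FALSE
            }
        }
        exl[[i]] <- ex
        cdl[[i]] <- cd
        gid <- if (!is.null(sub$gene_id)) as.character(sub$gene_id[1]) else tid
        rows[[i]] <- data.frame(
            transcript_id = tid, gene_id = gid, seqid = seqid,
            strand = strand, biotype = .biotypeOf(S4Vectors::mcols(sub)),
            usable = usable, stringsAsFactors = FALSE)
    }
    new("AnnotationSet",
        exons = GenomicRanges::GRangesList(exl),
        cds = GenomicRanges::GRangesList(cdl),
        tx = do.call(rbind, rows))
}

#' Write an AnnotationSet as GTF
#'
#' Emits exon and CDS features with gene_id/transcript_id/transcript_biotype
#' attributes; coordinates are the 1-based closed GTF convention.
#' @param annotation AnnotationSet.
#' @param path output path.
#' @export
writeAnnotationGtf <- function(annotation, path) {
    con <- file(path, "wt")
    on.exit(close(con))
    for (i in seq_len(nrow(annotation@tx))) {
        info <- annotation@tx[i, ]
        attrs <- sprintf(
            'gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
            info$gene_id, info$transcript_id, info$biotype)
        emit <- function(gr, type) {
            if (!length(gr)) return()
            writeLines(sprintf("%s\tORFpi\t%s\t%d\t%d\t.\t%s\t.\t%s",
                               info$seqid, type,
                               GenomicRanges::start(gr),
                               GenomicRanges::end(gr),
                               info$strand, attrs), con)
        }
        emit(annotation@exons[[i]], "exon")
        emit(annotation@cds[[i]], "CDS")
    }
    invisible(path)
}

setMethod("show", "AnnotationSet", function(object) {
    cat(sprintf("AnnotationSet: %d transcripts, %d genes\n",
                nrow(object@tx), length(unique(object@tx$gene_id))))
})

#' Transcript table of an annotation
#' @param annotation AnnotationSet.
#' @return data.frame of per-transcript metadata.
#' @export
transcriptInfo <- function(annotation) annotation@tx

orfTableColumns <- function() {
    c("orf_id", "transcript_id", "gene_id", "seqid", "strand", "blocks",
      "tx_start", "tx_end", "start_codon", "length_nt",
      "p_div_f0", "p_div_f1", "p_use_f1", "p_use_f2", "p_combined",
      "category", "nuc_seq", "prot_seq")
}

emptyOrfTable <- function() {
    cols <- orfTableColumns()
    out <- data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(out) <- cols
    chr <- c("orf_id", "transcript_id", "gene_id", "seqid", "strand",
             "blocks", "start_codon", "category", "nuc_seq", "prot_seq")
    for (cc in cols)
        out[[cc]] <- if (cc %in% chr) character(0)
                     else if (cc %in% c("tx_start", "tx_end", "length_nt"))
                         integer(0) else numeric(0)
    out
}

#' Write a predicted-ORF table
#'
#' @param rows data.frame in the package's ORF-table schema (see
#'   [predictOrfs()]).
#' @param path output path.
#' @param format one of "tsv" (full schema, round-trips through
#'   [readOrfTable()]), "bed12" (spliced blocks, 0-based half-open) or
#'   "gff3" (multi-line CDS features, 1-based closed, with phase).
#' @export
writeOrfTable <- function(rows, path, format = c("tsv", "bed12", "gff3")) {
    format <- match.arg(format)
    cols <- orfTableColumns()
    if (nrow(rows)) rows <- rows[cols] else rows <- emptyOrfTable()
    if (format == "tsv") {
        data.table::fwrite(rows, path, sep = "\t", na = "NA", quote = FALSE)
    } else if (format == "bed12") {
        con <- file(path, "wt"); on.exit(close(con))
        for (i in seq_len(nrow(rows))) {
            b <- parseBlocks(rows$blocks[i])
            cs <- min(b[, "start"]) - 1L   # BED is 0-based half-open
            ce <- max(b[, "end"])
            sizes <- b[, "end"] - b[, "start"] + 1L
            starts <- b[, "start"] - 1L - cs
            writeLines(sprintf(
                "%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
                rows$seqid[i], cs, ce, rows$orf_id[i], rows$strand[i],
                cs, ce, nrow(b),
                paste0(paste(sizes, collapse = ","), ","),
                paste0(paste(starts, collapse = ","), ",")), con)
        }
    } else {
        con <- file(path, "wt"); on.exit(close(con))
        writeLines("##gff-version 3", con)
        for (i in seq_len(nrow(rows))) {
            b <- parseBlocks(rows$blocks[i])
            # phase: coding order is ascending blocks on +, descending on -
            ord <- if (rows$strand[i] == "+") order(b[, "start"])
                   else order(-b[, "start"])
            b <- b[ord, , drop = FALSE]
            lens <- b[, "end"] - b[, "start"] + 1L
            before <- c(0L, cumsum(lens)[-length(lens)])
            phase <- (3L - before %% 3L) %% 3L
            writeLines(sprintf(
                "%s\tORFpi\tCDS\t%d\t%d\t%s\t%s\t%d\tID=%s;category=%s",
                rows$seqid[i], b[, "start"], b[, "end"],
                format(rows$p_combined[i], digits = 4), rows$strand[i],
                phase, rows$orf_id[i], rows$category[i]), con)
        }
    }
    invisible(path)
}

#' Read a predicted-ORF TSV written by [writeOrfTable()]
#' @param path TSV path.
#' @return data.frame in the ORF-table schema.
#' @export
readOrfTable <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            na.strings = "NA", colClasses = list(
                                character = c("seqid", "blocks", "strand")))
    out <- as.data.frame(dt)
    if (!nrow(out)) return(emptyOrfTable())
    for (cc in c("tx_start", "tx_end", "length_nt"))
        out[[cc]] <- as.integer(out[[cc]])
    out[orfTableColumns()]
}
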