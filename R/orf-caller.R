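#' Construct a caller configuration
#'
#' Defaults: ATG starts only (near-cognates CTG/GTG/TTG can be added),
#' reported ORFs >= 60 nt, codon-usage training on ORFs >= 300 nt, alpha
#' 0.05, Fisher p-value combination, 5'-most start per stop, at least 2
#' segregating sites per candidate.
#'
#' @param startCodons character vector of allowed start triplets.
#' @param minLength minimum reported ORF length (nt, stop included).
#' @param trainMinLength minimum ORF length for the training pass.
#' @param alpha significance threshold on the combined p-value.
#' @param combineMethod "fisher" or "stouffer".
#' @param startPolicy "5prime" or "all".
#' @param minInformative minimum sites with pi > 0 for testability.
#' @param usagePerNucleotide repeat each usage value per nucleotide.
#' @param maxNFraction skip candidates with more N than this fraction.
#' @param adjustMethod "none" or "BH".
#' @return a [CallerConfig-class].
#' @export
callerConfig <- function(startCodons = "ATG", minLength = 60L,
                         trainMinLength = 300L, alpha = 0.05,
                         combineMethod = "fisher", startPolicy = "5prime",
                         minInformative = 2L, usagePerNucleotide = FALSE,
                         maxNFraction = 0.1, adjustMethod = "none") {
    new("CallerConfig", startCodons = toupper(startCodons),
        minLength = as.integer(minLength),
        trainMinLength = as.integer(trainMinLength), alpha = alpha,
        combineMethod = combineMethod, startPolicy = startPolicy,
        minInformative = as.integer(minInformative),
        usagePerNucleotide = usagePerNucleotide,
        maxNFraction = maxNFraction, adjustMethod = adjustMethod)
}

#' Enumerate candidate ORFs on a transcript sequence
#'
#' A candidate starts with an allowed start codon, ends with the first
#' in-frame stop codon (TAA/TAG/TGA, included in the interval), has length
#' a multiple of 3 and at least `minLength`. Under the default "5prime"
#' policy at most one candidate per (stop, frame) is returned, anchored at
#' the 5'-most qualifying start; "all" enumerates nested starts.
#' Candidates with more than `maxNFraction` N are dropped.
#'
#' @param sequence character scalar over A/C/G/T/N.
#' @param config CallerConfig (`minLength` may be overridden).
#' @param minLength optional override of config@minLength.
#' @param startCodons optional override of config@startCodons.
#' @return data.frame with columns start, end (1-based, inclusive, stop
#'   codon included) and start_codon.
#' @export
scanCandidates <- function(sequence, config = callerConfig(),
                           minLength = config@minLength,
                           startCodons = config@startCodons) {
    sequence <- toupper(sequence)
    L <- nchar(sequence)
    stops <- stopCodons()
    res <- list()
    for (f in 0:2) {
        ncod <- (L - f) %/% 3L
        if (ncod < 2) next
        cstart <- f + 1L + 3L * (0:(ncod - 1L))
        cod <- substring(sequence, cstart, cstart + 2L)
        isStop <- cod %in% stops
        isStart <- cod %in% startCodons
        if (!any(isStop) || !any(isStart)) next
        seg <- cumsum(c(FALSE, isStop[-ncod]))  # segment id per codon
        for (si in which(isStop)) {
            inSeg <- which(isStart & seg == seg[si])
            inSeg <- inSeg[inSeg < si]
            if (!length(inSeg)) next
            if (config@startPolicy == "5prime") inSeg <- inSeg[1]
            for (st in inSeg) {
                s <- cstart[st]; e <- cstart[si] + 2L
                if (e - s + 1L < minLength) next
                sub <- substr(sequence, s, e)
                nN <- nchar(gsub("[^N]", "", sub))
                if (nN / (e - s + 1L) > config@maxNFraction) next
                res[[length(res) + 1L]] <-
                    data.frame(start = s, end = e, start_codon = cod[st],
                               stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(res))
        return(data.frame(start = integer(0), end = integer(0),
                          start_codon = character(0)))
    out <- do.call(rbind, res)
    out[order(out$start, out$end), , drop = FALSE]
}

#' Split a per-nucleotide vector into the three codon frames
#'
#' Frame f holds the values at positions p in [start, end] with
#' (p - start) mod 3 = f; frame 2 are the wobble (third codon) positions.
#'
#' @param values numeric per-nucleotide vector.
#' @param start,end 1-based inclusive interval, length a multiple of 3.
#' @return list with f0, f1, f2 (each of length (end-start+1)/3).
#' @export
splitFrames <- function(values, start, end) {
    len <- end - start + 1L
    if (len %% 3L != 0L) stop("interval length must be a multiple of 3")
    v <- values[start:end]
    list(f0 = v[seq(1L, len, 3L)], f1 = v[seq(2L, len, 3L)],
         f2 = v[seq(3L, len, 3L)])
}

#' One-sided pooled-variance Student's t-test
#'
#' Tests H1: mean(b) > mean(a) with the classical pooled-variance two
#' sample t statistic at |a|+|b|-2 degrees of freedom. When both samples
#' have zero variance the test degenerates and the p-value is defined by
#' the mean ordering: 0 if mean(b) > mean(a), 1 if smaller, 0.5 if equal.
#'
#' @param a,b numeric vectors of length >= 2.
#' @return p-value in [0, 1].
#' @export
oneSidedT <- function(a, b) {
    if (length(a) < 2 || length(b) < 2)
        stop("both samples need at least two values")
    va <- stats::var(a); vb <- stats::var(b)
    if (va == 0 && vb == 0) {
        d <- mean(b) - mean(a)
        return(if (d > 0) 0 else if (d < 0) 1 else 0.5)
    }
    res <- tryCatch(
        t.test(b, a, alternative = "greater", var.equal = TRUE)$p.value,
        error = function(e) {
            # near-constant data: fall back to the explicit formula
            na <- length(a); nb <- length(b)
            sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
            tt <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
            pt(tt, na + nb - 2, lower.tail = FALSE)
        })
    res
}

#' Combine p-values
#'
#' Fisher's method (default): X = -2 sum log p is referred to a chi-square
#' with 2m degrees of freedom. Stouffer's method converts each p to a
#' z-score and refers the scaled sum to the standard normal. Zeros are
#' clamped to the smallest positive double before taking logs.
#'
#' @param ps numeric vector of p-values in [0, 1].
#' @param method "fisher" or "stouffer".
#' @return combined p-value.
#' @export
combinePvalues <- function(ps, method = c("fisher", "stouffer")) {
    method <- match.arg(method)
    if (!length(ps)) stop("no p-values to combine")
    if (any(ps < 0 | ps > 1)) stop("p-values must lie in [0,1]")
    ps <- pmax(ps, .Machine$double.xmin)
    if (method == "fisher") {
        pchisq(-2 * sum(log(ps)), df = 2 * length(ps), lower.tail = FALSE)
    } else {
        ps <- pmin(ps, 1 - 1e-16)
        z <- qnorm(ps, lower.tail = FALSE)
        pnorm(sum(z) / sqrt(length(ps)), lower.tail = FALSE)
    }
}

#' Frame-wise diversity tests for one candidate
#'
#' Tests whether per-site diversity at frame-2 (wobble) positions exceeds
#' frame 0 and frame 1, by two one-sided pooled t-tests. All positions are
#' included: sites absent from the track contribute pi = 0. A candidate
#' with fewer than `minInformative` sites of pi > 0 is untestable and
#' returns NULL.
#'
#' @param divValues per-nucleotide diversity vector of the transcript.
#' @param start,end candidate interval (1-based inclusive, multiple of 3).
#' @param config CallerConfig.
#' @return list(p_div_f0, p_div_f1) or NULL when untestable.
#' @export
diversityFrameTest <- function(divValues, start, end,
                               config = callerConfig()) {
    if (end - start + 1L < 6L) stop("candidate must span at least 2 codons")
    sl <- divValues[start:end]
    if (sum(sl > 0) < config@minInformative) return(NULL)
    fr <- splitFrames(divValues, start, end)
    list(p_div_f0 = oneSidedT(fr$f0, fr$f2),
         p_div_f1 = oneSidedT(fr$f1, fr$f2))
}

#' Per-triplet codon-usage values of a reading
#'
#' Assigns to each complete triplet of the reading shifted by `frameShift`
#' from the candidate start its trained usage frequency. Triplets
#' containing N (or any unknown triplet) score 0; stop codons score 0 by
#' construction of the table. The trailing incomplete triplet of shifted
#' readings is dropped.
#'
#' @param sequence transcript sequence.
#' @param start,end candidate interval.
#' @param frameShift 0, 1 or 2.
#' @param table CodonUsageTable.
#' @return numeric vector of length floor((end-start+1-frameShift)/3).
#' @export
usageValues <- function(sequence, start, end, frameShift, table) {
    if ((end - start + 1L) %% 3L != 0L)
        stop("interval length must be a multiple of 3")
    s <- start + frameShift
    m <- (end - s + 1L) %/% 3L
    if (m < 1) return(numeric(0))
    cs <- s + 3L * (0:(m - 1L))
    cods <- substring(sequence, cs, cs + 2L)
    v <- table@freq[cods]
    v[is.na(v)] <- 0
    unname(v)
}

#' Frame-wise codon-usage tests for one candidate
#'
#' Tests whether usage values in the candidate's own reading (frame 0)
#' exceed those of the +1 and +2 shifted readings, by two one-sided
#' pooled t-tests.
#'
#' @param sequence transcript sequence.
#' @param start,end candidate interval.
#' @param table CodonUsageTable.
#' @param config CallerConfig (`usagePerNucleotide` honoured).
#' @return list(p_use_f1, p_use_f2).
#' @export
usageFrameTest <- function(sequence, start, end, table,
                           config = callerConfig()) {
    b <- usageValues(sequence, start, end, 0L, table)
    a1 <- usageValues(sequence, start, end, 1L, table)
    a2 <- usageValues(sequence, start, end, 2L, table)
    if (config@usagePerNucleotide) {
        b <- rep(b, each = 3L); a1 <- rep(a1, each = 3L)
        a2 <- rep(a2, each = 3L)
    }
    list(p_use_f1 = oneSidedT(a1, b), p_use_f2 = oneSidedT(a2, b))
}

#' Build a CodonUsageTable from codon counts
#' @param counts named numeric vector of sense-codon counts.
#' @param nOrfs number of ORFs the counts came from.
#' @return a [CodonUsageTable-class].
#' @export
codonUsageFromCounts <- function(counts, nOrfs = NA_integer_) {
    freq <- setNames(numeric(64), allCodons())
    counts <- counts[names(counts) %in% senseCodons()]
    if (!sum(counts)) stop("no sense-codon counts")
    freq[names(counts)] <- counts / sum(counts)
    new("CodonUsageTable", freq = freq, nOrfs = as.integer(nOrfs),
        nCodons = as.integer(sum(counts)))
}

#' Uniform codon usage over the 61 sense codons
#' @return a [CodonUsageTable-class] with every sense codon at 1/61.
#' @export
uniformCodonUsage <- function() {
    codonUsageFromCounts(setNames(rep(1, 61), senseCodons()))
}

#' Codon usage frequencies
#' @param table CodonUsageTable.
#' @return named numeric of length 64.
#' @export
codonFrequencies <- function(table) table@freq

setMethod("show", "CodonUsageTable", function(object) {
    cat(sprintf("CodonUsageTable: trained on %s ORFs (%s codons); top: %s\n",
                object@nOrfs, object@nCodons,
                paste(names(sort(object@freq, decreasing = TRUE))[1:3],
                      collapse = ", ")))
})

# internal: codons of an interval of a transcript sequence
.codonsOf <- function(sequence, start, end) {
    cs <- seq(start, end - 2L, by = 3L)
    substring(sequence, cs, cs + 2L)
}

#' Train genome-wide codon usage from a stringent preliminary pass
#'
#' The preliminary pass predicts ORFs from the two diversity t-tests only
#' (Fisher-combined), restricted to ATG starts and candidates of at least
#' `trainMinLength` nt (default 300). Codons of the accepted ORFs
#' (deduplicated by genomic identity; stop codons excluded) are pooled and
#' normalised to frequencies.
#'
#' @param transcripts list of TranscriptModel.
#' @param track DiversityTrack.
#' @param config CallerConfig.
#' @return a [CodonUsageTable-class].
#' @export
trainCodonUsage <- function(transcripts, track, config = callerConfig()) {
    counts <- setNames(numeric(61), senseCodons())
    seen <- character(0)
    nOrfs <- 0L
    for (tx in transcripts) {
        cands <- scanCandidates(tx@sequence, config,
                                minLength = config@trainMinLength,
                                startCodons = "ATG")
        if (!nrow(cands)) next
        dv <- projectDiversity(tx, track)
        for (i in seq_len(nrow(cands))) {
            s <- cands$start[i]; e <- cands$end[i]
            dt <- diversityFrameTest(dv, s, e, config)
            if (is.null(dt)) next
            pc <- combinePvalues(c(dt$p_div_f0, dt$p_div_f1),
                                 config@combineMethod)
            if (pc >= config@alpha) next
            key <- paste(tx@seqid, tx@strand,
                         formatBlocks(tx@gpos[s:e]), sep = "|")
            if (key %in% seen) next
            seen <- c(seen, key)
            nOrfs <- nOrfs + 1L
            cods <- .codonsOf(tx@sequence, s, e - 3L)  # drop terminal stop
            cods <- cods[cods %in% names(counts)]      # drops stops and Ns
            tb <- table(cods)
            counts[names(tb)] <- counts[names(tb)] + as.numeric(tb)
        }
    }
    if (nOrfs == 0L)
        stop(structure(class = c("orfpiTrainingError", "error", "condition"),
                       list(message = paste(
                           "no preliminary ORFs passed the training filter;",
                           "supply more data or relax alpha"),
                           call = sys.call())))
    codonUsageFromCounts(counts, nOrfs)
}

# internal: test every candidate of one transcript; returns rows with
# unadjusted combined p (filtering happens in predictOrfs)
.testTranscript <- function(tx, track, table, config) {
    cands <- scanCandidates(tx@sequence, config)
    if (!nrow(cands)) return(NULL)
    dv <- projectDiversity(tx, track)
    rows <- list()
    for (i in seq_len(nrow(cands))) {
        s <- cands$start[i]; e <- cands$end[i]
        dt <- diversityFrameTest(dv, s, e, config)
        if (is.null(dt)) next
        ut <- usageFrameTest(tx@sequence, s, e, table, config)
        ps <- c(dt$p_div_f0, dt$p_div_f1, ut$p_use_f1, ut$p_use_f2)
        pc <- combinePvalues(ps, config@combineMethod)
        nuc <- substr(tx@sequence, s, e)
        prot <- suppressWarnings(as.character(Biostrings::translate(
            Biostrings::DNAString(chartr("N", "A", nuc)),
            if.fuzzy.codon = "X")))
        rows[[length(rows) + 1L]] <- data.frame(
            orf_id = sprintf("%s:%d-%d", tx@transcriptId, s, e),
            transcript_id = tx@transcriptId, gene_id = tx@geneId,
            seqid = tx@seqid, strand = tx@strand,
            blocks = formatBlocks(tx@gpos[s:e]),
            tx_start = s, tx_end = e,
            start_codon = cands$start_codon[i],
            length_nt = e - s + 1L,
            p_div_f0 = dt$p_div_f0, p_div_f1 = dt$p_div_f1,
            p_use_f1 = ut$p_use_f1, p_use_f2 = ut$p_use_f2,
            p_combined = pc, category = NA_character_,
            nuc_seq = nuc, prot_seq = prot, stringsAsFactors = FALSE)
    }
    if (!length(rows)) return(NULL)
    do.call(rbind, rows)
}

#' Predict ORFs from projected diversity and trained codon usage
#'
#' For every candidate on every transcript, computes the four one-sided
#' t-tests (diversity frame2 > frame0, frame2 > frame1; usage frame0 >
#' frame1, frame0 > frame2), combines them (Fisher by default) and reports
#' candidates with combined p below alpha. Identical ORFs reached via
#' different transcript isoforms (same seqid, strand, genomic blocks) are
#' collapsed to one row. Output order is deterministic: seqid, genomic
#' start, genomic end, strand.
#'
#' @param transcripts list of TranscriptModel.
#' @param track DiversityTrack.
#' @param table CodonUsageTable from [trainCodonUsage()].
#' @param config CallerConfig.
#' @param nCores workers for the per-transcript loop; results are
#'   independent of the worker count.
#' @return data.frame in the ORF-table schema (possibly 0 rows).
#' @export
predictOrfs <- function(transcripts, track, table, config = callerConfig(),
                        nCores = 1L) {
    fun <- function(tx) .testTranscript(tx, track, table, config)
    parts <- if (nCores > 1L)
        parallel::mclapply(transcripts, fun, mc.cores = nCores)
    else lapply(transcripts, fun)
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (!length(parts)) return(emptyOrfTable())
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    if (config@adjustMethod == "BH")
        out$p_combined <- p.adjust(out$p_combined, method = "BH")
    out <- out[out$p_combined < config@alpha, , drop = FALSE]
    if (!nrow(out)) return(emptyOrfTable())
    key <- paste(out$seqid, out$strand, out$blocks, sep = "|")
    out <- out[!duplicated(key), , drop = FALSE]
    gstart <- vapply(out$blocks, function(b) min(parseBlocks(b)[, "start"]),
                     integer(1))
    gend <- vapply(out$blocks, function(b) max(parseBlocks(b)[, "end"]),
                   integer(1))
    out <- out[order(out$seqid, gstart, gend, out$strand), , drop = FALSE]
    rownames(out) <- NULL
    out
}
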