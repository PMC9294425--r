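#' Construct a DiversityTrack from a site table
#'
#' @param sites data.frame with columns `seqid`, `pos` (1-based genomic
#'   position) and `pi` (non-negative). Zero-pi rows may be included or
#'   omitted; by the absent-site rule the two are equivalent.
#' @return a [DiversityTrack-class] object.
#' @examples
#' trk <- diversityTrack(data.frame(seqid = "chr1", pos = 5, pi = 0.25))
#' piAt(trk, "chr1", c(5, 100))
#' @export
diversityTrack <- function(sites = data.frame(seqid = character(),
                                              pos = integer(),
                                              pi = numeric())) {
    stopifnot(all(c("seqid", "pos", "pi") %in% names(sites)))
    if (nrow(sites) && any(!is.finite(sites$pi)))
        stop("non-numeric pi value")
    if (nrow(sites) && any(sites$pi < 0))
        stop("negative pi value")
    if (anyDuplicated(sites[c("seqid", "pos")]))
        stop("duplicated (seqid, pos) entries")
    data <- lapply(split(sites[c("pos", "pi")], sites$seqid), function(d) {
        o <- order(d$pos)
        list(pos = as.integer(d$pos[o]), pi = as.numeric(d$pi[o]))
    })
    new("DiversityTrack", data = data)
}

#' Look up per-site diversity
#'
#' Total function: any (seqid, pos) query returns a non-negative number;
#' sites absent from the track are invariant and return 0.
#'
#' @param track a DiversityTrack.
#' @param seqid sequence name (scalar).
#' @param pos integer vector of 1-based positions.
#' @return numeric vector of pi values, same length as `pos`.
#' @export
piAt <- function(track, seqid, pos) {
    d <- track@data[[seqid]]
    if (is.null(d)) return(numeric(length(pos)))
    idx <- match(as.integer(pos), d$pos)
    out <- d$pi[idx]
    out[is.na(idx)] <- 0
    out
}

#' Number of segregating sites stored in a track
#' @param track a DiversityTrack.
#' @return integer count of stored sites (pi > 0 entries plus any stored
#'   zeros).
#' @export
trackSize <- function(track) {
    sum(vapply(track@data, function(d) length(d$pos), integer(1)))
}

#' All stored sites of a track as a data.frame
#' @param track a DiversityTrack.
#' @return data.frame with seqid, pos, pi.
#' @export
trackSites <- function(track) {
    if (!length(track@data))
        return(data.frame(seqid = character(), pos = integer(),
                          pi = numeric()))
    do.call(rbind, lapply(names(track@data), function(nm) {
        d <- track@data[[nm]]
        data.frame(seqid = rep(nm, length(d$pos)), pos = d$pos, pi = d$pi)
    }))
}

setMethod("show", "DiversityTrack", function(object) {
    cat(sprintf("DiversityTrack: %d sites on %d sequence(s)\n",
                trackSize(object), length(object@data)))
})

#' Read a per-site diversity table
#'
#' Reads the tab-delimited dialect written by `vcftools --site-pi`: a
#' header line `CHROM POS PI` followed by one row per site, POS 1-based.
#' Gzip input is handled transparently.
#'
#' @param path path to the table (.gz allowed).
#' @return a [DiversityTrack-class].
#' @export
readSitePi <- function(path) {
    if (grepl("\\.gz$", path)) {
        con <- gzfile(path, "rt")
        txt <- paste(readLines(con), collapse = "\n")
        close(con)
        dt <- data.table::fread(text = txt, sep = "\t", header = TRUE,
                                colClasses = list(character = 1))
    } else {
        dt <- data.table::fread(path, sep = "\t", header = TRUE,
                                colClasses = list(character = 1))
    }
    need <- c("CHROM", "POS", "PI")
    if (!all(need %in% names(dt)))
        stop("site-pi table must have header CHROM, POS, PI")
    pi <- suppressWarnings(as.numeric(dt$PI))
    bad <- which(!is.finite(pi))
    if (length(bad))
        stop(sprintf("non-numeric PI at line %d", bad[1] + 1L))
    neg <- which(pi < 0)
    if (length(neg))
        stop(sprintf("negative PI at line %d", neg[1] + 1L))
    dup <- which(duplicated(paste(dt$CHROM, dt$POS)))
    if (length(dup))
        stop(sprintf("duplicate CHROM/POS at line %d", dup[1] + 1L))
    diversityTrack(data.frame(seqid = dt$CHROM, pos = as.integer(dt$POS),
                              pi = pi))
}

#' Write a per-site diversity table
#'
#' Inverse of [readSitePi()]; writes the `CHROM POS PI` dialect.
#' @param track a DiversityTrack.
#' @param path output path.
#' @export
writeSitePi <- function(track, path) {
    s <- trackSites(track)
    names(s) <- c("CHROM", "POS", "PI")
    data.table::fwrite(s, path, sep = "\t")
    invisible(path)
}

#' Per-site nucleotide diversity from allele counts
#'
#' Computes pi = average proportion of pairwise allele differences,
#' `1 - sum_a (n_a/n) ((n_a-1)/(n-1))`, equivalently
#' `sum_{a<b} 2 n_a n_b / (n (n-1))`. Handles any number of alleles.
#'
#' @param counts numeric vector of per-allele counts at one site (n >= 2).
#' @return pi in [0, 1].
#' @examples
#' sitePiFromCounts(c(1, 1))  # one pair, differing: 1
#' sitePiFromCounts(c(2, 2))  # 4 of 6 pairs differ: 2/3
#' @export
sitePiFromCounts <- function(counts) {
    counts <- counts[counts > 0]
    n <- sum(counts)
    if (n < 2) stop("need at least two sampled alleles")
    1 - sum((counts / n) * ((counts - 1) / (n - 1)))
}

#' Per-site diversity from a simple VCF
#'
#' Optional convenience source for the diversity track: parses the GT field
#' of a multi-sample VCF (v4.x; CHROM/POS/REF/ALT/GT only are used), counts
#' alleles per site and applies [sitePiFromCounts()]. Sites with fewer than
#' two called alleles are skipped with a warning. Monomorphic sites give
#' pi = 0 and are stored.
#'
#' @param path VCF path (.gz allowed).
#' @return a [DiversityTrack-class].
#' @export
readVcfPi <- function(path) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    chrom <- vcfR::getCHROM(v)
    pos <- vcfR::getPOS(v)
    pis <- numeric(0); keep <- integer(0)
    nskip <- 0L
    for (i in seq_len(nrow(gt))) {
        al <- unlist(strsplit(gt[i, ], "[/|]"))
        al <- al[!is.na(al) & al != "."]
        if (length(al) < 2) { nskip <- nskip + 1L; next }
        pis <- c(pis, sitePiFromCounts(table(al)))
        keep <- c(keep, i)
    }
    if (nskip > 0)
        warning(sprintf("%d site(s) skipped: fewer than two called alleles",
                        nskip))
    diversityTrack(data.frame(seqid = chrom[keep], pos = pos[keep], pi = pis))
}
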