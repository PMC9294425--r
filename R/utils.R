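# internal helpers

#' Format sorted genomic positions as a block string
#'
#' Consecutive runs of positions become `start-end` blocks (1-based,
#' inclusive), joined by `;`. This string is the genomic identity of a
#' spliced ORF.
#' @param pos integer vector of genomic positions (any order).
#' @return character scalar like `"101-160;221-280"`.
#' @export
formatBlocks <- function(pos) {
    pos <- sort(unique(as.integer(pos)))
    if (!length(pos)) return("")
    brk <- c(0L, which(diff(pos) != 1L), length(pos))
    paste(vapply(seq_len(length(brk) - 1L), function(i) {
        s <- pos[brk[i] + 1L]; e <- pos[brk[i + 1L]]
        paste0(s, "-", e)
    }, character(1)), collapse = ";")
}

#' Parse a block string back to a two-column matrix
#' @param x block string from [formatBlocks()].
#' @return integer matrix with columns start, end.
#' @export
parseBlocks <- function(x) {
    if (!nzchar(x)) return(matrix(integer(0), ncol = 2,
                                  dimnames = list(NULL, c("start", "end"))))
    parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
    m <- t(vapply(parts, function(p) as.integer(p), integer(2)))
    colnames(m) <- c("start", "end")
    m
}

blockLengthSum <- function(x) {
    m <- parseBlocks(x)
    if (!nrow(m)) return(0L)
    sum(m[, "end"] - m[, "start"] + 1L)
}

# half-away-from-zero rounding to `digits` decimals (base round() is
# round-half-even, which does not match printed-percentage conventions)
roundHalfUp <- function(x, digits = 2) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

revComp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

stopCodons <- function() c("TAA", "TAG", "TGA")

senseCodons <- function() {
    gc <- Biostrings::GENETIC_CODE
    names(gc)[gc != "*"]
}

allCodons <- function() names(Biostrings::GENETIC_CODE)

# gzip-aware connection for text readers
openMaybeGz <- function(path) {
    if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}
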