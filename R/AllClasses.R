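#' @import methods
#' @importFrom stats pchisq pf pnorm pt qnorm rexp rgamma runif t.test sd
#'   p.adjust setNames var fft
NULL

#' DiversityTrack: sparse per-site nucleotide diversity
#'
#' Maps genomic sites (1-based) to per-site nucleotide diversity (pi).
#' Sites absent from the track are treated as invariant (pi = 0), matching
#' the convention of `vcftools --site-pi` output, which lists only sites
#' present in the VCF.
#'
#' @slot data named list, one element per sequence; each element is a list
#'   with integer vector `pos` (sorted, unique, 1-based) and numeric vector
#'   `pi` (non-negative, same length).
#' @exportClass DiversityTrack
setClass("DiversityTrack", representation(data = "list"))

setValidity("DiversityTrack", function(object) {
    for (nm in names(object@data)) {
        d <- object@data[[nm]]
        if (!is.list(d) || !all(c("pos", "pi") %in% names(d)))
            return(sprintf("element '%s' must have 'pos' and 'pi'", nm))
        if (length(d$pos) != length(d$pi))
            return(sprintf("element '%s': pos/pi length mismatch", nm))
        if (anyDuplicated(d$pos))
            return(sprintf("element '%s': duplicated positions", nm))
        if (length(d$pi) && any(d$pi < 0))
            return(sprintf("element '%s': negative pi", nm))
        if (is.unsorted(d$pos))
            return(sprintf("element '%s': positions must be sorted", nm))
    }
    TRUE
})

#' AnnotationSet: gene/transcript/feature hierarchy from a GTF
#'
#' @slot exons GRangesList of exons, one element per transcript, sorted by
#'   genomic start.
#' @slot cds GRangesList of CDS intervals per transcript (zero-length element
#'   when the transcript is non-coding). CDS intervals written by this
#'   package include the stop codon.
#' @slot tx data.frame with columns transcript_id, gene_id, seqid, strand,
#'   biotype, usable.
#' @exportClass AnnotationSet
setClass("AnnotationSet", representation(
    exons = "ANY", cds = "ANY", tx = "data.frame"))

setValidity("AnnotationSet", function(object) {
    if (!all(c("transcript_id", "gene_id", "seqid", "strand", "biotype",
               "usable") %in% names(object@tx)))
        return("tx table lacks required columns")
    if (length(object@exons) != nrow(object@tx))
        return("exons and tx table disagree in length")
    TRUE
})

#' TranscriptModel: a spliced transcript with projected coordinates
#'
#' Carries the spliced sequence (reverse-complemented on the minus strand),
#' the per-position genomic coordinate map, and the CDS interval in
#' transcript coordinates when annotated (stop codon included).
#'
#' @slot transcriptId,geneId,seqid,strand,biotype character scalars.
#' @slot exons IRanges of genomic exon blocks (ascending).
#' @slot sequence character scalar, the spliced sequence.
#' @slot gpos integer vector; `gpos[i]` is the 1-based genomic position
#'   underlying transcript position `i`.
#' @slot cdsTxStart,cdsTxEnd integer, CDS interval in transcript
#'   coordinates (NA when absent).
#' @exportClass TranscriptModel
setClass("TranscriptModel", representation(
    transcriptId = "character", geneId = "character", seqid = "character",
    strand = "character", exons = "ANY", sequence = "character",
    gpos = "integer", cdsTxStart = "integer", cdsTxEnd = "integer",
    biotype = "character"))

setValidity("TranscriptModel", function(object) {
    if (nchar(object@sequence) != length(object@gpos))
        return("sequence length != coordinate map length")
    if (!object@strand %in% c("+", "-"))
        return("strand must be + or -")
    if (!is.na(object@cdsTxStart)) {
        if (object@cdsTxStart < 1L || object@cdsTxEnd > length(object@gpos))
            return("CDS interval outside transcript")
    }
    TRUE
})

#' CodonUsageTable: genome-wide codon usage frequencies
#'
#' @slot freq named numeric of length 64 (all DNA triplets); sense-codon
#'   frequencies sum to 1, stop codons are 0.
#' @slot nOrfs,nCodons integer training metadata.
#' @exportClass CodonUsageTable
setClass("CodonUsageTable", representation(
    freq = "numeric", nOrfs = "integer", nCodons = "integer"))

setValidity("CodonUsageTable", function(object) {
    if (length(object@freq) != 64L) return("freq must have 64 entries")
    if (any(object@freq < 0)) return("negative frequency")
    stops <- c("TAA", "TAG", "TGA")
    if (any(object@freq[stops] != 0)) return("stop codon frequency must be 0")
    s <- sum(object@freq)
    if (abs(s - 1) > 1e-8) return("sense-codon frequencies must sum to 1")
    TRUE
})

#' CallerConfig: tuning parameters of the ORF caller
#'
#' @slot startCodons character; default "ATG"; near-cognates CTG/GTG/TTG
#'   may be added.
#' @slot minLength minimum reported ORF length in nt including the stop
#'   codon (default 60).
#' @slot trainMinLength minimum length for the codon-usage training pass
#'   (default 300).
#' @slot alpha significance threshold on the combined p-value.
#' @slot combineMethod "fisher" or "stouffer".
#' @slot startPolicy "5prime" (one candidate per stop and frame, the
#'   5'-most qualifying start) or "all" (nested starts enumerated).
#' @slot minInformative minimum number of sites with pi > 0 for a candidate
#'   to be testable.
#' @slot usagePerNucleotide logical; if TRUE each usage value is repeated
#'   once per nucleotide of its triplet (tripling the t-test sample size).
#' @slot maxNFraction candidates with more N than this fraction are skipped.
#' @slot adjustMethod "none" (default) or "BH" for Benjamini-Hochberg
#'   adjustment of combined p-values before thresholding.
#' @exportClass CallerConfig
setClass("CallerConfig", representation(
    startCodons = "character", minLength = "integer",
    trainMinLength = "integer", alpha = "numeric", combineMethod = "character",
    startPolicy = "character", minInformative = "integer",
    usagePerNucleotide = "logical", maxNFraction = "numeric",
    adjustMethod = "character"))

setValidity("CallerConfig", function(object) {
    if (object@minLength %% 3L != 0L) return("minLength must be a multiple of 3")
    if (object@trainMinLength %% 3L != 0L)
        return("trainMinLength must be a multiple of 3")
    if (object@alpha <= 0 || object@alpha >= 1) return("alpha must be in (0,1)")
    if (!object@combineMethod %in% c("fisher", "stouffer"))
        return("combineMethod must be fisher or stouffer")
    if (!object@startPolicy %in% c("5prime", "all"))
        return("startPolicy must be 5prime or all")
    if (any(nchar(object@startCodons) != 3L))
        return("start codons must be triplets")
    TRUE
})

#' MetageneProfile: positionwise mean diversity over aligned windows
#'
#' @slot region one of "CDS", "UTR5", "UTR3", "intergenic".
#' @slot profile numeric, mean pi per position.
#' @slot nWindows number of contributing windows.
#' @exportClass MetageneProfile
setClass("MetageneProfile", representation(
    region = "character", profile = "numeric", nWindows = "integer"))

setValidity("MetageneProfile", function(object) {
    if (length(object@profile) && any(object@profile < 0))
        return("profile values must be non-negative")
    TRUE
})

#' PeriodicityResult: multitaper harmonic F-test over a frequency grid
#'
#' @slot frequencies cycles per nucleotide, in (0, 0.5].
#' @slot fstat,pvalues per-frequency harmonic F statistic and p-value.
#' @slot peakFrequency frequency of the maximal F statistic.
#' @slot targetFrequency the frequency of interest (1/3 for 3-nt
#'   periodicity); `pAtTarget` is read at the nearest grid frequency.
#' @slot significant TRUE when pAtTarget < the configured threshold.
#' @slot degenerate TRUE for a constant input series (all p = 1).
#' @exportClass PeriodicityResult
setClass("PeriodicityResult", representation(
    frequencies = "numeric", fstat = "numeric", pvalues = "numeric",
    peakFrequency = "numeric", targetFrequency = "numeric",
    pAtTarget = "numeric", significant = "logical", degenerate = "logical",
    nw = "numeric", k = "integer"))

setValidity("PeriodicityResult", function(object) {
    if (any(object@pvalues < 0 | object@pvalues > 1))
        return("p-values must lie in [0,1]")
    if (length(object@frequencies) &&
        (min(object@frequencies) <= 0 || max(object@frequencies) > 0.5))
        return("frequencies must lie in (0, 0.5]")
    TRUE
})

#' SetComparison: exact-identity comparison of two ORF sets
#'
#' Identity is (seqid, strand, genomic block list); transcript-relative
#' coordinates are never compared.
#'
#' @slot nPred,nRef,nCommon counts.
#' @slot predCommon,refCommon logical membership flags per element.
#' @exportClass SetComparison
setClass("SetComparison", representation(
    nPred = "integer", nRef = "integer", nCommon = "integer",
    predCommon = "logical", refCommon = "logical"))

setValidity("SetComparison", function(object) {
    if (object@nCommon > min(object@nPred, object@nRef))
        return("nCommon exceeds a set size")
    TRUE
})

#' PredictionMetrics: accuracy, recall and F-score
#'
#' accuracy = true positives / predicted; recall = true positives /
#' annotated; F = 2RA/(R+A). Values are raw fractions; see
#' [percentMetrics()] for the rounded percentage form.
#'
#' @slot accuracy,recall,fScore numeric in [0,1], NA when the denominator
#'   is zero.
#' @exportClass PredictionMetrics
setClass("PredictionMetrics", representation(
    accuracy = "numeric", recall = "numeric", fScore = "numeric"))

#' SimulationParams: knobs of the synthetic genome generator
#'
#' Ranges are inclusive integer ranges `c(lo, hi)`. Diversity classes are
#' wobble (third codon positions), nonwobble (first/second), utr (exonic
#' non-CDS) and intergenic (everything else, introns included).
#'
#' @slot nGenes number of protein-coding genes.
#' @slot exonsPerGene,utr5Len,utr3Len,cdsLen,intronLen,spacerLen ranges;
#'   cdsLen endpoints are multiples of 3 (stop codon included).
#' @slot codonFreq optional named frequency vector over sense codons; when
#'   NULL a skew is drawn once from a symmetric Dirichlet with
#'   concentration `codonSkew`.
#' @slot segProb,piMean named per-class segregating-site probabilities and
#'   mean pi given segregating (exponential model).
#' @slot nUorfsPerGene,nDorfsPerGene planted small-ORF controls per gene.
#' @slot sorfLen length range for planted sORFs (multiples of 3).
#' @slot seed integer seed governing all randomness of the generator.
#' @exportClass SimulationParams
setClass("SimulationParams", representation(
    nGenes = "integer", exonsPerGene = "integer", utr5Len = "integer",
    utr3Len = "integer", cdsLen = "integer", intronLen = "integer",
    spacerLen = "integer", codonFreq = "ANY", codonSkew = "numeric",
    segProb = "numeric", piMean = "numeric", nUorfsPerGene = "integer",
    nDorfsPerGene = "integer", sorfLen = "integer", seed = "integer"))

setValidity("SimulationParams", function(object) {
    cls <- c("wobble", "nonwobble", "utr", "intergenic")
    if (!all(cls %in% names(object@segProb))) return("segProb lacks a class")
    if (!all(cls %in% names(object@piMean))) return("piMean lacks a class")
    if (any(object@segProb < 0 | object@segProb > 1))
        return("segProb must lie in [0,1]")
    if (object@segProb["wobble"] < object@segProb["nonwobble"])
        return("wobble segregating probability must be >= nonwobble")
    if (any(object@cdsLen %% 3L != 0L)) return("cdsLen must be multiples of 3")
    if (any(object@sorfLen %% 3L != 0L)) return("sorfLen must be multiples of 3")
    TRUE
})
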