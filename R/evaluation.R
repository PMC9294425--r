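#' Genomic identity key of each ORF row
#'
#' ORF identity for all set comparisons is (seqid, strand, exact genomic
#' block list); transcript-relative coordinates are never compared, so the
#' same ORF reached through different isoforms compares equal.
#'
#' @param orfs ORF table (or any data.frame with seqid, strand, blocks).
#' @return character vector of identity keys.
#' @export
orfIdentity <- function(orfs) {
    paste(orfs$seqid, orfs$strand, orfs$blocks, sep = "|")
}

#' Construct a SetComparison from counts
#'
#' For evaluation arithmetic on externally supplied counts (no membership
#' flags available).
#' @param nCommon,nPred,nRef counts; nCommon <= min(nPred, nRef).
#' @return a [SetComparison-class].
#' @export
setComparison <- function(nCommon, nPred, nRef) {
    new("SetComparison", nPred = as.integer(nPred), nRef = as.integer(nRef),
        nCommon = as.integer(nCommon),
        predCommon = logical(0), refCommon = logical(0))
}

#' Compare a predicted ORF set with a reference set
#'
#' Exact-identity intersection under [orfIdentity()]; order-independent
#' and symmetric in the common count.
#'
#' @param pred,ref ORF tables or character vectors of identity keys.
#' @return a [SetComparison-class] with membership flags.
#' @export
compareSets <- function(pred, ref) {
    pk <- if (is.character(pred)) pred else orfIdentity(pred)
    rk <- if (is.character(ref)) ref else orfIdentity(ref)
    pk <- unique(pk); rk <- unique(rk)
    pc <- pk %in% rk
    rc <- rk %in% pk
    new("SetComparison", nPred = length(pk), nRef = length(rk),
        nCommon = sum(pc), predCommon = pc, refCommon = rc)
}

setMethod("show", "SetComparison", function(object) {
    cat(sprintf("SetComparison: %d predicted, %d reference, %d common\n",
                object@nPred, object@nRef, object@nCommon))
})

#' Accuracy, recall and F-score of a comparison
#'
#' accuracy = common/predicted, recall = common/reference,
#' F = 2RA/(R+A). A zero denominator yields NA (never silently 0); F is 0
#' when both accuracy and recall are 0.
#'
#' @param comparison a [SetComparison-class].
#' @return a [PredictionMetrics-class].
#' @export
predictionMetrics <- function(comparison) {
    acc <- if (comparison@nPred > 0) comparison@nCommon / comparison@nPred
           else NA_real_
    rec <- if (comparison@nRef > 0) comparison@nCommon / comparison@nRef
           else NA_real_
    f <- if (is.na(acc) || is.na(rec)) NA_real_
         else if (acc + rec == 0) 0
         else 2 * rec * acc / (rec + acc)
    new("PredictionMetrics", accuracy = acc, recall = rec, fScore = f)
}

setMethod("show", "PredictionMetrics", function(object) {
    p <- percentMetrics(object)
    cat(sprintf("PredictionMetrics: accuracy %s%%, recall %s%%, F %s%%\n",
                p["accuracy"], p["recall"], p["f_score"]))
})

#' Metrics as printed percentages
#'
#' Rounds half away from zero to two decimals, the convention of printed
#' percentage tables.
#' @param metrics a [PredictionMetrics-class].
#' @return named numeric: accuracy, recall, f_score (percent).
#' @export
percentMetrics <- function(metrics) {
    c(accuracy = roundHalfUp(100 * metrics@accuracy, 2),
      recall = roundHalfUp(100 * metrics@recall, 2),
      f_score = roundHalfUp(100 * metrics@fScore, 2))
}

#' Degree of mass-spectrometry support of an ORF class
#'
#' log10(nSupported / (nTotal * expression)): the fraction of ORFs in the
#' class with at least one matching peptide, normalised by the class mean
#' expression level (higher-expressed classes are better represented in MS
#' data). Pure arithmetic on externally supplied counts.
#'
#' @param nSupported ORFs with >= 1 matching peptide (> 0 for a defined
#'   value; 0 returns NA).
#' @param nTotal total ORFs in the class.
#' @param expression mean expression level of the class (> 0).
#' @return the support value, or NA when nSupported is 0.
#' @export
msSupport <- function(nSupported, nTotal, expression) {
    stopifnot(nSupported >= 0, nSupported <= nTotal, expression > 0)
    if (nSupported == 0) return(NA_real_)
    log10(nSupported / (nTotal * expression))
}

#' Ratio of MS support between novel and annotated ORFs
#'
#' Enables intraspecies comparison of support degrees.
#' @param novel,annotated support values from [msSupport()].
#' @return novel / annotated.
#' @export
normalizedMsSupport <- function(novel, annotated) {
    if (is.na(novel) || is.na(annotated)) return(NA_real_)
    if (annotated == 0) stop("annotated support is zero")
    novel / annotated
}

#' Split a universe of ORFs into prediction-support groups
#'
#' Partitions the universe (typically the annotated ORFs) into (i) common:
#' predicted from both SNPs and RPFs, (ii) snp_only: predicted from SNPs
#' only, (iii) not_predicted: not predicted from SNPs (ORFs found only in
#' the RPF set fall here, since the grouping tracks SNP-based recovery).
#'
#' @param universe,snp,rpf ORF tables or identity-key vectors.
#' @return factor over the universe with levels common, snp_only,
#'   not_predicted.
#' @export
threeGroupSplit <- function(universe, snp, rpf) {
    uk <- if (is.character(universe)) universe else orfIdentity(universe)
    sk <- if (is.character(snp)) snp else orfIdentity(snp)
    rk <- if (is.character(rpf)) rpf else orfIdentity(rpf)
    lab <- ifelse(uk %in% sk & uk %in% rk, "common",
           ifelse(uk %in% sk, "snp_only", "not_predicted"))
    factor(lab, levels = c("common", "snp_only", "not_predicted"))
}
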