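#' MethylationSet: site x sample methylation container
#'
#' Thin extension of \linkS4class{SummarizedExperiment} holding a beta-value
#' assay (methylation fractions in \[0,1\], \code{NA} allowed), optional CpG
#' manifest information as \code{rowData}/\code{rowRanges} and sample
#' annotation as \code{colData}.
#'
#' All slots are inherited from \code{RangedSummarizedExperiment}.
#'
#' @seealso [MethylationSet()], [betaValues()], [mValues()]
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#'   RangedSummarizedExperiment
#' @exportClass MethylationSet
setClass("MethylationSet", contains = "RangedSummarizedExperiment")

setValidity("MethylationSet", function(object) {
    msg <- NULL
    if (!("beta" %in% names(assays(object))))
        msg <- c(msg, "assay 'beta' is required")
    else {
        b <- assay(object, "beta")
        if (any(b < 0 | b > 1, na.rm = TRUE))
            msg <- c(msg, "beta values must lie in [0, 1]")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "site ids (rownames) must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be unique")
    if (is.null(msg)) TRUE else msg
})

#' Construct a MethylationSet
#'
#' @param beta numeric matrix of methylation beta values (sites x samples),
#'   values in \[0,1\] or \code{NA}; rownames are CpG ids, colnames sample ids.
#' @param manifest optional \code{GRanges} (names = CpG ids) or data.frame
#'   with columns \code{cpg_id, chrom, pos, strand, gene} describing probe
#'   loci (1-based coordinates).
#' @param sampleInfo optional data.frame of per-sample annotation, rownames
#'   or a \code{sample_id} column matching \code{colnames(beta)}.
#' @return a \linkS4class{MethylationSet}
#' @examples
#' b <- matrix(runif(6), 3, 2,
#'             dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' MethylationSet(b)
#' @export
MethylationSet <- function(beta, manifest = NULL, sampleInfo = NULL) {
    beta <- as.matrix(beta)
    if (is.null(rownames(beta)))
        stop("'beta' must have rownames (CpG ids)")
    if (is.null(colnames(beta)))
        stop("'beta' must have colnames (sample ids)")
    storage.mode(beta) <- "double"
    cd <- if (is.null(sampleInfo)) {
        DataFrame(row.names = colnames(beta))
    } else {
        si <- as.data.frame(sampleInfo)
        if ("sample_id" %in% names(si)) rownames(si) <- si$sample_id
        DataFrame(si[colnames(beta), , drop = FALSE])
    }
    se <- if (inherits(manifest, "GRanges")) {
        SummarizedExperiment(assays = list(beta = beta),
                             rowRanges = manifest[rownames(beta)],
                             colData = cd)
    } else if (is.data.frame(manifest)) {
        rd <- manifest
        rownames(rd) <- rd$cpg_id
        SummarizedExperiment(assays = list(beta = beta),
                             rowData = DataFrame(rd[rownames(beta), , drop = FALSE]),
                             colData = cd)
    } else {
        SummarizedExperiment(assays = list(beta = beta), colData = cd)
    }
    se <- as(se, "RangedSummarizedExperiment")
    new("MethylationSet", se)
}

#' Per-site linear model fit on M-values
#'
#' Ordinary least-squares fit of a common design matrix to every methylation
#' site. After [applyContrasts()] the \code{coefficients} hold contrast
#' estimates and \code{covUnscaled} the contrast covariance factor.
#'
#' @slot coefficients numeric matrix, sites x coefficients (M-value units).
#' @slot covUnscaled unscaled covariance factor of the coefficients,
#'   \eqn{(X^T X)^{-1}} (or \eqn{C^T (X^T X)^{-1} C} after contrasts).
#' @slot sigma2 per-site residual variance.
#' @slot df residual degrees of freedom (scalar, common to all sites).
#' @slot design the design matrix used for fitting.
#' @seealso [fitLinearModel()], [applyContrasts()], [eBayesModerate()]
#' @exportClass MethylFit
setClass("MethylFit", representation(
    coefficients = "matrix",
    covUnscaled  = "matrix",
    sigma2       = "numeric",
    df           = "numeric",
    design       = "matrix"))

setValidity("MethylFit", function(object) {
    msg <- NULL
    k <- ncol(object@coefficients)
    if (!all(dim(object@covUnscaled) == c(k, k)))
        msg <- c(msg, "covUnscaled must be k x k for k coefficient columns")
    if (length(object@sigma2) != nrow(object@coefficients))
        msg <- c(msg, "sigma2 must have one entry per site")
    if (length(object@df) != 1L || object@df < 0)
        msg <- c(msg, "df must be a single nonnegative number")
    if (any(object@sigma2 < 0, na.rm = TRUE))
        msg <- c(msg, "sigma2 must be nonnegative")
    if (is.null(msg)) TRUE else msg
})

#' Empirical-Bayes moderated fit
#'
#' A [MethylFit-class] augmented with the estimated variance prior
#' (\code{d0}, \code{s02}), posterior variances and moderated statistics.
#'
#' @slot d0 prior degrees of freedom of the inverse-chi-square variance prior.
#' @slot s02 prior variance.
#' @slot s2Post per-site posterior (shrunken) residual variance
#'   \eqn{(d_0 s_0^2 + d s^2) / (d_0 + d)}.
#' @slot dfTotal total degrees of freedom \code{d0 + df} used for p-values.
#' @slot tStat moderated t-statistics, sites x contrasts.
#' @slot pValue raw two-sided p-values.
#' @slot qValue Benjamini-Hochberg adjusted p-values (per contrast column).
#' @seealso [eBayesModerate()], [moderatedF()], [decisionMatrix()]
#' @exportClass ModeratedFit
setClass("ModeratedFit", contains = "MethylFit", representation(
    d0      = "numeric",
    s02     = "numeric",
    s2Post  = "numeric",
    dfTotal = "numeric",
    tStat   = "matrix",
    pValue  = "matrix",
    qValue  = "matrix"))

setValidity("ModeratedFit", function(object) {
    msg <- NULL
    s2 <- object@sigma2
    sp <- object@s2Post
    lo <- pmin(s2, object@s02) - 1e-8
    hi <- pmax(s2, object@s02) + 1e-8
    bad <- !is.na(sp) & (sp < lo | sp > hi)
    if (any(bad))
        msg <- c(msg, "s2Post must lie between sigma2 and s02 for every site")
    if (any(object@qValue < object@pValue - 1e-12, na.rm = TRUE))
        msg <- c(msg, "adjusted p-values cannot be smaller than raw p-values")
    if (any(object@qValue > 1 + 1e-12 | object@qValue < 0, na.rm = TRUE))
        msg <- c(msg, "qValue must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' EpiTYPER amplicon
#'
#' A PCR amplicon on bisulfite-converted DNA with tagged primers, as used in
#' MassARRAY EpiTYPER assays. CpG positions are enumerated 5'->3' on the
#' converted forward strand; variable (C/T after conversion) positions are
#' carried as \code{Y}.
#'
#' @slot chrom chromosome label (may be \code{NA} for synthetic templates).
#' @slot genomicStart 1-based genomic coordinate of template position 1.
#' @slot template original (unconverted) template sequence.
#' @slot converted bisulfite-converted template (CpG Cs as \code{Y}).
#' @slot ampStart,ampEnd 1-based span of the amplicon within the template.
#' @slot ampSeq converted amplicon subsequence.
#' @slot cpgPos 1-based positions of CpG Cs within the amplicon.
#' @slot fwdPrimer,revPrimer tagged primers as supplied (lowercase tags).
#' @seealso [buildAmplicon()], [cleaveTranscript()]
#' @exportClass Amplicon
setClass("Amplicon", representation(
    chrom        = "character",
    genomicStart = "numeric",
    template     = "character",
    converted    = "character",
    ampStart     = "integer",
    ampEnd       = "integer",
    ampSeq       = "character",
    cpgPos       = "integer",
    fwdPrimer    = "character",
    revPrimer    = "character"))

setValidity("Amplicon", function(object) {
    msg <- NULL
    if (is.unsorted(object@cpgPos, strictly = TRUE))
        msg <- c(msg, "cpgPos must be strictly increasing")
    if (object@ampStart < 1L || object@ampEnd > nchar(object@template))
        msg <- c(msg, "amplicon span must lie within the template")
    if (is.null(msg)) TRUE else msg
})

#' ROC curve result
#'
#' @slot points data.frame with columns \code{threshold}, \code{sensitivity},
#'   \code{specificity}, ordered by decreasing threshold (the decision rule is
#'   \dQuote{score >= threshold is called positive}).
#' @slot auc area under the curve (tie-corrected; equals the Mann-Whitney
#'   U statistic divided by n1*n0).
#' @slot nCases,nControls class sizes.
#' @seealso [rocCurve()], [sensitivityAtSpecificity()]
#' @exportClass RocCurve
setClass("RocCurve", representation(
    points    = "data.frame",
    auc       = "numeric",
    nCases    = "integer",
    nControls = "integer"))

setValidity("RocCurve", function(object) {
    msg <- NULL
    if (object@auc < 0 || object@auc > 1)
        msg <- c(msg, "auc must lie in [0, 1]")
    p <- object@points
    if (!all(c("threshold", "sensitivity", "specificity") %in% names(p)))
        msg <- c(msg, "points must have threshold/sensitivity/specificity")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "ModeratedFit", function(object) {
    cat("ModeratedFit:", nrow(object@coefficients), "sites,",
        ncol(object@coefficients), "contrast(s)\n")
    cat(sprintf("  residual df %g, prior df d0 = %.4g, prior variance s0^2 = %.4g\n",
                object@df, object@d0, object@s02))
    nsig <- colSums(object@qValue < 0.05, na.rm = TRUE)
    cat("  sites with q < 0.05 per contrast:\n")
    print(nsig)
    invisible(object)
})

setMethod("show", "MethylFit", function(object) {
    cat("MethylFit:", nrow(object@coefficients), "sites,",
        ncol(object@coefficients), "coefficient(s), residual df",
        object@df, "\n")
    invisible(object)
})

setMethod("show", "Amplicon", function(object) {
    cat("Amplicon", if (!is.na(object@chrom))
            sprintf("%s:%d-%d", object@chrom,
                    as.integer(object@genomicStart + object@ampStart - 1),
                    as.integer(object@genomicStart + object@ampEnd - 1))
        else sprintf("(template positions %d-%d)", object@ampStart, object@ampEnd),
        "\n")
    cat("  length", nchar(object@ampSeq), "nt,", length(object@cpgPos),
        "CpG site(s) at amplicon positions:",
        paste(object@cpgPos, collapse = ", "), "\n")
    invisible(object)
})

setMethod("show", "RocCurve", function(object) {
    cat(sprintf("RocCurve: %d cases vs %d controls, AUC = %.4f\n",
                object@nCases, object@nControls, object@auc))
    invisible(object)
})
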