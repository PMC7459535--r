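# metadata columns of a cohort table; everything else numeric is treated
# as a CpG/unit methylation column
.cohortMetaCols <- c("sampleId", "cohortGroup", "gender", "age",
                     "ucHistory", "leukocytesPerUl", "stage", "grade")

#' CpG/unit methylation columns of a cohort table
#'
#' @param cohort cohort data.frame.
#' @return character vector of methylation column names.
#' @export
cpgColumns <- function(cohort) {
    cand <- setdiff(names(cohort), .cohortMetaCols)
    cand[vapply(cohort[cand], is.numeric, logical(1))]
}

#' Cohort exclusion filter
#'
#' Excludes urine specimens with a leukocyte count at or above
#' \code{leukoMax} per microliter, and (when \code{requireHistory}) UC cases
#' lacking information on UC history. Values are never modified, only
#' membership; the exclusion log is attached as attribute
#' \code{"exclusionLog"}.
#'
#' @param cohort cohort data.frame with columns \code{sampleId},
#'   \code{cohortGroup}, \code{leukocytesPerUl}, \code{ucHistory}, plus
#'   methylation columns.
#' @param leukoMax exclusion threshold, count per microliter (default 500;
#'   exclusion at \code{>=}).
#' @param requireHistory drop UC cases with missing \code{ucHistory}
#'   (default TRUE).
#' @return the filtered cohort with an \code{exclusionLog} attribute
#'   (data.frame of \code{sampleId}, \code{reason}).
#' @export
cohortFilter <- function(cohort, leukoMax = 500, requireHistory = TRUE) {
    leukoOut <- !is.na(cohort$leukocytesPerUl) &
                cohort$leukocytesPerUl >= leukoMax
    histOut <- requireHistory & cohort$cohortGroup == "UC" &
               is.na(cohort$ucHistory)
    log <- rbind(
        data.frame(sampleId = cohort$sampleId[leukoOut],
                   reason = rep(sprintf("leukocytes >= %g/uL", leukoMax),
                                sum(leukoOut))),
        data.frame(sampleId = cohort$sampleId[histOut & !leukoOut],
                   reason = rep("UC case with missing UC history",
                                sum(histOut & !leukoOut))))
    out <- cohort[!(leukoOut | histOut), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "exclusionLog") <- log
    out
}

#' Mann-Whitney U test
#'
#' Rank-sum test with the U statistic reported for the first sample. The
#' two-sided p-value is exact (via the null U distribution) when
#' \code{length(x) + length(y) <= 12} and there are no ties, otherwise a
#' normal approximation with tie and continuity correction is used.
#'
#' @param x,y numeric samples (NAs dropped).
#' @return list with \code{statistic} (U for \code{x}), \code{pValue} and
#'   \code{method} (\code{"exact"} or \code{"normal"}).
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mannWhitney <- function(x, y) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    n1 <- length(x); n2 <- length(y)
    if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty")
    r <- rank(c(x, y))
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    ties <- table(c(x, y))
    hasTies <- any(ties > 1L)
    if (!hasTies && n1 + n2 <= 12L) {
        p <- 2 * min(pwilcox(U, n1, n2),
                     1 - pwilcox(U - 1, n1, n2))
        list(statistic = U, pValue = min(1, p), method = "exact")
    } else {
        N <- n1 + n2
        mu <- n1 * n2 / 2
        tieAdj <- sum(ties^3 - ties) / (N * (N - 1))
        sigma2 <- n1 * n2 / 12 * ((N + 1) - tieAdj)
        if (sigma2 <= 0) return(list(statistic = U, pValue = 1,
                                     method = "normal"))
        z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
        z <- max(z, 0)
        list(statistic = U, pValue = min(1, 2 * pnorm(-z)),
             method = "normal")
    }
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-square reference on k - 1 degrees
#' of freedom (via \code{stats::kruskal.test}). All-identical input returns
#' H = 0, p = 1.
#'
#' @param groups list of numeric vectors (NAs dropped; empty groups
#'   removed).
#' @return list with \code{statistic} (H), \code{df} and \code{pValue}.
#' @examples
#' kruskalWallis(list(c(1, 2), c(3, 4), c(5, 6)))$statistic  # 32/7
#' @export
kruskalWallis <- function(groups) {
    groups <- lapply(groups, function(g) g[!is.na(g)])
    groups <- groups[lengths(groups) > 0L]
    if (length(groups) < 2L) stop("at least two non-empty groups required")
    vals <- unlist(groups, use.names = FALSE)
    if (length(unique(vals)) == 1L)
        return(list(statistic = 0, df = length(groups) - 1L, pValue = 1))
    g <- factor(rep(seq_along(groups), lengths(groups)))
    kt <- kruskal.test(vals, g)
    list(statistic = unname(kt$statistic), df = unname(kt$parameter),
         pValue = kt$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks with a t-distribution p-value
#' approximation on n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors (pairwise-complete; n >= 3 required).
#' @return list with \code{rho}, \code{pValue} and \code{n}; when either
#'   variable has zero rank variance, \code{rho} is \code{NA} with a
#'   \code{reason}.
#' @examples
#' spearmanCor(1:4, c(2, 1, 4, 3))$rho  # 0.6
#' @export
spearmanCor <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3L) stop("at least three complete pairs required")
    rx <- rank(x); ry <- rank(y)
    if (sd(rx) == 0 || sd(ry) == 0)
        return(list(rho = NA_real_, pValue = NA_real_, n = n,
                    reason = "zero rank variance"))
    rho <- stats::cor(rx, ry)
    if (abs(rho) >= 1) {
        p <- 0
    } else {
        tstat <- rho * sqrt((n - 2) / (1 - rho^2))
        p <- 2 * pt(-abs(tstat), df = n - 2)
    }
    list(rho = rho, pValue = p, n = n)
}

#' Median of per-CpG statistics
#'
#' @param perCpgValues numeric vector of per-CpG statistics (differences,
#'   p-values, correlations...).
#' @return their median (even counts: mean of the central pair).
#' @export
medianAcrossCpgs <- function(perCpgValues) {
    stopifnot(length(perCpgValues) >= 1L)
    median(perCpgValues, na.rm = TRUE)
}

#' ROC curve
#'
#' Sweeps all distinct score thresholds under the decision rule
#' \dQuote{score >= threshold called positive} (higher methylation predicts
#' UC). The AUC is computed from ranks (tied case-control pairs credited
#' 0.5), which equals the trapezoidal area under the empirical curve.
#'
#' @param scores numeric scores (NAs dropped pairwise with labels).
#' @param labels case indicator: logical, 0/1, or a factor/character whose
#'   \code{positive} level marks cases.
#' @param positive positive-class label used when \code{labels} is not
#'   logical/numeric (default \code{"UC"}).
#' @return a [RocCurve-class].
#' @export
rocCurve <- function(scores, labels, positive = "UC") {
    if (is.logical(labels)) isCase <- labels
    else if (is.numeric(labels)) isCase <- labels != 0
    else isCase <- as.character(labels) == positive
    ok <- !is.na(scores) & !is.na(isCase)
    scores <- scores[ok]; isCase <- isCase[ok]
    n1 <- sum(isCase); n0 <- sum(!isCase)
    if (n1 == 0L || n0 == 0L)
        stop("both classes must be present")
    thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
    sens <- vapply(thr, function(t) sum(scores[isCase] >= t) / n1, numeric(1))
    spec <- vapply(thr, function(t) sum(scores[!isCase] < t) / n0, numeric(1))
    r <- rank(scores)
    auc <- (sum(r[isCase]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    new("RocCurve",
        points = data.frame(threshold = thr, sensitivity = sens,
                            specificity = spec),
        auc = auc, nCases = as.integer(n1), nControls = as.integer(n0))
}

#' Sensitivity at a preset specificity
#'
#' Among all thresholds whose specificity is at least \code{specTarget},
#' returns the maximum sensitivity and the corresponding threshold
#' (0 and \code{NA} when no threshold qualifies).
#'
#' @param roc a [RocCurve-class].
#' @param specTarget required specificity (default 0.95).
#' @return list with \code{sensitivity} and \code{threshold}.
#' @export
sensitivityAtSpecificity <- function(roc, specTarget = 0.95) {
    p <- roc@points
    ok <- p$specificity >= specTarget
    if (!any(ok)) return(list(sensitivity = 0, threshold = NA_real_))
    best <- which(ok)[which.max(p$sensitivity[ok])]
    list(sensitivity = p$sensitivity[best], threshold = p$threshold[best])
}

#' Gender-stratified group comparison report
#'
#' For each stratum: drops CpG/unit columns whose within-stratum missing
#' fraction exceeds \code{missingnessMax}; runs per-CpG Mann-Whitney tests
#' of UC against each control group, a Kruskal-Wallis test across the
#' non-UC groups, the pooled non-UC vs UC comparison, and a ROC per CpG
#' (UC vs pooled non-UC) with sensitivity at the preset specificity;
#' summarizes each statistic by its median across CpGs. Comparisons whose
#' stratum lacks a class are skipped with a recorded reason.
#'
#' @param cohort (filtered) cohort data.frame; see [cohortFilter()].
#' @param cpgCols methylation columns (default: autodetected).
#' @param controlGroups control groups compared against UC (default
#'   \code{c("PC", "RC", "PCt", "UCt")}).
#' @param strata stratification column (default \code{"gender"}).
#' @param missingnessMax maximum tolerated missing fraction per CpG within
#'   a stratum (default 0.25).
#' @param specTarget preset specificity for the sensitivity readout
#'   (default 0.95).
#' @return named list (one element per stratum level), each with
#'   \code{pairwise} (per-CpG data.frame), \code{pooled}, \code{roc},
#'   \code{kruskalNonUc}, \code{medians}, \code{droppedCpgs} and
#'   \code{skipped}.
#' @export
groupComparisonReport <- function(cohort, cpgCols = NULL,
                                  controlGroups = c("PC", "RC", "PCt", "UCt"),
                                  strata = "gender",
                                  missingnessMax = 0.25,
                                  specTarget = 0.95) {
    if (is.null(cpgCols)) cpgCols <- cpgColumns(cohort)
    out <- list()
    for (lev in unique(cohort[[strata]])) {
        sub <- cohort[cohort[[strata]] == lev, , drop = FALSE]
        missFrac <- vapply(sub[cpgCols],
                           function(v) mean(is.na(v)), numeric(1))
        dropped <- cpgCols[missFrac > missingnessMax]
        keep <- setdiff(cpgCols, dropped)
        skipped <- data.frame(comparison = character(0),
                              reason = character(0))
        grp <- function(g) sub[sub$cohortGroup %in% g, keep, drop = FALSE]
        ucDat <- grp("UC")
        pairwise <- NULL
        for (ctrl in controlGroups) {
            cDat <- grp(ctrl)
            if (nrow(ucDat) == 0L || nrow(cDat) == 0L) {
                skipped <- rbind(skipped, data.frame(
                    comparison = paste0("UC_vs_", ctrl),
                    reason = sprintf("empty class (UC n=%d, %s n=%d)",
                                     nrow(ucDat), ctrl, nrow(cDat))))
                next
            }
            for (cpg in keep) {
                mw <- mannWhitney(ucDat[[cpg]], cDat[[cpg]])
                pairwise <- rbind(pairwise, data.frame(
                    comparison = paste0("UC_vs_", ctrl), cpg = cpg,
                    medianDiff = median(ucDat[[cpg]], na.rm = TRUE) -
                                 median(cDat[[cpg]], na.rm = TRUE),
                    U = mw$statistic, pValue = mw$pValue))
            }
        }
        nonUc <- sub[sub$cohortGroup %in% controlGroups, , drop = FALSE]
        kw <- NULL
        if (length(unique(nonUc$cohortGroup)) >= 2L) {
            for (cpg in keep) {
                g <- split(nonUc[[cpg]], nonUc$cohortGroup)
                g <- lapply(g, function(v) v[!is.na(v)])
                g <- g[lengths(g) > 0L]
                if (length(g) < 2L) next
                k <- kruskalWallis(g)
                kw <- rbind(kw, data.frame(cpg = cpg, H = k$statistic,
                                           pValue = k$pValue))
            }
        } else {
            skipped <- rbind(skipped, data.frame(
                comparison = "kruskal_nonUC",
                reason = "fewer than two non-UC groups present"))
        }
        pooled <- NULL; rocTab <- NULL
        if (nrow(ucDat) > 0L && nrow(nonUc) > 0L) {
            for (cpg in keep) {
                mw <- mannWhitney(ucDat[[cpg]], nonUc[[cpg]])
                pooled <- rbind(pooled, data.frame(
                    cpg = cpg,
                    medianDiff = median(ucDat[[cpg]], na.rm = TRUE) -
                                 median(nonUc[[cpg]], na.rm = TRUE),
                    U = mw$statistic, pValue = mw$pValue))
                scores <- c(ucDat[[cpg]], nonUc[[cpg]])
                lab <- c(rep(TRUE, nrow(ucDat)), rep(FALSE, nrow(nonUc)))
                if (sum(!is.na(ucDat[[cpg]])) > 0L &&
                    sum(!is.na(nonUc[[cpg]])) > 0L) {
                    roc <- rocCurve(scores, lab)
                    sas <- sensitivityAtSpecificity(roc, specTarget)
                    rocTab <- rbind(rocTab, data.frame(
                        cpg = cpg, auc = roc@auc,
                        sensitivity = sas$sensitivity,
                        threshold = sas$threshold))
                }
            }
        } else {
            skipped <- rbind(skipped, data.frame(
                comparison = "UC_vs_nonUC",
                reason = "UC or pooled non-UC stratum empty"))
        }
        medians <- list(
            pairwiseDiff = if (!is.null(pairwise))
                vapply(split(pairwise$medianDiff, pairwise$comparison),
                       median, numeric(1)) else NULL,
            pairwiseP = if (!is.null(pairwise))
                vapply(split(pairwise$pValue, pairwise$comparison),
                       median, numeric(1)) else NULL,
            pooledDiff = if (!is.null(pooled))
                median(pooled$medianDiff) else NA_real_,
            pooledP = if (!is.null(pooled)) median(pooled$pValue) else NA_real_,
            auc = if (!is.null(rocTab)) median(rocTab$auc) else NA_real_,
            sensitivity = if (!is.null(rocTab))
                median(rocTab$sensitivity) else NA_real_)
        out[[as.character(lev)]] <- list(
            pairwise = pairwise, pooled = pooled, roc = rocTab,
            kruskalNonUc = kw, medians = medians,
            droppedCpgs = dropped, skipped = skipped)
    }
    out
}
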