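#' Per-tissue differential site sets
#'
#' Extracts, for each contrast column of a decision matrix, the set of sites
#' with a nonzero call.
#'
#' @param decisions integer matrix from [decisionMatrix()].
#' @param contrasts columns to extract (default all).
#' @return named list of character vectors of site ids.
#' @export
tissueDifferentialSets <- function(decisions, contrasts = colnames(decisions)) {
    sets <- lapply(contrasts, function(ct)
        rownames(decisions)[decisions[, ct] != 0L])
    names(sets) <- contrasts
    sets
}

#' Three-set Venn counts
#'
#' Standard inclusion-exclusion partition of three sets into the seven
#' exclusive regions, plus the total pairwise overlaps and the union size.
#'
#' @param A,B,C character vectors (sets of site ids).
#' @param setNames labels for the three sets.
#' @return list with \code{exclusive} (named counts of the 7 regions),
#'   \code{pairwiseTotal} (|A∩B|, |A∩C|, |B∩C|), \code{tripleTotal}
#'   (|A∩B∩C|) and \code{union}.
#' @export
vennCounts3 <- function(A, B, C, setNames = c("A", "B", "C")) {
    A <- unique(A); B <- unique(B); C <- unique(C)
    ab <- intersect(A, B); ac <- intersect(A, C); bc <- intersect(B, C)
    abc <- intersect(ab, C)
    excl <- c(
        length(setdiff(A, union(B, C))),
        length(setdiff(B, union(A, C))),
        length(setdiff(C, union(A, B))),
        length(ab) - length(abc),
        length(ac) - length(abc),
        length(bc) - length(abc),
        length(abc))
    names(excl) <- c(setNames,
                     paste(setNames[1], setNames[2], sep = "."),
                     paste(setNames[1], setNames[3], sep = "."),
                     paste(setNames[2], setNames[3], sep = "."),
                     paste(setNames, collapse = "."))
    pw <- c(length(ab), length(ac), length(bc))
    names(pw) <- names(excl)[4:6]
    list(exclusive = excl, pairwiseTotal = pw,
         tripleTotal = length(abc),
         union = length(union(union(A, B), C)))
}

#' Two-stage urothelial-specific selection
#'
#' A site is UC-specific when it (stage 1) is differentially methylated
#' between the UC cell lines and the primary urothelial cells, and (stage 2)
#' remains significant when the UC cell lines are compared against the
#' pooled group of all other cultures (prostate/renal lines and all primary
#' cells).
#'
#' @param stage1Sites site ids significant in the bladder cancer-vs-primary
#'   contrast.
#' @param stage2Q named vector of BH-adjusted p-values from the two-group
#'   (3 UC lines vs 9 remaining cultures) moderated comparison.
#' @param alpha significance threshold (default 0.05).
#' @return sorted character vector of selected site ids.
#' @export
selectUcSpecific <- function(stage1Sites, stage2Q, alpha = 0.05) {
    sig2 <- names(stage2Q)[!is.na(stage2Q) & stage2Q < alpha]
    sort(intersect(stage1Sites, sig2))
}

#' Direction and magnitude classification of candidates
#'
#' Classifies each site as hyper- or hypomethylated in cancer by the sign of
#' its in-vitro beta difference and bins the magnitude. The lower bin edge
#' is strict (\code{> 0.2}), the upper non-strict (\code{>= 0.4}).
#'
#' @param delta named per-site beta differences (cancer - primary).
#' @param thresholds two magnitude bin edges (default \code{c(0.2, 0.4)}).
#' @return data.frame with columns \code{cpgId}, \code{deltaBeta},
#'   \code{direction} (\code{hyper}/\code{hypo}/\code{none}) and \code{bin}.
#' @export
classifyDirection <- function(delta, thresholds = c(0.2, 0.4)) {
    stopifnot(length(thresholds) == 2L, thresholds[1] < thresholds[2])
    a <- abs(delta)
    bin <- ifelse(a >= thresholds[2], sprintf(">=%.1f", thresholds[2]),
           ifelse(a > thresholds[1],
                  sprintf("%.1f-%.1f", thresholds[1], thresholds[2]),
                  sprintf("<=%.1f", thresholds[1])))
    direction <- ifelse(delta > 0, "hyper", ifelse(delta < 0, "hypo", "none"))
    bin[direction == "none"] <- NA_character_
    data.frame(cpgId = names(delta), deltaBeta = unname(delta),
               direction = direction, bin = bin,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Integer percentage, rounded half-up
#'
#' @param k numerator count.
#' @param n denominator count (0 gives 0).
#' @return integer percent.
#' @examples
#' roundPercent(6577, 7000)  # 94
#' @export
roundPercent <- function(k, n) {
    if (n == 0) return(0L)
    as.integer(floor(100 * k / n + 0.5))
}

#' In-vitro/in-vivo concordance filtering and ranking
#'
#' Joins the in-vitro candidates against urine (in-vivo) array results and
#' applies the two concordance filters: \code{pass1} requires an absolute
#' urine beta difference above \code{minDelta}; \code{pass2} additionally
#' requires BH-adjusted significance in the UC-vs-population-control
#' comparison. Candidates absent from the urine table are flagged
#' (\code{inUrine = FALSE}), never silently dropped. The result is ranked by
#' decreasing |urine difference|, ties broken by CpG id.
#'
#' @param candidates character vector of candidate site ids.
#' @param urineResults data.frame with columns \code{cpgId},
#'   \code{deltaBetaInvivo}, \code{qPCt} (UC vs population controls) and
#'   optionally \code{qUCt}.
#' @param minDelta urine effect-size filter (default 0.2, strict).
#' @param alpha significance threshold for pass2 (default 0.05).
#' @return data.frame ordered by rank with columns \code{cpgId},
#'   \code{deltaBetaInvivo}, \code{qPCt}, \code{qUCt}, \code{inUrine},
#'   \code{pass1}, \code{pass2}, \code{rank}.
#' @export
invivoConcordance <- function(candidates, urineResults,
                              minDelta = 0.2, alpha = 0.05) {
    idx <- match(candidates, urineResults$cpgId)
    out <- data.frame(
        cpgId = candidates,
        deltaBetaInvivo = urineResults$deltaBetaInvivo[idx],
        qPCt = urineResults$qPCt[idx],
        qUCt = if ("qUCt" %in% names(urineResults))
                   urineResults$qUCt[idx] else NA_real_,
        inUrine = !is.na(idx),
        stringsAsFactors = FALSE)
    if (any(!out$inUrine))
        warning(sum(!out$inUrine),
                " candidate(s) absent from the urine results table")
    out$pass1 <- out$inUrine & !is.na(out$deltaBetaInvivo) &
                 abs(out$deltaBetaInvivo) > minDelta
    out$pass2 <- out$pass1 & !is.na(out$qPCt) & out$qPCt < alpha
    key <- abs(out$deltaBetaInvivo)
    key[is.na(key)] <- -Inf
    ord <- order(-key, out$cpgId)
    out <- out[ord, , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
}

#' Pick an amplicon target region around the top candidate
#'
#' The anchor is the top-ranked site of the supplied (already ranked)
#' candidate table; all candidate sites on the anchor's chromosome within
#' \code{windowBp} of its position become region members. The span covers
#' all members (1-based inclusive).
#'
#' @param ranked data.frame from [invivoConcordance()] (rank order is
#'   respected; typically pre-filtered to \code{pass2}).
#' @param manifest \code{GRanges} named by CpG id (see [readManifest()]).
#' @param windowBp half-window around the anchor position (default 300).
#' @param label region label (default \code{"ROI"}).
#' @return list with \code{label}, \code{anchor}, \code{members},
#'   \code{chrom}, \code{start}, \code{end}.
#' @export
pickRegion <- function(ranked, manifest, windowBp = 300, label = "ROI") {
    if (nrow(ranked) == 0L) stop("no candidates to pick a region from")
    anchor <- ranked$cpgId[1L]
    if (!(anchor %in% names(manifest)))
        stop("anchor site ", anchor, " not present in the manifest")
    known <- ranked$cpgId[ranked$cpgId %in% names(manifest)]
    gr <- manifest[known]
    achr <- as.character(seqnames(manifest[anchor]))
    apos <- start(manifest[anchor])
    sel <- as.character(seqnames(gr)) == achr &
           abs(start(gr) - apos) <= windowBp
    members <- known[sel]
    pos <- start(gr)[sel]
    list(label = label, anchor = anchor, members = members,
         chrom = achr, start = min(pos), end = max(pos))
}

#' Region of interest as a BED line
#'
#' Converts the 1-based inclusive region span to the 0-based half-open BED
#' convention (start - 1, end unchanged).
#'
#' @param region list from [pickRegion()].
#' @return a single BED-format string (chrom, start, end, name).
#' @export
regionToBed <- function(region) {
    sprintf("%s\t%d\t%d\t%s", region$chrom, region$start - 1L,
            region$end, region$label)
}

#' Screening summary counts and percentages
#'
#' Reproduces the reporting style of the cell-line screen: totals, hyper-
#' vs hypomethylated counts, and within each direction the share of sites
#' above the moderate (>0.2) and strong (>=0.4) beta-difference thresholds,
#' as integer percents rounded half-up.
#'
#' @param dirTable data.frame from [classifyDirection()].
#' @return list of counts and percentages.
#' @export
screenSummary <- function(dirTable) {
    tot <- nrow(dirTable)
    hyper <- dirTable[dirTable$direction == "hyper", , drop = FALSE]
    hypo <- dirTable[dirTable$direction == "hypo", , drop = FALSE]
    strong <- function(d) sum(abs(d$deltaBeta) >= 0.4)
    moderate <- function(d) sum(abs(d$deltaBeta) > 0.2)
    list(
        total = tot,
        nHyper = nrow(hyper), pctHyper = roundPercent(nrow(hyper), tot),
        nHypo = nrow(hypo), pctHypo = roundPercent(nrow(hypo), tot),
        hyperModerate = moderate(hyper),
        pctHyperModerate = roundPercent(moderate(hyper), nrow(hyper)),
        hyperStrong = strong(hyper),
        pctHyperStrong = roundPercent(strong(hyper), nrow(hyper)),
        hypoModerate = moderate(hypo),
        pctHypoModerate = roundPercent(moderate(hypo), nrow(hypo)),
        hypoStrong = strong(hypo),
        pctHypoStrong = roundPercent(strong(hypo), nrow(hypo)))
}
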