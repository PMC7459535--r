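#' End-to-end discovery pipeline on synthetic data
#'
#' Runs the full in-vitro screen: generates the 12-sample cell-line beta
#' matrix, fits the 6-group (tissue x malignancy) moderated model on
#' M-values, calls per-tissue cancer-vs-primary differential sites,
#' computes the three-set overlap, applies the second-stage
#' urothelial-specificity model (3 UC lines vs the 9 remaining cultures,
#' BH within the stage-1 set), classifies direction/magnitude, filters
#' against simulated urine array results and picks the amplicon target
#' region around the top concordant site.
#'
#' @param config screen generator settings ([screenConfig()]).
#' @param urineConfig urine array generator settings ([urineArrayConfig()]).
#' @param seed integer seed driving all randomness.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param minDelta urine concordance effect threshold (default 0.2).
#' @param windowBp region-picking window (default 300).
#' @param outDir optional output directory; when given, candidate report
#'   (TSV), Venn counts (JSON), region (BED) and a run manifest (JSON) are
#'   written.
#' @return list with all intermediate results: \code{screen}, \code{mod},
#'   \code{decisions}, \code{tissueSets}, \code{venn}, \code{stage2Q},
#'   \code{selected}, \code{dirTable}, \code{summary}, \code{urine},
#'   \code{concordance}, \code{region}.
#' @export
runDiscovery <- function(config = screenConfig(),
                         urineConfig = urineArrayConfig(),
                         seed, alpha = 0.05, minDelta = 0.2,
                         windowBp = 300, outDir = NULL) {
    if (missing(seed)) stop("'seed' is mandatory")
    screen <- simulateCellLineScreen(config, seed = seed)
    mset <- screen$mset
    si <- as.data.frame(colData(mset))

    design <- groupDesign(setNames(si$group, si$sample_id))
    contrasts <- makeContrasts2(
        design,
        bladder  = c("bladder_cancer", "bladder_primary"),
        prostate = c("prostate_cancer", "prostate_primary"),
        kidney   = c("kidney_cancer", "kidney_primary"))
    fit <- fitLinearModel(mset, design)
    mod <- eBayesModerate(applyContrasts(fit, contrasts))
    decisions <- decisionMatrix(mod, alpha)
    tissueSets <- tissueDifferentialSets(decisions)
    venn <- vennCounts3(tissueSets$bladder, tissueSets$prostate,
                        tissueSets$kidney,
                        setNames = c("bladder", "prostate", "kidney"))

    # stage 2: UC lines vs everything else, restricted to stage-1 sites
    ucLines <- si$sample_id[si$group == "bladder_cancer"]
    stage2Group <- ifelse(si$sample_id %in% ucLines, "uc", "other")
    design2 <- groupDesign(setNames(stage2Group, si$sample_id))
    m2 <- mValues(mset)[tissueSets$bladder, , drop = FALSE]
    stage2Q <- if (nrow(m2) >= 2L) {
        fit2 <- fitLinearModel(m2, design2)
        mod2 <- eBayesModerate(
            applyContrasts(fit2, makeContrasts2(design2,
                                                ucVsOther = c("uc", "other"))))
        mod2@qValue[, 1L]
    } else setNames(numeric(0), character(0))
    selected <- selectUcSpecific(tissueSets$bladder, stage2Q, alpha)

    primary <- si$sample_id[si$group == "bladder_primary"]
    dBladder <- deltaBeta(mset, ucLines, primary)
    dirAll <- classifyDirection(dBladder[tissueSets$bladder])
    dirSelected <- classifyDirection(dBladder[selected])

    urine <- simulateUrineArrayResults(screen$truth, urineConfig,
                                       seed = seed + 1L)
    concordance <- invivoConcordance(selected, urine,
                                     minDelta = minDelta, alpha = alpha)
    passing <- concordance[concordance$pass2, , drop = FALSE]
    region <- if (nrow(passing) > 0L) {
        pickRegion(passing, SummarizedExperiment::rowRanges(mset),
                   windowBp = windowBp, label = "BLSP-like")
    } else NULL

    res <- list(screen = screen, design = design, contrasts = contrasts,
                mod = mod, decisions = decisions, tissueSets = tissueSets,
                venn = venn, stage2Q = stage2Q, selected = selected,
                dirTable = dirSelected, summary = screenSummary(dirAll),
                urine = urine, concordance = concordance, region = region)
    if (!is.null(outDir)) .writeDiscovery(res, outDir, seed, config, alpha)
    res
}

.writeDiscovery <- function(res, outDir, seed, config, alpha) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.table(res$concordance,
                file.path(outDir, "candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_json(lapply(res$venn, as.list),
               file.path(outDir, "venn_counts.json"), auto_unbox = TRUE)
    if (!is.null(res$region))
        writeLines(regionToBed(res$region),
                   file.path(outDir, "region.bed"))
    write_json(list(seed = seed, alpha = alpha, config = config,
                    nSelected = length(res$selected),
                    perTissue = lapply(res$tissueSets, length)),
               file.path(outDir, "run_manifest.json"), auto_unbox = TRUE)
    invisible(NULL)
}

#' End-to-end diagnostic evaluation on a synthetic urine cohort
#'
#' Simulates the EpiTYPER urine cohort, aggregates CpGs into measurement
#' units, applies the leukocyte/history exclusion filter and produces the
#' gender-stratified statistical report (group tests, ROC/AUC, sensitivity
#' at preset specificity, medians across CpGs).
#'
#' @param config cohort generator settings ([cohortConfig()]).
#' @param units measurement unit table (default [markerUnits()]).
#' @param seed integer seed.
#' @param leukoMax,specTarget filter threshold and ROC specificity target.
#' @param outDir optional output directory for the report JSON.
#' @return list with \code{cohort} (raw), \code{unitCohort},
#'   \code{filtered}, \code{exclusions} and \code{report}.
#' @export
runDiagnostics <- function(config = cohortConfig(), units = markerUnits(),
                           seed, leukoMax = 500, specTarget = 0.95,
                           outDir = NULL) {
    if (missing(seed)) stop("'seed' is mandatory")
    cohort <- simulateUrineCohort(config, seed = seed)
    unitCohort <- simulateEpityperReadout(cohort, units)
    filtered <- cohortFilter(unitCohort, leukoMax = leukoMax)
    report <- groupComparisonReport(filtered, specTarget = specTarget)
    res <- list(cohort = cohort, unitCohort = unitCohort,
                filtered = filtered,
                exclusions = attr(filtered, "exclusionLog"),
                report = report)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        summ <- lapply(report, function(s) list(
            medians = s$medians,
            auc = if (!is.null(s$roc))
                setNames(as.list(s$roc$auc), s$roc$cpg) else NULL,
            sensitivity = if (!is.null(s$roc))
                setNames(as.list(s$roc$sensitivity), s$roc$cpg) else NULL,
            droppedCpgs = s$droppedCpgs))
        write_json(list(seed = seed, summary = summ),
                   file.path(outDir, "diagnostics_summary.json"),
                   auto_unbox = TRUE, digits = NA)
    }
    res
}
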