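#' Configuration for the cell-line screen generator
#'
#' Defaults emulate the 450K screening design: 12 samples (3 cancer cell
#' lines plus 1 primary culture for each of bladder, prostate and kidney),
#' a bimodal baseline methylation landscape, and planted differential
#' categories. Planted effects are drawn on the beta scale from
#' \code{deltaRange}; replicate noise is added on the M scale.
#'
#' @param nSites number of CpG sites (default 20000).
#' @param nUcSpecific planted urothelial-cancer-specific sites (default 40).
#' @param nPanCancer sites differential in all three tissues (default 2000).
#' @param nPairShared sites differential in bladder and prostate (default
#'   1000).
#' @param deltaRange planted |beta difference| range (default
#'   \code{c(0.4, 0.7)}).
#' @param hyperFracUc probability that a UC-specific planted site is
#'   hypermethylated in cancer (default 31/40, matching the observed
#'   hyper/hypo split).
#' @param hyperFracOther same for the other planted categories (default
#'   0.94).
#' @param noiseSd replicate noise standard deviation on the M scale
#'   (default 0.3).
#' @param lowFrac fraction of baseline sites in the unmethylated mode
#'   (default 0.6).
#' @return config list.
#' @export
screenConfig <- function(nSites = 20000, nUcSpecific = 40,
                         nPanCancer = 2000, nPairShared = 1000,
                         deltaRange = c(0.4, 0.7),
                         hyperFracUc = 31 / 40, hyperFracOther = 0.94,
                         noiseSd = 0.3, lowFrac = 0.6) {
    nPlanted <- nUcSpecific + nPanCancer + nPairShared
    if (nPlanted > nSites)
        stop("planted categories exceed the number of sites")
    if (deltaRange[1] < 0 || deltaRange[2] > 1 ||
        deltaRange[1] > deltaRange[2])
        stop("invalid 'deltaRange'")
    list(nSites = nSites, nUcSpecific = nUcSpecific,
         nPanCancer = nPanCancer, nPairShared = nPairShared,
         deltaRange = deltaRange, hyperFracUc = hyperFracUc,
         hyperFracOther = hyperFracOther, noiseSd = noiseSd,
         lowFrac = lowFrac)
}

.tissues <- c("bladder", "prostate", "kidney")

#' Simulate the cell-line methylation screen
#'
#' Generates a 12-sample beta matrix (3 cancer cell lines + 1 primary
#' culture per tissue) with planted ground truth. Baseline methylation per
#' site comes from a bimodal beta mixture; planted effects are added on the
#' beta scale (clipped to \[0.01, 0.99\]); replicate noise is applied on
#' the M scale and transformed back. A synthetic manifest is attached; the
#' two largest planted UC-specific sites are placed 6 bp apart on one
#' chromosome so that region picking has a realistic adjacent pair.
#'
#' @param config from [screenConfig()].
#' @param seed integer seed (mandatory; the generator is fully
#'   deterministic given the seed).
#' @return list with \code{mset} (a [MethylationSet-class] with manifest
#'   and sample annotation) and \code{truth} (data.frame: \code{cpgId},
#'   \code{category}, \code{direction}, \code{baseline},
#'   \code{deltaBladder}, \code{deltaProstate}, \code{deltaKidney}).
#' @export
simulateCellLineScreen <- function(config = screenConfig(), seed) {
    if (missing(seed)) stop("'seed' is mandatory")
    set.seed(seed)
    n <- config$nSites
    ids <- sprintf("cg%08d", seq_len(n))

    category <- rep("null", n)
    planted <- sample.int(n, config$nUcSpecific + config$nPanCancer +
                              config$nPairShared)
    category[planted[seq_len(config$nUcSpecific)]] <- "uc_specific"
    category[planted[config$nUcSpecific + seq_len(config$nPanCancer)]] <-
        "pan_cancer"
    category[planted[config$nUcSpecific + config$nPanCancer +
                     seq_len(config$nPairShared)]] <- "pair_shared"

    isPlanted <- category != "null"
    hyperP <- ifelse(category == "uc_specific", config$hyperFracUc,
                     config$hyperFracOther)
    direction <- rep(NA_character_, n)
    direction[isPlanted] <- ifelse(
        runif(sum(isPlanted)) < hyperP[isPlanted], "hyper", "hypo")

    baseline <- numeric(n)
    nullIdx <- which(!isPlanted)
    lowN <- rbinom(1L, length(nullIdx), config$lowFrac)
    lowPick <- sample(nullIdx, lowN)
    baseline[lowPick] <- rbeta(lowN, 2, 18)
    baseline[setdiff(nullIdx, lowPick)] <-
        rbeta(length(nullIdx) - lowN, 18, 2)
    # planted baselines leave headroom for the effect
    hyperIdx <- which(direction == "hyper")
    hypoIdx <- which(direction == "hypo")
    baseline[hyperIdx] <- runif(length(hyperIdx), 0.05, 0.25)
    baseline[hypoIdx] <- runif(length(hypoIdx), 0.70, 0.95)

    mag <- runif(n, config$deltaRange[1], config$deltaRange[2])
    effect <- ifelse(direction == "hypo", -mag, mag)
    effect[!isPlanted] <- 0
    affected <- cbind(
        bladder  = category %in% c("uc_specific", "pan_cancer", "pair_shared"),
        prostate = category %in% c("pan_cancer", "pair_shared"),
        kidney   = category == "pan_cancer")
    deltaTissue <- affected * effect  # n x 3 true beta effects

    sampleId <- unlist(lapply(.tissues, function(t)
        c(paste0(t, "_line", 1:3), paste0(t, "_primary"))))
    tissueOf <- rep(.tissues, each = 4L)
    malignancy <- rep(c("cancer_line", "cancer_line", "cancer_line",
                        "primary"), times = 3L)
    group <- paste(tissueOf, ifelse(malignancy == "primary",
                                    "primary", "cancer"), sep = "_")
    sampleInfo <- data.frame(sample_id = sampleId, tissue = tissueOf,
                             malignancy = malignancy, group = group,
                             stringsAsFactors = FALSE)

    trueBeta <- matrix(baseline, n, 12L)
    for (j in seq_len(12L)) {
        if (malignancy[j] != "primary")
            trueBeta[, j] <- trueBeta[, j] + deltaTissue[, tissueOf[j]]
    }
    trueBeta <- pmin(pmax(trueBeta, 0.01), 0.99)
    m <- betaToM(trueBeta) + matrix(rnorm(n * 12L, sd = config$noiseSd),
                                    n, 12L)
    beta <- mToBeta(m)
    dimnames(beta) <- list(ids, sampleId)

    # synthetic manifest; adjacent pair for the top two UC-specific effects
    chrom <- sample(paste0("chr", 1:22), n, replace = TRUE)
    pos <- sample.int(5e7, n, replace = TRUE)
    ucIdx <- which(category == "uc_specific")
    if (length(ucIdx) >= 2L) {
        top2 <- ucIdx[order(-abs(effect[ucIdx]))[1:2]]
        chrom[top2] <- "chr6"
        pos[top2[2]] <- 28911537L
        pos[top2[1]] <- 28911543L   # 6 bp downstream of its neighbor
    }
    manifest <- GRanges(chrom, IRanges(pos, width = 1L), strand = "+")
    names(manifest) <- ids
    manifest$gene <- NA_character_

    truth <- data.frame(cpgId = ids, category = category,
                        direction = direction, baseline = baseline,
                        deltaBladder = deltaTissue[, "bladder"],
                        deltaProstate = deltaTissue[, "prostate"],
                        deltaKidney = deltaTissue[, "kidney"],
                        stringsAsFactors = FALSE)
    list(mset = MethylationSet(beta, manifest = manifest,
                               sampleInfo = sampleInfo),
         truth = truth)
}

#' Configuration for the urine-array results generator
#'
#' @param attenuation multiplicative shrinkage of the in-vitro effect when
#'   observed in urine (default 0.8; urine dilutes the tumor signal).
#' @param noiseSd sd of the additive noise on the planted urine beta
#'   difference (default 0.05).
#' @param nPerGroup samples per group in the simulated 12-vs-12 urine
#'   array comparison (default 12).
#' @param mNoiseSd M-scale noise of the simulated urine arrays (default
#'   0.3).
#' @return config list.
#' @export
urineArrayConfig <- function(attenuation = 0.8, noiseSd = 0.05,
                             nPerGroup = 12, mNoiseSd = 0.3) {
    list(attenuation = attenuation, noiseSd = noiseSd,
         nPerGroup = nPerGroup, mNoiseSd = mNoiseSd)
}

#' Simulate urine (in-vivo) array results
#'
#' UC-specific sites carry an attenuated version of their planted in-vitro
#' effect (\code{attenuation * delta + noise}); all other sites are near
#' zero. Adjusted p-values come from running the moderated differential
#' pipeline on a simulated two-group urine comparison (UC patients vs
#' population controls, \code{nPerGroup} each); a second, independent
#' control comparison (UC vs urological controls) is simulated likewise.
#'
#' @param truth truth table from [simulateCellLineScreen()].
#' @param config from [urineArrayConfig()].
#' @param seed integer seed (mandatory).
#' @return data.frame with \code{cpgId}, \code{deltaBetaInvivo},
#'   \code{qPCt}, \code{qUCt}.
#' @export
simulateUrineArrayResults <- function(truth, config = urineArrayConfig(),
                                      seed) {
    if (missing(seed)) stop("'seed' is mandatory")
    set.seed(seed)
    n <- nrow(truth)
    isUc <- truth$category == "uc_specific"
    delta <- ifelse(isUc, config$attenuation * truth$deltaBladder, 0) +
             rnorm(n, sd = config$noiseSd)

    simulateComparison <- function() {
        k <- config$nPerGroup
        base <- truth$baseline
        caseBeta <- pmin(pmax(base + delta, 0.01), 0.99)
        ctrlBeta <- pmin(pmax(base, 0.01), 0.99)
        m <- cbind(
            matrix(betaToM(caseBeta), n, k) +
                matrix(rnorm(n * k, sd = config$mNoiseSd), n, k),
            matrix(betaToM(ctrlBeta), n, k) +
                matrix(rnorm(n * k, sd = config$mNoiseSd), n, k))
        rownames(m) <- truth$cpgId
        colnames(m) <- c(paste0("UC", seq_len(k)), paste0("Ct", seq_len(k)))
        design <- groupDesign(rep(c("UC", "Ct"), each = k))
        rownames(design) <- colnames(m)
        fit <- fitLinearModel(m, design)
        cfit <- applyContrasts(fit,
                               makeContrasts2(design, ucVsCt = c("UC", "Ct")))
        mod <- eBayesModerate(cfit)
        mod@qValue[, 1L]
    }
    qPCt <- simulateComparison()
    qUCt <- simulateComparison()
    data.frame(cpgId = truth$cpgId, deltaBetaInvivo = delta,
               qPCt = unname(qPCt[truth$cpgId]),
               qUCt = unname(qUCt[truth$cpgId]),
               stringsAsFactors = FALSE)
}

#' Configuration for the urine cohort generator
#'
#' Group sizes default to the reduced clinical collective (after leukocyte
#' and history exclusions): 207/42 UC male/female, 71 PC, 21 RC (13/8),
#' 41 population controls (30/11) and 68 urological controls (52/16).
#' Observed methylation in UC urine is a tumor-fraction mixture,
#' \deqn{\phi = \phi_0(gender) \cdot r^{recurrent} / (1 + c \cdot leuko/500),}
#' \deqn{obs = \phi \beta_{tumor} + (1-\phi) \beta_{background} + noise,}
#' with \eqn{\phi = 0} for all non-UC groups. Leukocyte counts are
#' log-normal with roughly 8\% of males and 30\% of females above 500/uL
#' (before filtering). Edge CpGs 1 and 13 get a high missingness rate,
#' emulating their exclusion for excessive missing values.
#'
#' @param groupSizes named list \code{group -> c(male, female)} counts.
#' @param basePhiMale,basePhiFemale baseline tumor fraction in urine
#'   sediment by gender (defaults 0.5 and 0.15; the female value encodes
#'   dilution by squamous cells).
#' @param leukoCoef leukocyte dilution coefficient \code{c} (default 1).
#' @param recurrenceMultiplier tumor-fraction multiplier for recurrent UC
#'   (default 0.7).
#' @param recurrentFrac fraction of UC cases with recurrent disease
#'   (default 0.5).
#' @param historyMissingRate fraction of UC cases with missing history
#'   annotation (default 0.05).
#' @param betaTumor,betaBackground methylation of tumor and background DNA
#'   at the marker CpGs (defaults 0.55 and 0.05: planted contrast 0.5 over
#'   a low-methylated background).
#' @param phiDispersion beta-distribution concentration for the per-sample
#'   tumor fraction (default 2: tumor shedding into urine varies strongly
#'   between patients; the gender/recurrence/leukocyte model sets the mean).
#' @param bgDispersion beta-distribution concentration for the per-sample
#'   background methylation (default 8; occasional controls reach
#'   background levels of 0.2 or more).
#' @param noiseSd measurement noise sd, truncated to keep values in
#'   \[0,1\] (default 0.05).
#' @param cpgs CpG labels measured by the assay (default CpGs 1, 5, 6, 7,
#'   8, 12, 13 of the amplicon).
#' @param edgeCpgs high-missingness CpGs (default \code{"CpG_1"},
#'   \code{"CpG_13"}).
#' @param missRateEdge,missRateOther per-CpG missingness rates (defaults
#'   0.4 and 0.05).
#' @param leukoMeanlogMale,leukoSdlogMale,leukoMeanlogFemale,leukoSdlogFemale
#'   log-normal leukocyte parameters.
#' @param ageMean,ageSd donor age distribution (default 68 +- 10).
#' @param ageSlope per-year additive methylation increase in male UC urine
#'   (default 0.002, a weak age effect).
#' @return config list.
#' @export
cohortConfig <- function(
        groupSizes = list(UC = c(207, 42), PC = c(71, 0), RC = c(13, 8),
                          PCt = c(30, 11), UCt = c(52, 16)),
        basePhiMale = 0.5, basePhiFemale = 0.15,
        leukoCoef = 1, recurrenceMultiplier = 0.7, recurrentFrac = 0.5,
        historyMissingRate = 0.05,
        betaTumor = 0.55, betaBackground = 0.05,
        phiDispersion = 2, bgDispersion = 8, noiseSd = 0.05,
        cpgs = c("CpG_1", "CpG_5", "CpG_6", "CpG_7", "CpG_8",
                 "CpG_12", "CpG_13"),
        edgeCpgs = c("CpG_1", "CpG_13"),
        missRateEdge = 0.4, missRateOther = 0.05,
        leukoMeanlogMale = 4.5, leukoSdlogMale = 1.25,
        leukoMeanlogFemale = 5.4, leukoSdlogFemale = 1.4,
        ageMean = 68, ageSd = 10, ageSlope = 0.002) {
    stopifnot(basePhiMale >= 0, basePhiMale <= 1,
              basePhiFemale >= 0, basePhiFemale <= 1,
              recurrenceMultiplier > 0, recurrenceMultiplier <= 1)
    as.list(environment())
}

#' Simulate an EpiTYPER urine cohort
#'
#' Per-sample, per-CpG methylation fractions with clinical metadata
#' (group, gender, age, leukocyte count, UC history), generated under the
#' tumor-fraction dilution model described in [cohortConfig()].
#'
#' @param config from [cohortConfig()].
#' @param seed integer seed (mandatory).
#' @return cohort data.frame (one row per sample) with metadata columns
#'   and one numeric column per CpG.
#' @export
simulateUrineCohort <- function(config = cohortConfig(), seed) {
    if (missing(seed)) stop("'seed' is mandatory")
    set.seed(seed)
    rows <- NULL
    for (g in names(config$groupSizes)) {
        sz <- config$groupSizes[[g]]
        rows <- rbind(rows,
            data.frame(cohortGroup = g,
                       gender = rep(c("male", "female"), sz),
                       stringsAsFactors = FALSE))
    }
    nS <- nrow(rows)
    rows$sampleId <- sprintf("%s_%s_%03d", rows$cohortGroup,
                             substr(rows$gender, 1, 1), seq_len(nS))
    rows$age <- round(pmin(pmax(rnorm(nS, config$ageMean, config$ageSd),
                                30), 95))
    male <- rows$gender == "male"
    rows$leukocytesPerUl <- round(ifelse(male,
        rlnorm(nS, config$leukoMeanlogMale, config$leukoSdlogMale),
        rlnorm(nS, config$leukoMeanlogFemale, config$leukoSdlogFemale)))
    isUc <- rows$cohortGroup == "UC"
    recurrent <- isUc & runif(nS) < config$recurrentFrac
    rows$ucHistory <- ifelse(isUc,
                             ifelse(recurrent, "recurrent", "de_novo"),
                             NA_character_)
    histMissing <- isUc & runif(nS) < config$historyMissingRate
    rows$ucHistory[histMissing] <- NA_character_

    basePhi <- ifelse(male, config$basePhiMale, config$basePhiFemale)
    phiMean <- ifelse(isUc,
                      basePhi * config$recurrenceMultiplier^recurrent /
                          (1 + config$leukoCoef * rows$leukocytesPerUl / 500),
                      0)
    # per-patient tumor shedding varies strongly: draw the realized tumor
    # fraction from a beta distribution around the model mean
    kphi <- config$phiDispersion
    phi <- ifelse(phiMean > 0,
                  rbeta(nS, pmax(phiMean * kphi, 1e-6),
                        pmax((1 - phiMean) * kphi, 1e-6)),
                  0)
    # background (leukocyte/squamous) methylation varies between donors
    kbg <- config$bgDispersion
    bg <- rbeta(nS, config$betaBackground * kbg,
                (1 - config$betaBackground) * kbg)
    ageCentered <- rows$age - config$ageMean
    for (cpg in config$cpgs) {
        mu <- phi * config$betaTumor + (1 - phi) * bg
        mu <- mu + ifelse(isUc & male,
                          config$ageSlope * ageCentered, 0)
        obs <- pmin(pmax(mu + rnorm(nS, sd = config$noiseSd), 0), 1)
        missRate <- if (cpg %in% config$edgeCpgs) config$missRateEdge
                    else config$missRateOther
        obs[runif(nS) < missRate] <- NA_real_
        rows[[cpg]] <- obs
    }
    rows[, c("sampleId", "cohortGroup", "gender", "age", "ucHistory",
             "leukocytesPerUl", config$cpgs)]
}

#' Aggregate a cohort to EpiTYPER unit resolution
#'
#' Replaces the member-CpG columns of each unit by their integrated value
#' (mean of available member values plus truncated noise); unmeasurable
#' units are emitted as all-missing columns. Unit members are CpG ordinal
#' indices matched to columns named \code{CpG_<k>}.
#'
#' @param cohort cohort data.frame from [simulateUrineCohort()].
#' @param units unit table from [assignUnits()]/[detectConflicts()] or a
#'   data.frame with \code{unit}, \code{members} (list column) and
#'   optionally \code{measurable}.
#' @param noiseSd integration noise sd (default 0; truncated to \[0,1\]).
#' @param seed integer seed (mandatory if \code{noiseSd > 0}).
#' @return cohort data.frame with one column per unit (named
#'   \code{CpG_<label>}) instead of the member CpG columns.
#' @export
simulateEpityperReadout <- function(cohort, units, noiseSd = 0, seed) {
    if (noiseSd > 0) {
        if (missing(seed)) stop("'seed' is mandatory when noiseSd > 0")
        set.seed(seed)
    }
    meta <- intersect(.cohortMetaCols, names(cohort))
    out <- cohort[, meta, drop = FALSE]
    measurable <- if ("measurable" %in% names(units)) units$measurable
                  else rep(TRUE, nrow(units))
    for (u in seq_len(nrow(units))) {
        colName <- paste0("CpG_", units$unit[u])
        if (!measurable[u]) {
            out[[colName]] <- NA_real_
            next
        }
        memberCols <- paste0("CpG_", units$members[[u]])
        memberCols <- intersect(memberCols, names(cohort))
        if (length(memberCols) == 0L) next
        vals <- rowMeans(cohort[, memberCols, drop = FALSE], na.rm = TRUE)
        vals[is.nan(vals)] <- NA_real_
        if (noiseSd > 0)
            vals <- pmin(pmax(vals + rnorm(length(vals), sd = noiseSd),
                              0), 1)
        out[[colName]] <- vals
    }
    out
}

#' Default unit structure for the marker amplicon
#'
#' The measurable units observed for the bladder-specific amplicon: CpGs 5
#' and 6 integrated as one unit (they share a T-cleavage fragment), the
#' remaining assessed CpGs as singletons.
#'
#' @return data.frame usable by [simulateEpityperReadout()].
#' @export
markerUnits <- function() {
    data.frame(
        unit = c("1", "5.6", "7", "8", "12", "13"),
        members = I(list(1L, c(5L, 6L), 7L, 8L, 12L, 13L)),
        measurable = TRUE,
        stringsAsFactors = FALSE)
}
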