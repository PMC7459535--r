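test_that("cohort filter applies leukocyte and history rules, with a log", {
    co <- miniCohort()
    out <- cohortFilter(co)
    # three violations: UC with missing history, and two leukocyte-rich
    expect_equal(nrow(out), 7)
    log <- attr(out, "exclusionLog")
    expect_equal(nrow(log), 3)
    expect_setequal(log$sampleId, c("s2", "s3", "s8"))
    # a PCt control with missing history is retained
    expect_true("s7" %in% out$sampleId)
    # 600/uL excluded, 450/uL retained (threshold is >= 500)
    expect_false("s3" %in% out$sampleId)
    expect_true("s6" %in% out$sampleId)
    # values untouched, filter idempotent
    expect_equal(out$CpG_7, co$CpG_7[match(out$sampleId, co$sampleId)])
    again <- cohortFilter(out)
    expect_equal(again$sampleId, out$sampleId)
    expect_equal(nrow(attr(again, "exclusionLog")), 0)
})

test_that("Mann-Whitney matches exact enumeration and handles ties", {
    mw <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
    expect_equal(mw$statistic, 0)
    expect_equal(mw$pValue, 0.1)
    expect_identical(mw$method, "exact")
    # identical samples: center of the null, p = 1
    same <- mannWhitney(c(1, 2, 3), c(1, 2, 3))
    expect_equal(same$statistic, 4.5)
    expect_equal(same$pValue, 1)
    # exact p equals full enumeration for all small no-tie inputs
    set.seed(41)
    for (i in 1:8) {
        n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
        v <- sample(100, n1 + n2)       # distinct values, no ties
        x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
        expect_equal(mannWhitney(x, y)$pValue, mwExactOracle(x, y),
                     tolerance = 1e-12)
    }
    # strongly shifted large samples are overwhelmingly significant
    set.seed(42)
    big <- mannWhitney(rnorm(60), rnorm(60) + 3)
    expect_lt(big$pValue, 1e-6)
    # agreement with the base-R reference in the normal regime
    x <- rnorm(30); y <- rnorm(25) + 0.8
    expect_equal(mannWhitney(x, y)$pValue,
                 wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-10)
    expect_error(mannWhitney(numeric(0), 1), "non-empty")
})

test_that("Kruskal-Wallis reproduces the hand-computed H and degenerates", {
    kw <- kruskalWallis(list(c(1, 2), c(3, 4), c(5, 6)))
    expect_equal(kw$statistic, 32 / 7, tolerance = 1e-12)
    expect_equal(kw$df, 2)
    ident <- kruskalWallis(list(c(2, 2), c(2, 2)))
    expect_equal(ident$statistic, 0)
    expect_equal(ident$pValue, 1)
    # two-group KW orders like the Mann-Whitney normal approximation
    set.seed(43)
    x <- rnorm(20); y <- rnorm(20) + 1
    expect_lt(kruskalWallis(list(x, y))$pValue, 0.05)
    expect_lt(mannWhitney(x, y)$pValue, 0.05)
    expect_error(kruskalWallis(list(1:3)), "two non-empty")
})

test_that("Spearman correlation uses mid-ranks and a t approximation", {
    expect_equal(spearmanCor(1:5, (1:5)^2)$rho, 1)
    expect_equal(spearmanCor(1:5, -(1:5))$rho, -1)
    s <- spearmanCor(c(1, 2, 3, 4), c(2, 1, 4, 3))
    expect_equal(s$rho, 0.6)
    expect_equal(s$pValue,
                 cor.test(c(1, 2, 3, 4), c(2, 1, 4, 3), method = "spearman",
                          exact = FALSE)$p.value, tolerance = 1e-10)
    degen <- spearmanCor(c(1, 1, 1), c(1, 2, 3))
    expect_true(is.na(degen$rho))
    expect_identical(degen$reason, "zero rank variance")
    expect_error(spearmanCor(1:2, 1:2), "three complete")
})

test_that("median summaries follow the even-count rule", {
    expect_equal(medianAcrossCpgs(0.21), 0.21)
    expect_equal(medianAcrossCpgs(c(0.1, 0.2, 0.3)), 0.2)
    expect_equal(medianAcrossCpgs(c(0.1, 0.2, 0.3, 0.4)), 0.25)
})

test_that("ROC AUC equals the all-pairs oracle and the Mann-Whitney identity", {
    # perfect separation
    roc <- rocCurve(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T))
    expect_equal(roc@auc, 1)
    expect_equal(sensitivityAtSpecificity(roc, 0.95)$sensitivity, 1)
    # anti-perfect
    expect_equal(rocCurve(c(10, 11, 12, 1, 2, 3), c(F, F, F, T, T, T))@auc, 0)
    # random scores with ties: AUC equals brute-force pair counting
    set.seed(44)
    for (i in 1:3) {
        sc <- sample(seq(0, 1, by = 0.05), 100, replace = TRUE)
        lab <- rep(c(TRUE, FALSE), each = 50)
        roc <- rocCurve(sc, lab)
        expect_equal(roc@auc, aucOracle(sc, lab), tolerance = 1e-12)
        # cross-module identity: AUC = U / (n1 * n0)
        U <- mannWhitney(sc[lab], sc[!lab])$statistic
        expect_equal(roc@auc, U / (50 * 50), tolerance = 1e-12)
    }
    expect_error(rocCurve(1:5, rep(TRUE, 5)), "both classes")
})

test_that("ROC curve agrees with the pROC reference", {
    skip_if_not_installed("pROC")
    set.seed(45)
    sc <- c(rnorm(40, 1), rnorm(60))
    lab <- rep(c(TRUE, FALSE), c(40, 60))
    roc <- rocCurve(sc, lab)
    ref <- pROC::roc(response = lab, predictor = sc, quiet = TRUE,
                     direction = "<")
    expect_equal(roc@auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("sensitivity at preset specificity is monotone and degenerate-safe", {
    set.seed(46)
    sc <- c(rnorm(50, 1.2), rnorm(50))
    roc <- rocCurve(sc, rep(c(TRUE, FALSE), each = 50))
    # brute force over every threshold
    bruteSens <- function(target) {
        thr <- c(-Inf, sort(unique(sc)), Inf)
        best <- 0
        for (t in thr) {
            spec <- mean(sc[51:100] < t)
            if (spec >= target) best <- max(best, mean(sc[1:50] >= t))
        }
        best
    }
    for (tg in c(0.8, 0.9, 0.95, 0.99))
        expect_equal(sensitivityAtSpecificity(roc, tg)$sensitivity,
                     bruteSens(tg))
    sens <- vapply(c(0.5, 0.8, 0.9, 0.95, 0.99),
                   function(tg) sensitivityAtSpecificity(roc, tg)$sensitivity,
                   numeric(1))
    expect_true(all(diff(sens) <= 1e-12))
    # all-equal scores cannot reach 95% specificity with any sensitivity
    flat <- rocCurve(rep(0.3, 20), rep(c(TRUE, FALSE), 10))
    expect_equal(sensitivityAtSpecificity(flat, 0.95)$sensitivity, 0)
})

test_that("group comparison report recovers a planted shift and skips strata", {
    set.seed(47)
    n <- 40
    co <- data.frame(
        sampleId = paste0("s", 1:(5 * n)),
        cohortGroup = rep(c("UC", "PC", "RC", "PCt", "UCt"), each = n),
        gender = "male",
        age = 65, ucHistory = NA_character_, leukocytesPerUl = 100,
        stringsAsFactors = FALSE)
    co$ucHistory[co$cohortGroup == "UC"] <- "de_novo"
    base <- pmin(pmax(rnorm(5 * n, 0.1, 0.08), 0), 1)
    co$CpG_7 <- base + ifelse(co$cohortGroup == "UC", 0.26, 0)
    co$CpG_8 <- base + ifelse(co$cohortGroup == "UC", 0.26, 0) +
        rnorm(5 * n, 0, 0.02)
    rep1 <- groupComparisonReport(co)$male
    expect_true(all(rep1$pooled$pValue < 1e-4))
    expect_true(all(rep1$roc$auc > 0.8))
    expect_lt(abs(rep1$medians$pooledDiff - 0.26), 0.05)
    # non-UC groups are exchangeable here: Kruskal-Wallis stays quiet
    expect_true(all(rep1$kruskalNonUc$pValue > 0.01))
    # permuted labels give chance-level AUC
    set.seed(48)
    co2 <- co
    co2$cohortGroup <- sample(co2$cohortGroup)
    rep2 <- groupComparisonReport(co2)$male
    expect_lt(abs(median(rep2$roc$auc) - 0.5), 0.05)
    # a stratum lacking the UC class produces a skip record
    co3 <- co[co$cohortGroup != "UC", , drop = FALSE]
    co3$gender <- "female"
    rep3 <- groupComparisonReport(co3)$female
    expect_true(nrow(rep3$skipped) > 0)
    expect_true(any(grepl("empty", rep3$skipped$reason)))
    # high-missingness CpGs are dropped per stratum
    co4 <- co
    co4$CpG_13 <- NA_real_
    rep4 <- groupComparisonReport(co4)$male
    expect_identical(rep4$droppedCpgs, "CpG_13")
})
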