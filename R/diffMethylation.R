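#' Group-means design matrix
#'
#' Builds a cell-means (one indicator column per group) design matrix from a
#' sample-to-group assignment, the parameterization used throughout the
#' cell-culture analysis: each coefficient is a group mean on the M scale.
#'
#' @param groups character/factor vector of group labels, one per sample;
#'   names (if present) become the design rownames.
#' @return design matrix, samples x groups.
#' @examples
#' groupDesign(c(a = "x", b = "x", c = "y"))
#' @export
groupDesign <- function(groups) {
    f <- factor(groups)
    d <- model.matrix(~ 0 + f)
    colnames(d) <- levels(f)
    rownames(d) <- if (!is.null(names(groups))) names(groups)
                   else seq_along(groups)
    d
}

#' Build a contrast matrix over design coefficients
#'
#' Each contrast is given as \code{plus - minus} of coefficient (group)
#' names; \code{minus} groups may list several names, in which case their
#' mean is subtracted.
#'
#' @param design design matrix (for the coefficient names).
#' @param ... named contrasts; each value is a list/character vector
#'   \code{c(plus, minus...)}: the first element gets weight +1, the
#'   remaining elements share weight -1 equally.
#' @return coefficients x contrasts matrix.
#' @examples
#' d <- groupDesign(c("a", "a", "b", "c"))
#' makeContrasts2(d, aVsB = c("a", "b"), aVsRest = c("a", "b", "c"))
#' @export
makeContrasts2 <- function(design, ...) {
    if (!is.matrix(design))
        stop("'design' must be a design matrix; note that contrast names ",
             "that are a prefix of 'design' (e.g. 'd') would partially ",
             "match the first argument - use longer names")
    specs <- list(...)
    cm <- matrix(0, ncol(design), length(specs),
                 dimnames = list(colnames(design), names(specs)))
    for (i in seq_along(specs)) {
        s <- specs[[i]]
        if (!all(s %in% colnames(design)))
            stop("unknown coefficient(s): ",
                 paste(setdiff(s, colnames(design)), collapse = ", "))
        cm[s[1L], i] <- 1
        minus <- s[-1L]
        cm[minus, i] <- cm[minus, i] - 1 / length(minus)
    }
    cm
}

#' Per-site ordinary least squares on M-values
#'
#' Fits the same design matrix to every methylation site by OLS. Sites with
#' missing values in any used sample are dropped (recorded in the returned
#' object's \code{droppedSites} attribute) because a per-site design would
#' otherwise differ between sites.
#'
#' @param m M-value matrix (sites x samples) or a [MethylationSet-class]
#'   (then M-values are computed via [mValues()]).
#' @param design samples x coefficients design matrix of full column rank,
#'   e.g. from [groupDesign()].
#' @return a [MethylFit-class].
#' @export
fitLinearModel <- function(m, design) {
    if (is(m, "MethylationSet")) m <- mValues(m)
    m <- as.matrix(m)
    design <- as.matrix(design)
    if (ncol(m) != nrow(design))
        stop("design rows must match the number of samples")
    qrX <- qr(design)
    if (qrX$rank < ncol(design)) {
        aliased <- colnames(design)[qrX$pivot[(qrX$rank + 1L):ncol(design)]]
        stop("design is rank deficient; aliased column(s): ",
             paste(aliased, collapse = ", "))
    }
    keep <- rowSums(is.na(m)) == 0L
    dropped <- rownames(m)[!keep]
    if (length(dropped) > 0L)
        warning(length(dropped), " site(s) with missing values dropped")
    m <- m[keep, , drop = FALSE]
    if (nrow(m) == 0L) stop("no complete sites to fit")

    n <- nrow(design); p <- ncol(design)
    B <- qr.coef(qrX, t(m))                       # p x sites
    fitted <- design %*% B
    res <- t(m) - fitted
    df <- n - p
    sigma2 <- if (df > 0) colSums(res^2) / df else rep(NA_real_, ncol(res))
    covUn <- chol2inv(qr.R(qrX))
    # undo the QR pivot so rows/cols follow the design's column order
    piv <- qrX$pivot
    covUn[piv, piv] <- covUn
    dimnames(covUn) <- list(colnames(design), colnames(design))
    fit <- new("MethylFit",
               coefficients = t(B),
               covUnscaled  = covUn,
               sigma2       = unname(sigma2),
               df           = df,
               design       = design)
    attr(fit, "droppedSites") <- dropped
    fit
}

#' Apply a contrast matrix to a fitted model
#'
#' Re-expresses the fit in terms of contrasts: estimates become
#' \eqn{C^T \hat\beta} and the unscaled covariance becomes
#' \eqn{C^T (X^T X)^{-1} C}.
#'
#' @param fit a [MethylFit-class] from [fitLinearModel()].
#' @param contrasts coefficients x contrasts numeric matrix (a plain vector
#'   is treated as a single contrast).
#' @return a [MethylFit-class] on the contrast scale.
#' @export
applyContrasts <- function(fit, contrasts) {
    if (is.null(dim(contrasts)))
        contrasts <- matrix(contrasts, ncol = 1L,
                            dimnames = list(names(contrasts), "contrast"))
    contrasts <- as.matrix(contrasts)
    if (nrow(contrasts) != ncol(fit@coefficients))
        stop("contrast rows (", nrow(contrasts),
             ") must match fit coefficients (", ncol(fit@coefficients), ")")
    new("MethylFit",
        coefficients = fit@coefficients %*% contrasts,
        covUnscaled  = t(contrasts) %*% fit@covUnscaled %*% contrasts,
        sigma2       = fit@sigma2,
        df           = fit@df,
        design       = fit@design)
}

# Newton inversion of the trigamma function (x = trigamma(y), solve for y).
# Monotone decreasing; convergence is quadratic from y = 0.5 + 1/x.
trigammaInverse <- function(x) {
    out <- x
    lo <- x < 1e-7; hi <- x > 1e7
    out[lo] <- 1 / sqrt(x[lo])
    out[hi] <- 1 / x[hi]
    mid <- !(lo | hi) & !is.na(x)
    if (any(mid)) {
        y <- 0.5 + 1 / x[mid]
        for (i in 1:50) {
            tri <- trigamma(y)
            dif <- tri * (1 - tri / x[mid]) / psigamma(y, deriv = 2L)
            y <- y + dif
            if (max(-dif / y) < 1e-8) break
        }
        out[mid] <- y
    }
    out
}

#' Empirical-Bayes moderation of per-site variances
#'
#' Shrinks the per-site residual variances toward a common prior using the
#' scaled inverse-chi-square hierarchical model: the prior parameters
#' (\code{d0}, \code{s02}) are estimated by method of moments on
#' \eqn{\log s^2} (digamma/trigamma inversion), the posterior variance is
#' \eqn{\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)}, and moderated
#' t-statistics use \eqn{d_0 + d} degrees of freedom. Raw p-values are
#' two-sided; adjusted p-values (\code{qValue}) are Benjamini-Hochberg per
#' contrast column.
#'
#' @param fit a [MethylFit-class] (typically after [applyContrasts()]).
#' @param priorDf override the estimated prior degrees of freedom; use
#'   \code{0} for ordinary (unmoderated) t-statistics.
#' @param d0Cap cap for the prior df when the variances are essentially
#'   constant and the trigamma inversion diverges (default 1e6).
#' @return a [ModeratedFit-class].
#' @export
eBayesModerate <- function(fit, priorDf = NULL, d0Cap = 1e6) {
    s2 <- fit@sigma2
    d <- fit@df
    if (d <= 0) stop("no residual degrees of freedom")
    if (all(s2 == 0, na.rm = TRUE))
        stop("all residual variances are zero")
    if (sum(!is.na(s2)) < 2L)
        stop("at least two sites required to estimate the variance prior")

    if (is.null(priorDf)) {
        pos <- s2[!is.na(s2) & s2 > 0]
        z <- log(pos)
        e <- z - digamma(d / 2) + log(d / 2)
        emean <- mean(e)
        n <- length(e)
        evar <- mean((e - emean)^2) * n / (n - 1) - trigamma(d / 2)
        if (is.finite(evar) && evar > 0) {
            d0 <- 2 * trigammaInverse(evar)
            if (!is.finite(d0) || d0 > d0Cap) d0 <- d0Cap
            s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
        } else {
            # essentially constant variances: infinite-prior limit, the
            # prior collapses onto the (geometric-mean) common variance
            d0 <- d0Cap
            s02 <- exp(mean(z))
        }
    } else {
        if (priorDf < 0) stop("'priorDf' must be nonnegative")
        d0 <- min(priorDf, d0Cap)
        pos <- s2[!is.na(s2) & s2 > 0]
        s02 <- if (d0 > 0) exp(mean(log(pos))) else NA_real_
    }

    s2post <- if (d0 > 0) (d0 * s02 + d * s2) / (d0 + d) else s2
    dfTotal <- d0 + d
    sdUn <- sqrt(diag(fit@covUnscaled))
    tstat <- fit@coefficients / (rep(sdUn, each = nrow(fit@coefficients)) *
                                 sqrt(s2post))
    pval <- 2 * pt(-abs(tstat), df = dfTotal)
    qval <- apply(pval, 2L, bhAdjust)
    dim(qval) <- dim(pval); dimnames(qval) <- dimnames(pval)
    new("ModeratedFit", fit,
        d0 = d0, s02 = if (is.na(s02)) mean(s2, na.rm = TRUE) else s02,
        s2Post = s2post, dfTotal = dfTotal,
        tStat = tstat, pValue = pval, qValue = qval)
}

#' Moderated F-statistic over a set of contrasts
#'
#' For each site, tests whether any contrast in the subset is nonzero:
#' \deqn{F = \hat c^T V^{-1} \hat c / (r \tilde s^2)}
#' with \eqn{V} the unscaled covariance of the \eqn{r} contrast estimates.
#' For a single contrast this reduces to the squared moderated t.
#'
#' @param mod a [ModeratedFit-class].
#' @param contrasts contrast column names or indices (default: all).
#' @return data.frame with columns \code{F} and \code{pValue}, rownames the
#'   site ids.
#' @export
moderatedF <- function(mod, contrasts = NULL) {
    if (is.null(contrasts)) contrasts <- seq_len(ncol(mod@coefficients))
    b <- mod@coefficients[, contrasts, drop = FALSE]
    if (ncol(b) == 0L) stop("empty contrast subset")
    V <- mod@covUnscaled[contrasts, contrasts, drop = FALSE]
    Vi <- solve(V)
    r <- ncol(b)
    quad <- rowSums((b %*% Vi) * b)
    Fstat <- quad / (r * mod@s2Post)
    p <- pf(Fstat, r, mod@dfTotal, lower.tail = FALSE)
    data.frame(F = Fstat, pValue = p, row.names = rownames(b))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment,
#' \eqn{q_i = \min_{j: p_j \ge p_i} m p_j / \mathrm{rank}_j}, capped at 1.
#' Thin wrapper over \code{stats::p.adjust(method = "BH")}.
#'
#' @param p p-values in \[0,1\] (NA allowed).
#' @return adjusted p-values (q-values).
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Decision matrix from a moderated fit
#'
#' Classifies every (site, contrast) pair as +1 (significantly up at the
#' BH-adjusted threshold), -1 (significantly down) or 0.
#'
#' @param mod a [ModeratedFit-class].
#' @param alpha significance threshold on the adjusted p-value (default
#'   0.05).
#' @return integer matrix in \{-1, 0, +1\}, sites x contrasts.
#' @export
decisionMatrix <- function(mod, alpha = 0.05) {
    d <- sign(mod@coefficients) * (mod@qValue < alpha)
    storage.mode(d) <- "integer"
    d
}

#' Average beta difference, cancer minus primary
#'
#' Mean beta across the cancer cell-line replicates minus the beta of the
#' primary culture. Positive values mean hypermethylation in cancer (note
#' the sign convention: cancer - primary).
#'
#' @param beta beta matrix or [MethylationSet-class].
#' @param cancerSamples column ids of the cancer cell lines.
#' @param primarySample column id of the primary culture.
#' @return named per-site numeric vector; sites with missing values give
#'   \code{NA}.
#' @export
deltaBeta <- function(beta, cancerSamples, primarySample) {
    b <- betaValues(beta)
    miss <- setdiff(c(cancerSamples, primarySample), colnames(b))
    if (length(miss) > 0L)
        stop("sample(s) not present: ", paste(miss, collapse = ", "))
    rowMeans(b[, cancerSamples, drop = FALSE]) - b[, primarySample]
}
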