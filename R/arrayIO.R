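#' Beta values from methylated/unmethylated intensities
#'
#' \deqn{\beta = M / (M + U + \alpha)}
#' where \code{M} and \code{U} are the methylated and unmethylated probe
#' intensities and \code{alpha} a small regularizing offset (platform
#' convention 100). When \code{M + U + alpha == 0} the beta value is defined
#' as 0.
#'
#' @param meth,unmeth nonnegative intensity vectors/matrices (same shape).
#' @param alpha nonnegative offset added to the denominator (default 100).
#' @return beta values in \[0,1\], same shape as the inputs.
#' @examples
#' betaFromIntensities(900, 100)       # 0.8181...
#' betaFromIntensities(1000, 1000, 0)  # 0.5
#' @export
betaFromIntensities <- function(meth, unmeth, alpha = 100) {
    if (any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE))
        stop("intensities must be nonnegative")
    if (length(alpha) != 1L || alpha < 0)
        stop("'alpha' must be a single nonnegative number")
    denom <- meth + unmeth + alpha
    out <- ifelse(denom == 0, 0, meth / denom)
    dim(out) <- dim(meth)
    dimnames(out) <- dimnames(meth)
    out
}

#' Beta to M-value (logit-2)
#'
#' \deqn{M = \log_2(\beta' / (1 - \beta'))} with \eqn{\beta'} clamped to
#' \code{[epsilon, 1 - epsilon]} so that fully (un)methylated sites map to
#' large finite values.
#'
#' @param beta values in \[0,1\] (NA passed through).
#' @param epsilon boundary clamp, small positive (default 1e-6).
#' @return M-values, same shape as input.
#' @examples
#' betaToM(0.5)  # 0
#' betaToM(0.8)  # 2
#' @export
betaToM <- function(beta, epsilon = 1e-6) {
    if (any(beta < 0 | beta > 1, na.rm = TRUE))
        stop("beta values must lie in [0, 1]")
    if (length(epsilon) != 1L || epsilon <= 0 || epsilon >= 0.5)
        stop("'epsilon' must be in (0, 0.5)")
    b <- pmin(pmax(beta, epsilon), 1 - epsilon)
    out <- log2(b / (1 - b))
    dim(out) <- dim(beta)
    dimnames(out) <- dimnames(beta)
    out
}

#' M-value to beta (inverse logit-2)
#'
#' @param m finite M-values (NA passed through).
#' @return beta values in (0,1), same shape as input.
#' @examples
#' mToBeta(0)   # 0.5
#' mToBeta(2)   # 0.8
#' mToBeta(-2)  # 0.2
#' @export
mToBeta <- function(m) {
    out <- 1 / (1 + 2^(-m))
    dim(out) <- dim(m)
    dimnames(out) <- dimnames(m)
    out
}

#' Simple-scaling normalization of intensity matrices
#'
#' Rescales every sample (column) so that all sample means equal the grand
#' mean of the per-sample means: column j is multiplied by
#' \code{mean(colMeans(x)) / colMeans(x)[j]}. Idempotent; leaves already
#' equal-mean matrices unchanged.
#'
#' @param x nonnegative numeric matrix, samples in columns.
#' @return the rescaled matrix.
#' @export
simpleScalingNormalize <- function(x) {
    x <- as.matrix(x)
    if (any(x < 0, na.rm = TRUE))
        stop("intensities must be nonnegative")
    if (ncol(x) < 1L)
        stop("at least one sample required")
    cm <- colMeans(x, na.rm = TRUE)
    if (any(cm == 0))
        stop("all-zero sample(s): ",
             paste(colnames(x)[cm == 0], collapse = ", "))
    sweep(x, 2L, mean(cm) / cm, "*")
}

#' Read a beta-value table
#'
#' Reads a tab-separated sites x samples table (first column CpG ids, header
#' row sample ids, \code{NA} for missing). Lines starting with \code{!}
#' (GEO series-matrix-style metadata) are skipped.
#'
#' @param path file path.
#' @param manifest,sampleInfo optional annotation passed to
#'   [MethylationSet()].
#' @return a [MethylationSet-class].
#' @seealso [writeBetaTable()]
#' @export
readBetaTable <- function(path, manifest = NULL, sampleInfo = NULL) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "!")]
    lines <- lines[nzchar(lines)]
    tab <- read.delim(text = lines, header = TRUE, sep = "\t",
                      check.names = FALSE, colClasses = "character")
    ids <- tab[[1L]]
    if (anyDuplicated(ids))
        stop("duplicate site ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    if (anyDuplicated(names(tab)[-1L]))
        stop("duplicate sample ids: ",
             paste(unique(names(tab)[-1L][duplicated(names(tab)[-1L])]),
                   collapse = ", "))
    vals <- as.matrix(tab[, -1L, drop = FALSE])
    suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
    bad <- which(is.na(num) & !is.na(vals) & vals != "", arr.ind = TRUE)
    if (nrow(bad) > 0L)
        stop(sprintf("non-numeric cell at row '%s', column '%s'",
                     ids[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]]))
    dimnames(num) <- list(ids, colnames(vals))
    MethylationSet(num, manifest = manifest, sampleInfo = sampleInfo)
}

#' Write a beta-value table
#'
#' Tab-separated, \code{NA} for missing; loses no precision (values written
#' with full double precision). Round-trips through [readBetaTable()].
#'
#' @param x a [MethylationSet-class] or numeric matrix with dimnames.
#' @param path output file path.
#' @param idColumn name for the leading id column (default \code{"cpg_id"}).
#' @return invisibly, the path.
#' @export
writeBetaTable <- function(x, path, idColumn = "cpg_id") {
    b <- betaValues(x)
    df <- data.frame(id = rownames(b),
                     format(b, digits = 17, trim = TRUE, scientific = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(df)[1L] <- idColumn
    df[-1L][is.na(b)] <- "NA"
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a CpG manifest
#'
#' Tab-separated manifest with columns \code{cpg_id}, \code{chrom},
#' \code{pos} (1-based), \code{strand}, \code{gene}. Coordinates are
#' interpreted against the genome build the caller records (hg19 by
#' convention here).
#'
#' @param path file path.
#' @return a \code{GRanges} named by CpG id with a \code{gene} metadata
#'   column.
#' @export
readManifest <- function(path) {
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    need <- c("cpg_id", "chrom", "pos")
    if (!all(need %in% names(tab)))
        stop("manifest must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(tab$cpg_id))
        stop("duplicate cpg_id in manifest")
    if (any(tab$pos < 1))
        stop("manifest positions must be >= 1 (1-based)")
    gr <- GRanges(tab$chrom, IRanges(tab$pos, width = 1L),
                  strand = if ("strand" %in% names(tab)) tab$strand else "*")
    names(gr) <- tab$cpg_id
    gr$gene <- if ("gene" %in% names(tab)) tab$gene else NA_character_
    gr
}
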