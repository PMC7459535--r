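#' Extract beta values
#'
#' @param x a [MethylationSet-class] or numeric matrix.
#' @return numeric matrix of methylation fractions (sites x samples).
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' Extract M-values
#'
#' Logit-2 transform of the beta values; see [betaToM()] for the clamping
#' rule at the boundaries.
#'
#' @param x a [MethylationSet-class] or numeric matrix of beta values.
#' @param epsilon clamp applied to beta before the log-ratio (default 1e-6).
#' @return numeric matrix of M-values.
#' @export
setGeneric("mValues", function(x, epsilon = 1e-6) standardGeneric("mValues"))

#' @rdname betaValues
#' @export
setMethod("betaValues", "MethylationSet", function(x) assay(x, "beta"))

#' @rdname betaValues
#' @export
setMethod("betaValues", "matrix", function(x) x)

#' @rdname mValues
#' @export
setMethod("mValues", "MethylationSet", function(x, epsilon = 1e-6)
    betaToM(assay(x, "beta"), epsilon = epsilon))

#' @rdname mValues
#' @export
setMethod("mValues", "matrix", function(x, epsilon = 1e-6)
    betaToM(x, epsilon = epsilon))
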