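# Average ribonucleotide-monophosphate masses (Da) for the simplified
# EpiTYPER mass model. Methylation of a CpG substitutes G for A in the
# reverse-strand transcript: +16.00 Da per methylated CpG.
RNA_BASE_MASS <- c(A = 329.21, C = 305.18, G = 345.21, U = 306.17)
TERMINAL_WATER_DA <- 18.02
METHYL_SHIFT_DA <- 16.00

#' In-silico bisulfite conversion
#'
#' Converts every cytosine not followed by guanine to thymine; CpG
#' cytosines stay variable (unmethylated C reads as T, methylated as C)
#' and are encoded as the IUPAC symbol \code{Y}. Minus-strand conversion is
#' performed by reverse-complementing, converting, and reverse-complementing
#' back (CpG positions then carry \code{R}).
#'
#' @param sequence character string over A/C/G/T.
#' @param strand \code{"+"} (default) or \code{"-"}.
#' @return converted sequence with variable CpG positions marked.
#' @examples
#' bisulfiteConvert("ACGT")  # "AYGT"
#' bisulfiteConvert("ACCT")  # "ATTT"
#' @export
bisulfiteConvert <- function(sequence, strand = c("+", "-")) {
    strand <- match.arg(strand)
    if (grepl("[^ACGT]", sequence))
        stop("sequence must contain only A/C/G/T")
    if (strand == "-") {
        rc <- as.character(reverseComplement(DNAString(sequence)))
        conv <- bisulfiteConvert(rc, "+")
        return(as.character(reverseComplement(DNAString(conv))))
    }
    chars <- strsplit(sequence, "")[[1]]
    isC <- chars == "C"
    nextG <- c(chars[-1] == "G", FALSE)
    chars[isC & nextG] <- "Y"
    chars[isC & !nextG] <- "T"
    paste(chars, collapse = "")
}

# uppercase core of a tagged primer (tags are lowercase by convention)
.primerCore <- function(primer) gsub("[a-z]", "", primer)

# match a concrete primer core against a converted template; Y in the
# subject matches C or T (IUPAC semantics via fixed = FALSE)
.matchCore <- function(core, subject, what) {
    hits <- matchPattern(DNAString(core), DNAString(subject), fixed = FALSE)
    if (length(hits) == 0L)
        stop(what, " primer core '", core,
             "' not found in the converted template")
    if (length(hits) > 1L)
        stop(what, " primer core matches at multiple positions: ",
             paste(BiocGenerics::start(hits), collapse = ", "))
    c(BiocGenerics::start(hits), BiocGenerics::end(hits))
}

#' Build an EpiTYPER amplicon from a template and tagged primers
#'
#' The forward primer core (uppercase part) is matched against the
#' bisulfite-converted plus strand, the reverse primer core against its
#' reverse complement; the lowercase tag prefixes never take part in
#' matching. Variable \code{Y} positions in the converted template match
#' either C or T in a primer.
#'
#' @param template genomic template sequence (A/C/G/T), plus strand.
#' @param fwdPrimer,revPrimer tagged primer sequences; lowercase prefix =
#'   tag, uppercase = annealing core.
#' @param chrom,genomicStart optional genomic anchoring of template
#'   position 1 (1-based).
#' @return an [Amplicon-class].
#' @export
buildAmplicon <- function(template, fwdPrimer, revPrimer,
                          chrom = NA_character_, genomicStart = NA_real_) {
    converted <- bisulfiteConvert(template, "+")
    fwdCore <- .primerCore(fwdPrimer)
    revCore <- .primerCore(revPrimer)
    f <- .matchCore(fwdCore, converted, "forward")
    revQuery <- as.character(reverseComplement(DNAString(revCore)))
    r <- .matchCore(revQuery, converted, "reverse")
    if (r[1] <= f[2])
        stop("reverse primer site does not lie downstream of the forward site")
    ampStart <- f[1]; ampEnd <- r[2]
    ampSeq <- substr(converted, ampStart, ampEnd)
    cpgPos <- which(strsplit(ampSeq, "")[[1]] == "Y")
    new("Amplicon",
        chrom = chrom, genomicStart = genomicStart,
        template = template, converted = converted,
        ampStart = as.integer(ampStart), ampEnd = as.integer(ampEnd),
        ampSeq = ampSeq, cpgPos = as.integer(cpgPos),
        fwdPrimer = fwdPrimer, revPrimer = revPrimer)
}

#' Base-specific cleavage of the reverse-strand transcript
#'
#' Generates the reverse-strand RNA transcript of the amplicon (as primed
#' by the tagged reverse primer) and cleaves it after every U (T reaction)
#' or every C (C reaction). Variable CpG positions appear as \code{R} in the
#' transcript (A if unmethylated, G if methylated), so the cleavage pattern
#' does not depend on methylation state. Fragments tile the transcript;
#' each carries the indices (forward amplicon numbering, 1..K) of the CpGs
#' it contains.
#'
#' @param amplicon an [Amplicon-class].
#' @param reaction \code{"T"} (default) or \code{"C"}.
#' @return data.frame with columns \code{fragment} (RNA sequence, R at CpG
#'   positions), \code{start} (1-based within transcript), \code{nCpG},
#'   \code{cpgIndices} (list column) and \code{baseMass} (all CpGs
#'   unmethylated, Da).
#' @export
cleaveTranscript <- function(amplicon, reaction = c("T", "C")) {
    reaction <- match.arg(reaction)
    ampLen <- nchar(amplicon@ampSeq)
    rcDna <- as.character(reverseComplement(DNAString(amplicon@ampSeq)))
    transcript <- chartr("T", "U", rcDna)       # Y -> R under revcomp
    chars <- strsplit(transcript, "")[[1]]
    cutBase <- if (reaction == "T") "U" else "C"
    cuts <- which(chars == cutBase)
    bounds <- unique(c(0L, cuts, length(chars)))
    starts <- head(bounds, -1L) + 1L
    ends <- bounds[-1L]
    # map transcript position i -> amplicon position ampLen - i + 1;
    # CpG k sits at amplicon position cpgPos[k], i.e. transcript R at
    # position ampLen - cpgPos[k] + 1
    rPosToIndex <- setNames(seq_along(amplicon@cpgPos),
                            ampLen - amplicon@cpgPos + 1L)
    frags <- character(length(starts))
    idxList <- vector("list", length(starts))
    for (i in seq_along(starts)) {
        frags[i] <- substr(transcript, starts[i], ends[i])
        rpos <- starts[i]:ends[i]
        rpos <- rpos[chars[rpos] == "R"]
        idx <- sort(unname(rPosToIndex[as.character(rpos)]))
        idxList[[i]] <- as.integer(idx)
    }
    data.frame(fragment = frags, start = starts,
               nCpG = lengths(idxList),
               cpgIndices = I(idxList),
               baseMass = vapply(frags, fragmentMass, numeric(1),
                                 USE.NAMES = FALSE),
               stringsAsFactors = FALSE)
}

#' Mass of a cleavage fragment
#'
#' Sum of average ribonucleotide-monophosphate masses (A 329.21, C 305.18,
#' G 345.21, U 306.17 Da) plus 18.02 Da terminal water, plus 16.00 Da per
#' methylated CpG. Variable \code{R} positions count as A (the unmethylated
#' base); methylation is added through \code{nMethylated}.
#'
#' @param fragment RNA fragment sequence (A/C/G/U, R for variable CpG
#'   positions).
#' @param nMethylated number of methylated CpGs on the fragment (default 0).
#' @return mass in Da.
#' @examples
#' fragmentMass("AU")  # 653.40
#' @export
fragmentMass <- function(fragment, nMethylated = 0) {
    if (nchar(fragment) == 0L) stop("empty fragment")
    if (nMethylated < 0) stop("'nMethylated' must be nonnegative")
    chars <- strsplit(fragment, "")[[1]]
    nVar <- sum(chars == "R")
    if (nMethylated > nVar && nVar > 0)
        stop("more methylated CpGs than CpG positions on the fragment")
    chars[chars == "R"] <- "A"
    if (any(!chars %in% names(RNA_BASE_MASS)))
        stop("fragment must contain only A/C/G/U/R")
    sum(RNA_BASE_MASS[chars]) + TERMINAL_WATER_DA +
        METHYL_SHIFT_DA * nMethylated
}

#' Group co-fragment CpGs into measurement units
#'
#' CpGs that share a cleavage fragment are quantified as one integrated
#' unit, labelled by their dot-joined ordinal indices (e.g. \code{"5.6"});
#' singleton CpGs form singleton units.
#'
#' @param fragments data.frame from [cleaveTranscript()].
#' @return data.frame with columns \code{unit}, \code{members} (list
#'   column of CpG indices) and \code{fragmentRow} (row index into
#'   \code{fragments}).
#' @export
assignUnits <- function(fragments) {
    has <- which(fragments$nCpG > 0L)
    units <- vapply(fragments$cpgIndices[has],
                    function(ix) paste(ix, collapse = "."), character(1))
    ord <- order(vapply(fragments$cpgIndices[has], min, integer(1)))
    data.frame(unit = units[ord],
               members = I(fragments$cpgIndices[has][ord]),
               fragmentRow = has[ord],
               stringsAsFactors = FALSE)
}

#' Mass-collision detection for CpG units
#'
#' A unit is unmeasurable when any of its informative masses (its
#' fragment's base mass plus any number of +16 Da methylation shifts) lies
#' within \code{massResolutionDa} of a mass producible by a different
#' fragment (in any of that fragment's methylation states).
#'
#' @param fragments data.frame from [cleaveTranscript()].
#' @param massResolutionDa minimal resolvable mass difference (default
#'   16.0, one methylation shift).
#' @return the unit table from [assignUnits()] extended with
#'   \code{measurable} and \code{conflictReason} columns.
#' @export
detectConflicts <- function(fragments, massResolutionDa = 16.0) {
    stateMasses <- lapply(seq_len(nrow(fragments)), function(i)
        fragments$baseMass[i] + METHYL_SHIFT_DA * (0:fragments$nCpG[i]))
    units <- assignUnits(fragments)
    measurable <- logical(nrow(units))
    reason <- rep(NA_character_, nrow(units))
    for (u in seq_len(nrow(units))) {
        i <- units$fragmentRow[u]
        conflict <- NA_integer_
        for (j in seq_len(nrow(fragments))) {
            if (j == i) next
            dmin <- min(abs(outer(stateMasses[[i]], stateMasses[[j]], "-")))
            if (dmin < massResolutionDa) { conflict <- j; break }
        }
        measurable[u] <- is.na(conflict)
        if (!is.na(conflict))
            reason[u] <- sprintf(
                "mass within %.2f Da of fragment at transcript position %d",
                massResolutionDa, fragments$start[conflict])
    }
    units$measurable <- measurable
    units$conflictReason <- reason
    units
}

#' Full in-silico EpiTYPER report for an amplicon
#'
#' Convenience wrapper: cleaves the reverse-strand transcript, groups CpGs
#' into units and flags mass collisions.
#'
#' @param amplicon an [Amplicon-class].
#' @param reaction cleavage reaction, \code{"T"} (default) or \code{"C"}.
#' @param massResolutionDa see [detectConflicts()].
#' @return list with \code{fragments} and \code{units}.
#' @export
epityperReport <- function(amplicon, reaction = "T", massResolutionDa = 16.0) {
    fragments <- cleaveTranscript(amplicon, reaction)
    units <- detectConflicts(fragments, massResolutionDa)
    list(fragments = fragments, units = units)
}
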