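# Shared fixtures and independent oracles used across the test files.

# A synthetic EpiTYPER template: forward/reverse annealing regions free of
# CpGs, then CpG motifs separated by A (which becomes U on the reverse
# transcript, so every A is a T-cleavage point). CpGs 5 and 6 sit 6 bp
# apart inside a stretch without A, so they share one cleavage fragment.
# Spacer lengths differ so the singleton fragments have distinct masses.
toyTemplate <- function(nCpg = 8L) {
    spacers <- c("TTCGT", "TTCGTT", "TTCGTTT", "TTTCGT")
    parts <- character(0)
    k <- 0L
    while (k < nCpg) {
        k <- k + 1L
        if (k == 5L && nCpg >= 6L) {
            parts <- c(parts, "A", "TTCGTTTTCGTT")  # CpGs 5 and 6, 6 bp apart
            k <- k + 1L
        } else {
            parts <- c(parts, "A", spacers[(k %% length(spacers)) + 1L])
        }
    }
    paste0("GGAATTGAGAAGG", paste(parts, collapse = ""), "A",
           "GGTAGGAGTTGG")
}

toyFwdPrimer <- function() "aggaagagagGGAATTGAGAAGG"
# reverse primer anneals to the converted plus strand: its core is the
# reverse complement of the template's 3' annealing region
toyRevPrimer <- function() "cagtaatacgactcactatagggagaaggctCCAACTCCTACC"

toyAmplicon <- function(nCpg = 8L)
    buildAmplicon(toyTemplate(nCpg), toyFwdPrimer(), toyRevPrimer())

# Brute-force OLS oracle via explicit normal equations
olsOracle <- function(y, X) {
    XtXi <- solve(t(X) %*% X)
    b <- XtXi %*% t(X) %*% y
    res <- y - X %*% b
    df <- nrow(X) - ncol(X)
    list(coef = drop(b), sigma2 = sum(res^2) / df, covUnscaled = XtXi,
         df = df)
}

# Naive O(m^2) Benjamini-Hochberg step-up definition
bhOracle <- function(p) {
    m <- length(p)
    q <- numeric(m)
    r <- rank(p, ties.method = "min")
    for (i in seq_len(m))
        q[i] <- min(1, min((m * p / rank(p, ties.method = "max"))[p >= p[i]]))
    q
}

# All-pairs AUC oracle (ties credited 0.5)
aucOracle <- function(scores, isCase) {
    cs <- scores[isCase]; ct <- scores[!isCase]
    tot <- 0
    for (a in cs) for (b in ct)
        tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
    tot / (length(cs) * length(ct))
}

# Exact two-sided Mann-Whitney p by enumeration of all label assignments
mwExactOracle <- function(x, y) {
    n1 <- length(x)
    vals <- c(x, y)
    N <- length(vals)
    uOf <- function(ix) {
        r <- rank(vals)
        sum(r[ix]) - n1 * (n1 + 1) / 2
    }
    u0 <- uOf(seq_len(n1))
    combs <- combn(N, n1)
    us <- apply(combs, 2L, uOf)
    mu <- n1 * (N - n1) / 2
    mean(abs(us - mu) >= abs(u0 - mu) - 1e-9)
}

# tiny cohort for filter tests
miniCohort <- function() {
    data.frame(
        sampleId = paste0("s", 1:10),
        cohortGroup = c("UC", "UC", "UC", "UC", "PC", "RC",
                        "PCt", "PCt", "UCt", "UCt"),
        gender = rep("male", 10),
        age = 60 + 1:10,
        ucHistory = c("de_novo", NA, "recurrent", "de_novo",
                      NA, NA, NA, NA, NA, NA),
        leukocytesPerUl = c(100, 50, 600, 200, 80, 450, 20, 700, 90, 110),
        CpG_7 = seq(0.05, 0.5, length.out = 10),
        stringsAsFactors = FALSE)
}
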