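## Shared fixture builders; every fixture is generated in code.

writeTsv <- function(df, path = tempfile(fileext = ".tsv")) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

## Direction vector helpers for the classifiers: direction of a vs b at
## a conventional "perfect power" rule used to build calls from true
## means (relative difference above tol is significant).
trueDirection <- function(a, b, tol = 1e-8) {
    ifelse(abs(a - b) <= tol * pmax(abs(a), abs(b), 1), "ns",
           ifelse(a > b, "up", "down"))
}

## Independent Benjamini-Hochberg implementation used as an oracle:
## literal step-up definition, no cummin trick.
bhBruteForce <- function(p) {
    n <- length(p)
    ord <- order(p)
    adj <- numeric(n)
    for (i in seq_len(n)) {
        r <- which(ord == i)  # rank of p[i]
        adj[i] <- min(vapply(r:n, function(j) p[ord[j]] * n / j, 0), 1)
    }
    adj
}

## Independent Fisher exact p by full hypergeometric enumeration over
## all 2x2 tables with the observed margins (two-sided, by pmf rule).
fisherBruteForce <- function(tab) {
    a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
    r1 <- a + b; c1 <- a + cc; n <- a + b + cc + d
    aRange <- max(0, r1 + c1 - n):min(r1, c1)
    pmf <- vapply(aRange, function(x)
        exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1)),
        0)
    pObs <- pmf[aRange == a]
    sum(pmf[pmf <= pObs * (1 + 1e-7)])
}

## Independent beta-binomial log-pmf via log-gamma identities.
bbLogPmfOracle <- function(k, n, b, phi) {
    a <- (0.5 + b) / phi
    be <- (0.5 - b) / phi
    lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1) +
        lgamma(k + a) + lgamma(n - k + be) - lgamma(n + a + be) +
        lgamma(a + be) - lgamma(a) - lgamma(be)
}
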