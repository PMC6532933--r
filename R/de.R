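## Differential-expression calls.
##
## The classification machinery only consumes three-state calls
## (up / down / ns), so the engine is pluggable: a built-in Welch test on
## log2 CPM, an import path for externally computed tables (e.g. edgeR
## output), and an exact binomial / paired surrogate for
## homeologue-specific expression.

.directionFromCall <- function(logFC, fdr, threshold) {
    ifelse(fdr < threshold, ifelse(logFC > 0, "up", "down"), "ns")
}

#' Test a two-group expression contrast
#'
#' Welch two-sample t-test per gene on `log2(CPM + pseudoCount)`,
#' Benjamini-Hochberg correction across genes, and a three-state
#' direction from the sign of the mean difference at the FDR threshold.
#' Genes with zero variance in both groups and equal means get `p = 1`
#' (no signal).
#'
#' @param norm CPM matrix (see [cpmNormalize()]).
#' @param groups group label per column.
#' @param groupA,groupB the contrast, reported as `A` vs `B` (positive
#'   logFC = higher in `A`).
#' @param fdrThreshold FDR below which a gene is called.
#' @param pseudoCount added before the log when the matrix may contain
#'   zeros; use 0 if a pseudo-count was already applied.
#' @return data.frame `gene`, `contrast`, `logFC`, `PValue`, `FDR`,
#'   `direction`.
#' @export
testContrast <- function(norm, groups, groupA, groupB, fdrThreshold = 0.05,
                         pseudoCount = 0) {
    groups <- as.character(groups)
    a <- norm[, groups == groupA, drop = FALSE]
    b <- norm[, groups == groupB, drop = FALSE]
    if (ncol(a) < 2 || ncol(b) < 2)
        stop("each group needs at least two samples")
    la <- log2(a + pseudoCount); lb <- log2(b + pseudoCount)
    ma <- rowMeans(la); mb <- rowMeans(lb)
    va <- apply(la, 1, var); vb <- apply(lb, 1, var)
    na <- ncol(a); nb <- ncol(b)
    se2 <- va / na + vb / nb
    diff <- ma - mb
    tstat <- diff / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
    p[se2 == 0 & diff == 0] <- 1
    p[se2 == 0 & diff != 0] <- 0
    fdr <- p.adjust(p, method = "BH")
    data.frame(gene = rownames(norm),
               contrast = paste0(groupA, ":", groupB),
               logFC = diff, PValue = p, FDR = fdr,
               direction = .directionFromCall(diff, fdr, fdrThreshold),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Import externally computed differential-expression calls
#'
#' Reads a TSV with columns `gene`, `contrast`, `logFC`, `PValue`,
#' `FDR`.  Directions are recomputed from the configured threshold, not
#' trusted from the file.
#'
#' @param path TSV file.
#' @param fdrThreshold threshold for the three-state direction.
#' @return data.frame in the same shape as [testContrast()].
#' @export
importCalls <- function(path, fdrThreshold = 0.05) {
    tab <- read.delim(path, check.names = FALSE)
    need <- c("gene", "contrast", "logFC", "PValue", "FDR")
    if (!all(need %in% colnames(tab)))
        stop("missing column(s): ",
             paste(setdiff(need, colnames(tab)), collapse = ", "))
    if (any(is.na(tab$FDR)) || any(tab$FDR < 0) || any(tab$FDR > 1))
        stop("FDR outside [0, 1]")
    tab$direction <- .directionFromCall(tab$logFC, tab$FDR, fdrThreshold)
    tab[c(need, "direction")]
}

#' Homeologue-specific expression test
#'
#' Tests each gene for unequal expression of its two homeologues.  In
#' `"per_sample"` mode each accession is tested separately by a two-sided
#' exact binomial test of the Co count against half the homeologue total
#' (genes with zero total in a sample are excluded for that sample); in
#' `"pooled"` mode a one-sample t-test is applied to the per-accession
#' `log2(co/cg)` ratios.  BH correction runs across genes (within sample
#' in per-sample mode).  This is a calibrated frequentist surrogate for
#' hierarchical Bayesian allelic-count models; externally computed calls
#' can be supplied via [importCalls()].
#'
#' @param phased a [PhasedCounts-class] of (scaled) homeologue counts.
#' @param mode `"per_sample"` or `"pooled"`.
#' @param fdrThreshold FDR for the direction call.
#' @param pseudoCount used for the pooled log-ratios.
#' @return data.frame `gene`, (`accession`,) `logFC` (log2 co/cg),
#'   `PValue`, `FDR`, `direction` (contrast `Cbp_Co:Cbp_Cg`).
#' @export
hseTest <- function(phased, mode = c("per_sample", "pooled"),
                    fdrThreshold = 0.05, pseudoCount = 1) {
    mode <- match.arg(mode)
    co <- coCounts(phased); cg <- cgCounts(phased)
    if (mode == "per_sample") {
        out <- lapply(colnames(co), function(acc) {
            x <- round(co[, acc]); y <- round(cg[, acc])
            ok <- !is.na(x) & !is.na(y) & (x + y) > 0
            p <- .binomTwoSided(x[ok], x[ok] + y[ok])
            fdr <- p.adjust(p, method = "BH")
            lfc <- log2((x[ok] + pseudoCount) / (y[ok] + pseudoCount))
            data.frame(gene = rownames(co)[ok], accession = acc,
                       logFC = lfc, PValue = p, FDR = fdr,
                       direction = .directionFromCall(lfc, fdr, fdrThreshold),
                       stringsAsFactors = FALSE, row.names = NULL)
        })
        res <- do.call(rbind, out)
    } else {
        lr <- log2((co + pseudoCount) / (cg + pseudoCount))
        nObs <- rowSums(!is.na(lr))
        mu <- rowMeans(lr, na.rm = TRUE)
        s <- apply(lr, 1, sd, na.rm = TRUE)
        tstat <- mu / (s / sqrt(nObs))
        p <- 2 * pt(abs(tstat), nObs - 1, lower.tail = FALSE)
        p[is.na(p) & nObs > 0 & s == 0 & mu == 0] <- 1
        ok <- nObs >= 2 & !is.na(p)
        fdr <- p.adjust(p[ok], method = "BH")
        res <- data.frame(gene = rownames(co)[ok], logFC = mu[ok],
                          PValue = p[ok], FDR = fdr,
                          direction = .directionFromCall(mu[ok], fdr,
                                                         fdrThreshold),
                          stringsAsFactors = FALSE, row.names = NULL)
    }
    res$contrast <- "Cbp_Co:Cbp_Cg"
    res
}
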