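## Normalization, homeologue-count scaling, mapping-bias filtering and
## silenced-gene summaries.

#' Counts-per-million normalization
#'
#' `value = (count + pseudoCount) / librarySize * 1e6`, with library
#' sizes taken from the raw counts.  With `pseudoCount = 0` every column
#' sums to 1e6 exactly (up to float tolerance); the default pseudo-count
#' of 1 keeps zero counts loggable downstream.
#'
#' @param counts an [ExpressionCounts-class] or a numeric matrix.
#' @param pseudoCount non-negative value added to every count.
#' @return Numeric matrix of CPM values with attributes `method` and
#'   `libSizes`.
#' @export
cpmNormalize <- function(counts, pseudoCount = 1) {
    m <- if (is(counts, "ExpressionCounts")) assay(counts, "counts")
         else as.matrix(counts)
    stopifnot(pseudoCount >= 0)
    lib <- colSums(m)
    if (any(lib == 0))
        stop("zero library size in sample(s): ",
             paste(colnames(m)[lib == 0], collapse = ", "))
    out <- sweep(m + pseudoCount, 2, lib, "/") * 1e6
    attr(out, "method") <- if (pseudoCount > 0) "cpm+pseudo" else "cpm"
    attr(out, "libSizes") <- lib
    out
}

#' Trimmed mean of M-values scaling factors
#'
#' Per-sample scaling factors computed against a reference sample by the
#' trimmed mean of M-values: genes with zero counts in either sample are
#' dropped, the log-ratios M are trimmed by 30% on each side, the
#' log-abundances A by 5% on each side, and the surviving M values are
#' averaged with inverse asymptotic-variance weights.  Factors are
#' renormalized to geometric mean 1.  The reference defaults to the
#' sample whose upper-quartile CPM is closest to the mean upper quartile.
#'
#' @param counts an [ExpressionCounts-class] or matrix (>= 2 samples).
#' @param referenceSample column name or index; `NULL` for automatic
#'   choice.
#' @param trimM,trimA two-sided trim fractions.
#' @return Named numeric vector of scaling factors.
#' @export
tmmFactors <- function(counts, referenceSample = NULL,
                       trimM = 0.3, trimA = 0.05) {
    m <- if (is(counts, "ExpressionCounts")) assay(counts, "counts")
         else as.matrix(counts)
    if (ncol(m) < 2) stop("TMM needs at least two samples")
    lib <- colSums(m)
    if (is.null(referenceSample)) {
        uq <- apply(sweep(m, 2, lib, "/"), 2, quantile, probs = 0.75)
        referenceSample <- which.min(abs(uq - mean(uq)))
    }
    r <- m[, referenceSample]
    Nr <- lib[referenceSample]
    f <- vapply(seq_len(ncol(m)), function(j) {
        x <- m[, j]; N <- lib[j]
        keep <- x > 0 & r > 0
        if (!any(keep))
            stop("sample ", colnames(m)[j],
                 " shares no co-expressed genes with the reference")
        x <- x[keep]; rr <- r[keep]
        M <- log2((x / N) / (rr / Nr))
        A <- 0.5 * log2((x / N) * (rr / Nr))
        w <- 1 / ((N - x) / (N * x) + (Nr - rr) / (Nr * rr))
        loM <- quantile(M, trimM); hiM <- quantile(M, 1 - trimM)
        loA <- quantile(A, trimA); hiA <- quantile(A, 1 - trimA)
        keep2 <- M >= loM & M <= hiM & A >= loA & A <= hiA
        if (!any(keep2)) return(1)
        2^(sum(M[keep2] * w[keep2]) / sum(w[keep2]))
    }, numeric(1))
    f <- f / exp(mean(log(f)))
    names(f) <- colnames(m)
    f
}

#' Scale homeologue counts by the unphased totals
#'
#' SNP-level phased counts are subject to uneven SNP density and
#' coverage along a gene; the total (unphased) count is not.  The phased
#' data therefore only contributes the allelic ratio:
#' `scaled_co = total * co/(co + cg)`, `scaled_cg = total - scaled_co`.
#' Totals are conserved exactly.  Gene/accession cells with a phased
#' ratio of 0/0 but a positive total are unphaseable and become `NA`
#' (reported via a message and the `"unphaseable"` attribute).
#'
#' @param total matrix (or [ExpressionCounts-class]) of unphased
#'   tetraploid counts, genes x accessions, aligned with `phased`.
#' @param phased a [PhasedCounts-class] of raw allelic counts.
#' @return A [PhasedCounts-class] with real-valued scaled counts.
#' @export
scaleHomeologCounts <- function(total, phased) {
    tm <- if (is(total, "ExpressionCounts")) assay(total, "counts")
          else as.matrix(total)
    co <- coCounts(phased); cg <- cgCounts(phased)
    genes <- intersect(rownames(tm), rownames(co))
    if (!length(genes)) stop("no genes shared between total and phased data")
    acc <- intersect(colnames(tm), colnames(co))
    if (!length(acc)) stop("no accessions shared between total and phased data")
    tm <- tm[genes, acc, drop = FALSE]
    co <- co[genes, acc, drop = FALSE]
    cg <- cg[genes, acc, drop = FALSE]
    tot <- co + cg
    ratio <- ifelse(tot > 0, co / tot, NA_real_)
    bad <- !is.na(tm) & tm > 0 & !is.na(tot) & tot == 0
    sco <- tm * ratio
    sco[!is.na(tm) & tm == 0] <- 0
    scg <- tm - sco
    if (any(bad, na.rm = TRUE))
        message(sum(bad), " gene/accession cell(s) unphaseable (phased 0/0 ",
                "with positive total); set to NA")
    out <- PhasedCounts(sco, scg)
    attr(out, "unphaseable") <- which(bad, arr.ind = TRUE)
    out
}

#' Normalize phased counts by the mean subgenome library size
#'
#' Both subgenomes of an accession are divided by the same denominator,
#' the mean of the two subgenome library sizes
#' `(lib_co + lib_cg) / 2`, so the within-accession homeologue ratio is
#' preserved while accessions become comparable.
#'
#' @param phased a [PhasedCounts-class].
#' @param pseudoCount added to each count before scaling.
#' @return List with matrices `co` and `cg` (per-million units) and the
#'   vector `denominator`.
#' @export
normalizePhased <- function(phased, pseudoCount = 1) {
    ls <- librarySizes(phased)
    denom <- colMeans(ls)
    if (any(denom == 0))
        stop("accession(s) with zero total phased counts: ",
             paste(colnames(ls)[denom == 0], collapse = ", "))
    list(co = sweep(coCounts(phased) + pseudoCount, 2, denom, "/") * 1e6,
         cg = sweep(cgCounts(phased) + pseudoCount, 2, denom, "/") * 1e6,
         denominator = denom)
}

## Exact two-sided binomial p-value against p = 0.5, vectorized.
## For the symmetric null the two-sided p is
## P(X <= min(k, n-k)) + P(X >= max(k, n-k)).
.binomTwoSided <- function(k, n) {
    lo <- pmin(k, n - k)
    hi <- n - lo
    p <- pbinom(lo, n, 0.5) + pbinom(hi - 1, n, 0.5, lower.tail = FALSE)
    pmin(p, 1)
}

#' Screen SNPs for mapping bias in DNA allelic counts
#'
#' Each SNP's genomic (DNA) allelic counts are tested against the fair
#' 0.5 ratio by a two-sided exact binomial test; Benjamini-Hochberg
#' correction is applied across SNPs and SNPs below the FDR threshold are
#' dropped, as are genes retaining no SNP.  Zero-depth SNPs are excluded
#' with a warning.  An externally computed keep list can be supplied
#' downstream instead; this filter is a calibrated per-SNP surrogate for
#' hierarchical allelic-count models.
#'
#' @param dnaCounts data.frame with columns `snp`, `gene`, `count_co`,
#'   `count_cg` (see [simulateDnaAllelicCounts()]).
#' @param fdr FDR threshold for dropping a SNP.
#' @return List: `snps` (input plus `p`, `fdr`, `keep`), `keptGenes`,
#'   `droppedGenes`.
#' @export
mappingBiasFilter <- function(dnaCounts, fdr = 0.05) {
    need <- c("snp", "gene", "count_co", "count_cg")
    stopifnot(all(need %in% colnames(dnaCounts)))
    n <- dnaCounts$count_co + dnaCounts$count_cg
    zero <- n == 0
    if (any(zero))
        warning(sum(zero), " SNP(s) with zero depth excluded")
    d <- dnaCounts[!zero, , drop = FALSE]
    d$p <- .binomTwoSided(d$count_co, d$count_co + d$count_cg)
    d$fdr <- p.adjust(d$p, method = "BH")
    d$keep <- d$fdr >= fdr
    keptGenes <- unique(d$gene[d$keep])
    droppedGenes <- setdiff(unique(dnaCounts$gene), keptGenes)
    list(snps = d, keptGenes = keptGenes, droppedGenes = droppedGenes)
}

#' Presence filter across populations/species
#'
#' A gene is kept only if every group has at least one sample with a
#' non-zero count.
#'
#' @param counts raw count matrix (or [ExpressionCounts-class]).
#' @param groups group label per column.
#' @return Named logical vector over genes.
#' @export
expressionPresenceFilter <- function(counts, groups) {
    m <- if (is(counts, "ExpressionCounts")) assay(counts, "counts")
         else as.matrix(counts)
    groups <- as.factor(groups)
    stopifnot(length(groups) == ncol(m))
    if (any(table(groups) == 0) || nlevels(groups) == 0)
        stop("empty group")
    keep <- rep(TRUE, nrow(m))
    for (g in levels(groups))
        keep <- keep & rowSums(m[, groups == g, drop = FALSE] > 0) > 0
    names(keep) <- rownames(m)
    keep
}

#' Count silenced genes per subgenome
#'
#' A gene is silenced on a subgenome when its raw count is zero in every
#' accession of that subgenome (`NA` cells ignored).
#'
#' @param phased a [PhasedCounts-class] of raw counts.
#' @return Named vector `c(co = , cg = )` of silenced-gene counts.
#' @export
silencedGeneCounts <- function(phased) {
    silent <- function(m) sum(rowSums(m > 0, na.rm = TRUE) == 0 &
                              rowSums(!is.na(m)) > 0)
    c(co = silent(coCounts(phased)), cg = silent(cgCounts(phased)))
}
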