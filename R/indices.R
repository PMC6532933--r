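## Similarity, dominance and convergence indices, their sign/correlation
## tests, and the spatial-clustering resampling test.
##
## All indices work on mean expression in natural CPM units; logs are
## never taken (the formulas use raw deviations and differences).

#' Similarity index S
#'
#' Oriented relative deviation of a subgenome's mean expression from the
#' parental midpoint `mu = (E_CO + E_CG)/2`:
#' `S = (E_sub - mu)/mu`, multiplied by -1 when `E_CG > E_CO` so that
#' `S < 0` always means CG-like and `S > 0` CO-like expression.  `S = 0`
#' at the parental midpoint.  Genes with `mu = 0` or with exactly equal
#' parental means (orientation undefined) return `NA`; the index is
#' intended for genes differentially expressed between the parents.
#'
#' @param eCO,eCG,eSub mean expression of the CO parent, the CG parent
#'   and one subgenome (vectors).
#' @return Numeric vector of S values.
#' @export
similarityIndex <- function(eCO, eCG, eSub) {
    mu <- (eCO + eCG) / 2
    s <- (eSub - mu) / mu
    s <- ifelse(eCG > eCO, -s, s) + 0  # + 0 normalizes IEEE negative zero
    s[mu == 0 | eCG == eCO] <- NA_real_
    s
}

#' Dominance score
#'
#' `Delta_S = |S_CbpCo| - |S_CbpCg|`: negative values indicate overall
#' dominance of the CG genetic background, positive values of CO.
#'
#' @param sCo,sCg similarity indices of the Co- and Cg-derived
#'   subgenomes.
#' @return Numeric vector.
#' @export
dominanceScore <- function(sCo, sCg) abs(sCo) - abs(sCg)

#' Convergence index C
#'
#' With `Delta_par = |E_CG - E_CO|` and a comparison-specific
#' `Delta_x`, `C = (Delta_par - Delta_x) / max(Delta_par, Delta_x)`,
#' bounded in \[-1, 1\].  `which = "Cbp"` uses
#' `Delta_sub = |E_subCg - E_subCo|` (overall convergence of the two
#' subgenomes); `"CbpCg"` uses `|E_subCg - E_CO|` (convergence of Cbp_Cg
#' towards the opposite parent); `"CbpCo"` uses `|E_subCo - E_CG|`.
#' Positive C means the subgenomes are closer than the parents.  Genes
#' with `Delta_par = Delta_x = 0` return `NA`.  Intended for genes
#' differentially expressed between the parents.
#'
#' @param eCO,eCG,eSubCo,eSubCg mean expression vectors.
#' @param which one of `"Cbp"`, `"CbpCg"`, `"CbpCo"`.
#' @return Numeric vector of C values.
#' @export
convergenceIndex <- function(eCO, eCG, eSubCo, eSubCg,
                             which = c("Cbp", "CbpCg", "CbpCo")) {
    which <- match.arg(which)
    dPar <- abs(eCG - eCO)
    dX <- switch(which,
                 Cbp = abs(eSubCg - eSubCo),
                 CbpCg = abs(eSubCg - eCO),
                 CbpCo = abs(eSubCo - eCG))
    denom <- pmax(dPar, dX)
    ifelse(denom > 0, (dPar - dX) / denom, NA_real_)
}

#' Sign-bias test of an index
#'
#' Two-sided exact binomial test of the number of positive against
#' negative values (zeros and `NA` dropped).
#'
#' @param s numeric vector of index values.
#' @return List: `nPos`, `nNeg`, `p`.
#' @export
signBiasTest <- function(s) {
    s <- s[!is.na(s) & s != 0]
    if (!length(s)) stop("no nonzero index values")
    nPos <- sum(s > 0); nNeg <- sum(s < 0)
    list(nPos = nPos, nNeg = nNeg,
         p = binom.test(nPos, nPos + nNeg)$p.value)
}

#' Spearman correlation between the subgenome similarity indices
#'
#' A positive correlation between `S_Cg` and `S_Co` indicates that the
#' two subgenomes are co-regulated in the same direction.
#'
#' @param sCg,sCo paired similarity-index vectors.
#' @return List: `rho`, `p`, `n`.
#' @export
indexCorrelation <- function(sCg, sCo) {
    ok <- complete.cases(sCg, sCo)
    sCg <- sCg[ok]; sCo <- sCo[ok]
    if (length(sCg) < 3) stop("need at least three paired values")
    if (sd(sCg) == 0 || sd(sCo) == 0) stop("constant index vector")
    ct <- suppressWarnings(cor.test(sCg, sCo, method = "spearman"))
    list(rho = unname(ct$estimate), p = ct$p.value, n = length(sCg))
}

#' Convergence summary with accession pairing modes
#'
#' Computes per-gene convergence indices from per-accession phased
#' expression and summarizes the fraction of converging genes.  Pairing
#' controls how the two subgenome expression values of a gene are
#' combined: `"mean_over_accessions"` averages each subgenome across all
#' accessions first (breaking the shared-cell-pool association);
#' `"same_individual"` computes C within each accession and averages the
#' per-accession indices; `"cross_individual"` pairs each accession's Cg
#' values with a circularly shifted accession's Co values, removing any
#' shared-individual effect.
#'
#' @param eCO,eCG parental mean expression vectors.
#' @param coMat,cgMat genes x accessions matrices of normalized phased
#'   expression.
#' @param pairing pairing mode.
#' @return List with `C` (data.frame of `C_Cbp`, `C_CbpCg`, `C_CbpCo`
#'   per gene), per-index fractions positive with binomial p-values
#'   (`summary`), and `rho` / `rhoP`, the Spearman correlation of
#'   `C_Cbp` with `Delta_par`.
#' @export
convergenceSummary <- function(eCO, eCG, coMat, cgMat,
                               pairing = c("mean_over_accessions",
                                           "same_individual",
                                           "cross_individual")) {
    pairing <- match.arg(pairing)
    if (nrow(coMat) < 10) stop("need at least 10 genes")
    idx <- function(co, cg)
        data.frame(C_Cbp = convergenceIndex(eCO, eCG, co, cg, "Cbp"),
                   C_CbpCg = convergenceIndex(eCO, eCG, co, cg, "CbpCg"),
                   C_CbpCo = convergenceIndex(eCO, eCG, co, cg, "CbpCo"))
    if (pairing == "mean_over_accessions") {
        C <- idx(rowMeans(coMat, na.rm = TRUE), rowMeans(cgMat, na.rm = TRUE))
    } else {
        shift <- if (pairing == "cross_individual") 1L else 0L
        acc <- seq_len(ncol(coMat))
        per <- lapply(acc, function(j) {
            jj <- ((j - 1L + shift) %% ncol(coMat)) + 1L
            idx(coMat[, jj], cgMat[, j])
        })
        C <- Reduce(`+`, per) / length(per)
    }
    summarize <- function(x) {
        x <- x[!is.na(x) & x != 0]
        if (length(unique(x)) < 2) stop("fewer than 2 distinct C values")
        list(fracPositive = mean(x > 0),
             p = binom.test(sum(x > 0), length(x))$p.value)
    }
    dPar <- abs(eCG - eCO)
    ok <- !is.na(C$C_Cbp)
    ct <- suppressWarnings(cor.test(C$C_Cbp[ok], dPar[ok],
                                    method = "spearman"))
    list(C = C,
         summary = lapply(C, summarize),
         rho = unname(ct$estimate), rhoP = ct$p.value, pairing = pairing)
}

#' Spatial clustering test of expression categories
#'
#' Tests, per scaffold and category, whether genes of a category sit
#' closer together along the scaffold than expected: distances (midpoint
#' to midpoint) of randomly sampled within-category gene pairs are
#' compared with distances of pairs straddling the category boundary by
#' a Wilcoxon-Mann-Whitney test.  Scaffolds with fewer than two
#' categories, or categories with fewer than two genes on a scaffold,
#' are skipped (logged via message).
#'
#' @param positions named [GenomicRanges::GRanges] of gene positions.
#' @param assignments data.frame `gene`, `category`.
#' @param nResamples pairs sampled per side, capped at the
#'   within-category gene count (so that no gene is reused often enough
#'   to distort the rank test's calibration).
#' @param seed integer seed for the resampling.
#' @return data.frame `scaffold`, `category`, `nGenes`, `p`.
#' @export
spatialClusteringTest <- function(positions, assignments, nResamples = 1000,
                                  seed = 1L) {
    set.seed(as.integer(seed))
    common <- intersect(names(positions), assignments$gene)
    positions <- positions[common]
    catOf <- setNames(assignments$category, assignments$gene)[common]
    midpt <- mid(GenomicRanges::ranges(positions))
    scaf <- as.character(seqnames(positions))
    rows <- list()
    for (sc in unique(scaf)) {
        i <- scaf == sc
        cats <- unique(catOf[i])
        if (length(cats) < 2 || sum(i) < 3) {
            message("scaffold ", sc, " skipped (needs >= 2 categories)")
            next
        }
        for (cc in cats) {
            within <- which(i & catOf == cc)
            other <- which(i & catOf != cc)
            if (length(within) < 2) {
                message("scaffold ", sc, ", category ", cc,
                        " skipped (< 2 genes)")
                next
            }
            ## cap at the category size: reusing each gene many times
            ## across pairs breaks the rank test's independence
            ## assumption and makes the null p anti-conservative
            nPairs <- min(nResamples, length(within),
                          length(within) * (length(within) - 1) / 2)
            wA <- sample(within, nPairs, replace = TRUE)
            wB <- sample(within, nPairs, replace = TRUE)
            fix <- wA == wB
            while (any(fix)) {
                wB[fix] <- sample(within, sum(fix), replace = TRUE)
                fix <- wA == wB
            }
            bA <- sample(within, nPairs, replace = TRUE)
            bB <- sample(other, nPairs, replace = TRUE)
            dW <- abs(midpt[wA] - midpt[wB])
            dB <- abs(midpt[bA] - midpt[bB])
            p <- suppressWarnings(wilcox.test(dW, dB)$p.value)
            rows[[length(rows) + 1]] <-
                data.frame(scaffold = sc, category = cc,
                           nGenes = length(within), p = p,
                           stringsAsFactors = FALSE)
        }
    }
    if (!length(rows))
        return(data.frame(scaffold = character(), category = character(),
                          nGenes = integer(), p = numeric()))
    do.call(rbind, rows)
}
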