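## Cis/trans decomposition by ratio regression.
##
## Under pure cis regulation each homeologue keeps its parental
## expression, so the subgenome log-ratio equals the parental log-ratio
## (slope 1); under complete cross trans-regulation the homeologues are
## equalized regardless of the parents (slope 0).  The observed slope of
## the OLS regression of one ratio on the other therefore measures the
## aggregate cis fraction of regulatory divergence.

#' Build parental / subgenome expression ratio pairs
#'
#' @param meanCG,meanCO,meanCg,meanCo per-gene mean expression (CPM) of
#'   the two parents and the two subgenomes.
#' @param pseudoCount added to each mean before the ratio.
#' @param scale `"log2"` (default) or `"natural"` (plain ratios).
#' @param gene optional gene ids.
#' @return data.frame `gene`, `parental`, `subgenome`; genes whose four
#'   means are all zero (ratio undefined at pseudo-count 0) are excluded
#'   with a message.
#' @export
buildRatioPairs <- function(meanCG, meanCO, meanCg, meanCo,
                            pseudoCount = 0, scale = c("log2", "natural"),
                            gene = NULL) {
    scale <- match.arg(scale)
    gene <- gene %||% seq_along(meanCG)
    ratio <- function(a, b) {
        r <- (a + pseudoCount) / (b + pseudoCount)
        if (scale == "log2") log2(r) else r
    }
    par <- ratio(meanCG, meanCO)
    sub <- ratio(meanCg, meanCo)
    ok <- is.finite(par) & is.finite(sub)
    if (any(!ok))
        message(sum(!ok), " gene(s) with undefined ratios excluded")
    data.frame(gene = gene[ok], parental = par[ok], subgenome = sub[ok],
               stringsAsFactors = FALSE)
}

#' Regress the subgenome ratio on the parental ratio
#'
#' Ordinary least squares of `subgenome ~ parental`; the slope reads as
#' the aggregate cis fraction (1 = pure cis, 0 = pure trans).  A
#' major-axis fit is available for sensitivity analyses.
#'
#' @param pairs output of [buildRatioPairs()].
#' @param subset optional logical or index vector (e.g. one expression
#'   category) applied to `pairs`.
#' @param method `"ols"` or `"major_axis"`.
#' @return List: `slope`, `intercept`, `p` (two-sided slope test, OLS
#'   only), `se` (slope standard error), `r2`, `n`, `method`.
#' @export
fitCisTrans <- function(pairs, subset = NULL, method = c("ols", "major_axis")) {
    method <- match.arg(method)
    if (!is.null(subset)) pairs <- pairs[subset, , drop = FALSE]
    if (nrow(pairs) < 3) stop("need at least three ratio pairs")
    if (var(pairs$parental) == 0) stop("zero variance in the parental ratio")
    if (method == "ols") {
        fit <- lm(subgenome ~ parental, data = pairs)
        sm <- summary(fit)$coefficients
        list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
             p = sm["parental", "Pr(>|t|)"], se = sm["parental", "Std. Error"],
             r2 = summary(fit)$r.squared, n = nrow(pairs), method = method)
    } else {
        ## major axis: first principal axis of the centered cloud
        vx <- var(pairs$parental); vy <- var(pairs$subgenome)
        cxy <- cov(pairs$parental, pairs$subgenome)
        slope <- (vy - vx + sqrt((vy - vx)^2 + 4 * cxy^2)) / (2 * cxy)
        list(slope = slope,
             intercept = mean(pairs$subgenome) - slope * mean(pairs$parental),
             p = NA_real_, se = NA_real_,
             r2 = cxy^2 / (vx * vy), n = nrow(pairs), method = method)
    }
}

#' Per-category cis/trans slopes
#'
#' @param pairs output of [buildRatioPairs()].
#' @param categories category label per row of `pairs`.
#' @param minGenes categories with fewer pairs are skipped.
#' @return data.frame `category`, `slope`, `se`, `p`, `r2`, `n`,
#'   including an `"all"` row.
#' @export
fitCisTransByCategory <- function(pairs, categories, minGenes = 3) {
    stopifnot(length(categories) == nrow(pairs))
    cats <- c("all", sort(unique(categories)))
    rows <- lapply(cats, function(cc) {
        idx <- if (cc == "all") rep(TRUE, nrow(pairs)) else categories == cc
        if (sum(idx) < minGenes || var(pairs$parental[idx]) == 0) return(NULL)
        f <- fitCisTrans(pairs, subset = idx)
        data.frame(category = cc, slope = f$slope, se = f$se, p = f$p,
                   r2 = f$r2, n = f$n, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Fisher variance test of ratio convergence
#'
#' Tests whether the variance of the subgenome expression ratio is
#' smaller than the variance of the parental ratio:
#' `F = var(parental) / var(subgenome)` with `(n-1, n-1)` degrees of
#' freedom, one-sided.
#'
#' @param pairs output of [buildRatioPairs()].
#' @return List: `F`, `df`, `p` (one-sided, large F = subgenomes closer
#'   than parents), `n`.
#' @export
varianceConvergenceTest <- function(pairs) {
    n <- nrow(pairs)
    if (n < 2) stop("need at least two ratio pairs")
    vp <- var(pairs$parental); vs <- var(pairs$subgenome)
    if (vp == 0 || vs == 0) stop("zero variance in a ratio")
    Fstat <- vp / vs
    list(F = Fstat, df = c(n - 1, n - 1),
         p = pf(Fstat, n - 1, n - 1, lower.tail = FALSE), n = n)
}

#' @importFrom stats cov
NULL
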