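## Association between mutation-load bias and homeologue expression
## bias.
##
## For gene i in accession j, d = DEL_Cg - DEL_Co is the deleterious
## bias between homeologues and e = E_Co / (E_Co + E_Cg) the Co share of
## homeologue expression.  Under the load hypothesis the copy with more
## deleterious mutations is expressed less, so d and the e-side vary
## together: d > 0 (more DEL on Cg) should co-occur with e > 0.5 (more
## expression from Co).

#' Build per-gene/accession association records
#'
#' Joins mutation counts, homeologue-specific expression (HSE) calls and
#' phased expression, then applies the inclusion rules: records with
#' `d = 0` (no mutation bias) or without significant HSE are removed,
#' as are records whose expression pair is (0, 0).
#'
#' @param mutations data.frame `gene`, `accession`, `cg`, `co` — counts
#'   of (deleterious) mutations on each homeologue copy.
#' @param hse HSE calls with columns `gene`, `accession`, `FDR` (e.g.
#'   from [hseTest()] in per-sample mode; without an `accession` column
#'   the calls apply to every accession).
#' @param expression data.frame `gene`, `accession`, `expr_co`,
#'   `expr_cg` — normalized phased expression.
#' @param fdrThreshold HSE significance threshold.
#' @return data.frame `gene`, `accession`, `d`, `e`, `quadrant`.
#' @export
buildAssociation <- function(mutations, hse, expression,
                             fdrThreshold = 0.05) {
    stopifnot(all(c("gene", "accession", "cg", "co") %in%
                  colnames(mutations)),
              all(c("gene", "FDR") %in% colnames(hse)),
              all(c("gene", "accession", "expr_co", "expr_cg") %in%
                  colnames(expression)))
    rec <- merge(mutations, expression, by = c("gene", "accession"))
    if ("accession" %in% colnames(hse))
        rec <- merge(rec, hse[c("gene", "accession", "FDR")],
                     by = c("gene", "accession"))
    else
        rec <- merge(rec, hse[c("gene", "FDR")], by = "gene")
    rec$d <- rec$cg - rec$co
    tot <- rec$expr_co + rec$expr_cg
    zero <- tot == 0
    if (any(zero))
        message(sum(zero), " record(s) with (0, 0) expression excluded")
    rec <- rec[!zero, , drop = FALSE]
    rec$e <- rec$expr_co / (rec$expr_co + rec$expr_cg)
    rec <- rec[rec$d != 0 & rec$FDR < fdrThreshold & rec$e != 0.5, ,
               drop = FALSE]
    rec$quadrant <- if (nrow(rec))
        paste0(ifelse(rec$d > 0, "d>0", "d<0"), ",",
               ifelse(rec$e > 0.5, "e>0.5", "e<0.5"))
    else character()
    rec[c("gene", "accession", "d", "e", "quadrant")]
}

#' Fisher exact test of mutation-bias / expression-bias association
#'
#' Collapses the quadrants to a 2x2 table (sign of `d` x side of `e`)
#' and applies a two-sided Fisher exact test with the conditional-ML
#' odds ratio.  Same-direction over-representation (d>0 with e>0.5 and
#' d<0 with e<0.5) appears as an odds ratio above 1.
#'
#' @param records output of [buildAssociation()].
#' @param alternative passed to [stats::fisher.test()].
#' @return List: `table` (2x2 counts), `p`, `oddsRatio`.
#' @export
associationTest <- function(records, alternative = "two.sided") {
    if (!nrow(records)) stop("no association records")
    tab <- table(factor(records$d > 0, levels = c(TRUE, FALSE),
                        labels = c("d>0", "d<0")),
                 factor(records$e > 0.5, levels = c(TRUE, FALSE),
                        labels = c("e>0.5", "e<0.5")))
    if (sum(tab > 0) <= 1) {
        warning("all records fall in a single cell; no test possible")
        return(list(table = tab, p = 1, oddsRatio = NA_real_))
    }
    ft <- fisher.test(tab, alternative = alternative)
    list(table = tab, p = ft$p.value,
         oddsRatio = unname(ft$estimate))
}

#' Synonymous-mutation control analysis
#'
#' Repeats the association analysis with `d` computed from synonymous
#' mutations, restricted to genes carrying no deleterious mutation at
#' all; a mapping or annotation artifact would reproduce the
#' association here, a genuine load effect would not.
#'
#' @param synMutations data.frame like `mutations` in
#'   [buildAssociation()], but for synonymous counts.
#' @param delMutations the deleterious table used to identify genes to
#'   exclude (any gene with a positive DEL count on either copy).
#' @param hse,expression,fdrThreshold as in [buildAssociation()].
#' @return List: `records`, `table`, `p`, `oddsRatio`.
#' @export
synonymousControl <- function(synMutations, delMutations, hse, expression,
                              fdrThreshold = 0.05) {
    withDel <- unique(delMutations$gene[delMutations$cg + delMutations$co > 0])
    syn <- synMutations[!synMutations$gene %in% withDel, , drop = FALSE]
    rec <- buildAssociation(syn, hse, expression, fdrThreshold)
    if (!nrow(rec)) stop("empty synonymous control set")
    c(list(records = rec), associationTest(rec))
}
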