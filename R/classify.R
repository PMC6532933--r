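## Expression-pattern classification.
##
## Both schemes consume three-state significance calls (up / down / ns)
## between group pairs plus the point estimates of the group means.
## Significance decides every "equal / different" question; means decide
## interval membership (inside/outside the parental range) and which
## parent is closer.  Ambiguous significance patterns are resolved by an
## explicit precedence (transgressive > dominance > compensatory drift >
## legacy > reverse > intermediate), making the unavoidable arbitrariness
## of any such scheme testable.

.unphasedCategories <- c("no_difference", "intermediate", "dominance_CG",
                         "dominance_CO", "transgressive")

#' Classify total (unphased) allopolyploid expression
#'
#' Four-category scheme comparing the allopolyploid's total expression
#' with the two parents using three contrasts: Cbp vs CG, Cbp vs CO and
#' CG vs CO.
#'
#' \itemize{
#'   \item no_difference: all three contrasts non-significant;
#'   \item transgressive: Cbp mean outside the parental range and
#'     significantly different from the closer parent;
#'   \item dominance_CO (resp. dominance_CG): Cbp equal to CO (CG),
#'     different from the other parent, parents different;
#'   \item intermediate: parents different, Cbp strictly between the
#'     parental means and different from both.
#' }
#' Vectors matching none of these are resolved by precedence: outside
#' the parental interval and significant against at least one parent is
#' transgressive; one non-significant parental comparison with divergent
#' parents is dominance towards that parent; divergent parents otherwise
#' give intermediate; everything else no_difference.
#'
#' @param dirCbpCG,dirCbpCO,dirCGCO direction vectors in
#'   `c("up","down","ns")` for the contrasts Cbp:CG, Cbp:CO and CG:CO.
#' @param meanCbp,meanCG,meanCO group mean expression per gene.
#' @param gene optional gene ids.
#' @return data.frame `gene`, `category`.
#' @export
classifyUnphased <- function(dirCbpCG, dirCbpCO, dirCGCO,
                             meanCbp, meanCG, meanCO, gene = NULL) {
    n <- length(dirCbpCG)
    stopifnot(length(dirCbpCO) == n, length(dirCGCO) == n,
              length(meanCbp) == n, length(meanCG) == n,
              length(meanCO) == n)
    if (anyNA(c(dirCbpCG, dirCbpCO, dirCGCO)))
        stop("missing contrast direction")
    sigPC <- dirCbpCG != "ns"
    sigPO <- dirCbpCO != "ns"
    sigGO <- dirCGCO != "ns"
    lo <- pmin(meanCG, meanCO); hi <- pmax(meanCG, meanCO)
    outside <- meanCbp < lo | meanCbp > hi
    closerIsCG <- abs(meanCbp - meanCG) <= abs(meanCbp - meanCO)
    sigCloser <- ifelse(closerIsCG, sigPC, sigPO)
    inside <- meanCbp > lo & meanCbp < hi

    cat <- rep(NA_character_, n)
    cat[!sigPC & !sigPO & !sigGO] <- "no_difference"
    i <- is.na(cat) & outside & sigCloser
    cat[i] <- "transgressive"
    i <- is.na(cat) & sigGO & !sigPO & sigPC
    cat[i] <- "dominance_CO"
    i <- is.na(cat) & sigGO & !sigPC & sigPO
    cat[i] <- "dominance_CG"
    i <- is.na(cat) & sigGO & inside & sigPC & sigPO
    cat[i] <- "intermediate"
    ## precedence fallback for intransitive call patterns
    i <- is.na(cat) & outside & (sigPC | sigPO)
    cat[i] <- "transgressive"
    i <- is.na(cat) & sigGO & !sigPC & !sigPO
    cat[i] <- ifelse(closerIsCG[i], "dominance_CG", "dominance_CO")
    i <- is.na(cat) & sigGO & !sigPO
    cat[i] <- "dominance_CO"
    i <- is.na(cat) & sigGO & !sigPC
    cat[i] <- "dominance_CG"
    i <- is.na(cat) & sigGO
    cat[i] <- "intermediate"
    cat[is.na(cat)] <- "no_difference"
    data.frame(gene = gene %||% seq_len(n), category = cat,
               stringsAsFactors = FALSE)
}

.phasedCategories <- c("no_difference", "legacy", "reverse", "intermediate",
                       "compensatory_drift", "dominance", "transgressive",
                       "ambiguous")

#' Classify phased (homeologue-resolved) expression patterns
#'
#' Seven-category scheme over the six pairwise contrasts among CG, CO,
#' Cbp_Cg and Cbp_Co, each with three states, i.e. a decision table over
#' the 729 possible direction vectors (plus the group means for interval
#' and orientation checks).  Categories, in precedence order after
#' `no_difference` (all six ns):
#'
#' \enumerate{
#'   \item compensatory_drift (5): parents statistically equal,
#'     subgenomes differ.  Checked first because with equal parents the
#'     parental interval collapses to a point estimate artifact and any
#'     diverging subgenome would otherwise read as transgressive;
#'   \item transgressive (7): at least one subgenome mean outside the
#'     parental range and significant against its closer parent; 7a =
#'     only Cbp_Cg outside, 7b = only Cbp_Co, 7c = both;
#'   \item dominance (6): parents differ, subgenomes equal, both equal
#'     one parent and differ from the other; subcategory 6a for the
#'     CG-dominant pattern and 6b for CO (orientation configurable via
#'     `cgIs6a`);
#'   \item legacy (2): parents differ, each subgenome equals its own
#'     parent, subgenomes differ;
#'   \item reverse (3): parents differ, each subgenome equals the
#'     opposite parent, subgenomes differ;
#'   \item intermediate (4): parents differ, both subgenome means
#'     strictly inside the parental interval, and either both subgenomes
#'     differ from both parents or the subgenomes do not differ from
#'     each other.
#' }
#' Direction vectors matching no rule are `ambiguous`.
#'
#' @param dirCGCO,dirCgCo,dirCgCG,dirCgCO,dirCoCG,dirCoCO direction
#'   vectors (`up`/`down`/`ns`) for the contrasts CG:CO, Cbp_Cg:Cbp_Co,
#'   Cbp_Cg:CG, Cbp_Cg:CO, Cbp_Co:CG and Cbp_Co:CO.
#' @param meanCG,meanCO,meanCg,meanCo group means per gene.
#' @param gene optional ids.
#' @param cgIs6a if `TRUE` (default) subcategory 6a denotes dominance of
#'   the CG genetic background.
#' @return data.frame `gene`, `category`, `subcategory` (`""`, `"6a"`,
#'   `"6b"`, `"7a"`, `"7b"`, `"7c"`).
#' @export
classifyPhased <- function(dirCGCO, dirCgCo, dirCgCG, dirCgCO,
                           dirCoCG, dirCoCO,
                           meanCG, meanCO, meanCg, meanCo,
                           gene = NULL, cgIs6a = TRUE) {
    n <- length(dirCGCO)
    dirs <- cbind(dirCGCO, dirCgCo, dirCgCG, dirCgCO, dirCoCG, dirCoCO)
    if (nrow(dirs) != n || anyNA(dirs)) stop("missing contrast direction")
    sGO <- dirCGCO != "ns"   # parents differ
    sSub <- dirCgCo != "ns"  # subgenomes differ
    sCgCG <- dirCgCG != "ns"; sCgCO <- dirCgCO != "ns"
    sCoCG <- dirCoCG != "ns"; sCoCO <- dirCoCO != "ns"

    lo <- pmin(meanCG, meanCO); hi <- pmax(meanCG, meanCO)
    outCg <- meanCg < lo | meanCg > hi
    outCo <- meanCo < lo | meanCo > hi
    inCg <- meanCg > lo & meanCg < hi
    inCo <- meanCo > lo & meanCo < hi
    cgCloserCG <- abs(meanCg - meanCG) <= abs(meanCg - meanCO)
    coCloserCG <- abs(meanCo - meanCG) <= abs(meanCo - meanCO)
    transCg <- outCg & ifelse(cgCloserCG, sCgCG, sCgCO)
    transCo <- outCo & ifelse(coCloserCG, sCoCG, sCoCO)

    cat <- rep(NA_character_, n)
    sub <- rep("", n)

    i <- !sGO & !sSub & !sCgCG & !sCgCO & !sCoCG & !sCoCO
    cat[i] <- "no_difference"

    ## with statistically equal parents the parental "range" is a point
    ## estimate artifact, so diverging subgenomes read as compensatory
    ## drift, the category defined for exactly that configuration
    i <- is.na(cat) & !sGO & sSub
    cat[i] <- "compensatory_drift"

    i <- is.na(cat) & (transCg | transCo)
    cat[i] <- "transgressive"
    sub[i] <- ifelse(transCg[i] & transCo[i], "7c",
                     ifelse(transCg[i], "7a", "7b"))

    domCG <- sGO & !sSub & !sCgCG & !sCoCG & sCgCO & sCoCO
    domCO <- sGO & !sSub & !sCgCO & !sCoCO & sCgCG & sCoCG
    i <- is.na(cat) & (domCG | domCO)
    cat[i] <- "dominance"
    sub[i] <- ifelse(domCG[i], if (cgIs6a) "6a" else "6b",
                     if (cgIs6a) "6b" else "6a")

    i <- is.na(cat) & sGO & sSub & !sCgCG & !sCoCO
    cat[i] <- "legacy"

    i <- is.na(cat) & sGO & sSub & !sCgCO & !sCoCG
    cat[i] <- "reverse"

    i <- is.na(cat) & sGO & inCg & inCo &
        ((sCgCG & sCgCO & sCoCG & sCoCO) | !sSub)
    cat[i] <- "intermediate"

    cat[is.na(cat)] <- "ambiguous"
    data.frame(gene = gene %||% seq_len(n), category = cat,
               subcategory = sub, stringsAsFactors = FALSE)
}

#' Cross-tissue conservation of expression categories
#'
#' @param assignments data.frame with columns `gene`, `tissue`,
#'   `category` (one row per gene/tissue).
#' @return List: `perGene` (data.frame `gene`, `nTissues`, `conserved`,
#'   `partial` — `partial` flags genes missing from some tissue) and
#'   `pairwise`, the tissue x tissue matrix of the fraction of shared
#'   genes with identical category.
#' @export
tissueConservation <- function(assignments) {
    tissues <- unique(assignments$tissue)
    if (length(tissues) < 2) stop("need categories for >= 2 tissues")
    wide <- tapply(assignments$category,
                   list(assignments$gene, assignments$tissue),
                   function(x) x[1])
    nT <- rowSums(!is.na(wide))
    conserved <- apply(wide, 1, function(x) {
        x <- x[!is.na(x)]
        length(unique(x)) == 1
    })
    perGene <- data.frame(gene = rownames(wide), nTissues = as.integer(nT),
                          conserved = conserved & nT >= 1,
                          partial = nT < length(tissues),
                          stringsAsFactors = FALSE, row.names = NULL)
    pairwise <- matrix(NA_real_, length(tissues), length(tissues),
                       dimnames = list(tissues, tissues))
    for (a in tissues) for (b in tissues) {
        both <- !is.na(wide[, a]) & !is.na(wide[, b])
        pairwise[a, b] <- if (any(both))
            mean(wide[both, a] == wide[both, b]) else NA_real_
    }
    list(perGene = perGene, pairwise = pairwise)
}

#' Category proportion table
#'
#' Proportions over all classified genes and renormalized over
#' differentially expressed genes only (i.e. excluding the
#' `no_difference` category).  For the phased scheme the within-dominance
#' split (share of 6a vs 6b) is attached as the `"dominanceShare"`
#' attribute.
#'
#' @param assignments data.frame with `category` (and optionally
#'   `subcategory`).
#' @return data.frame `category`, `n`, `prop_all`, `prop_de_only`.
#' @export
categoryProportions <- function(assignments) {
    if (nrow(assignments) == 0) stop("no classified genes")
    tab <- table(assignments$category)
    de <- tab[names(tab) != "no_difference"]
    out <- data.frame(category = names(tab), n = as.integer(tab),
                      prop_all = as.numeric(tab) / sum(tab),
                      prop_de_only = ifelse(names(tab) == "no_difference",
                                            NA_real_,
                                            as.numeric(tab) / sum(de)),
                      stringsAsFactors = FALSE, row.names = NULL)
    if ("subcategory" %in% colnames(assignments)) {
        dom <- assignments$subcategory[assignments$category == "dominance"]
        if (length(dom))
            attr(out, "dominanceShare") <- prop.table(table(dom))
    }
    out
}
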