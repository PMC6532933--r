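## Synthetic data with exported ground truth.
##
## Expression counts are negative-binomial around per-group means set by
## the true regulatory category of each gene; mutation counts follow a
## (beta-)binomial placement between homeologues.  Inference code never
## reads the ground truth.

.drawDispersion <- function(n, disp) rlnorm(n, meanlog = log(disp), sdlog = 0.5)

#' Simulate parental and tetraploid expression counts
#'
#' Draws negative-binomial counts for the two parental species and phased
#' homeologue counts for the tetraploid under the regulatory architecture
#' of `scenario`.  Homeologue means per category:
#' \describe{
#'   \item{no_difference}{all four means equal the base level.}
#'   \item{legacy}{each homeologue keeps its parental mean (pure cis).}
#'   \item{reverse}{homeologue means swapped relative to the parents.}
#'   \item{intermediate}{both homeologues pulled halfway towards the
#'     parental midpoint (still strictly inside the parental interval).}
#'   \item{dominance_CO / dominance_CG}{both homeologues at the CO (resp.
#'     CG) parental mean.}
#'   \item{compensatory_drift}{parents equal, homeologues split apart.}
#'   \item{transgressive_one / transgressive_both}{one (resp. both)
#'     homeologue placed one log2 unit beyond the more extreme parent.}
#' }
#'
#' @param scenario a [RegulatoryScenario-class].
#' @param seed integer seed; the result is reproducible bit-for-bit from
#'   (scenario, seed).
#' @return A list with elements `parents` ([ExpressionCounts-class],
#'   columns `CG_*` and `CO_*`), `phased` ([PhasedCounts-class]) and
#'   `truth` (data.frame of per-gene category and true means).  The truth
#'   is also attached to the containers' metadata.
#' @export
simulateExpression <- function(scenario, seed = 1L) {
    stopifnot(is(scenario, "RegulatoryScenario"))
    validObject(scenario)
    set.seed(as.integer(seed))
    n <- scenario@nGenes
    cats <- sample(.regCategories, n, replace = TRUE,
                   prob = scenario@proportions)
    base <- rlnorm(n, meanlog = scenario@baseMeanLog, sdlog = 1)
    disp <- .drawDispersion(n, scenario@dispersion)

    parentsEqual <- cats %in% c("no_difference", "compensatory_drift")
    d <- rnorm(n, 0, scenario@divergence)
    d[parentsEqual] <- 0
    muCG <- base * 2^(d / 2)
    muCO <- base * 2^(-d / 2)

    muCg <- muCG
    muCo <- muCO
    i <- cats == "no_difference"
    muCg[i] <- base[i]; muCo[i] <- base[i]
    i <- cats == "reverse"
    muCg[i] <- muCO[i]; muCo[i] <- muCG[i]
    i <- cats == "intermediate"
    muCg[i] <- base[i] * 2^(d[i] / 4); muCo[i] <- base[i] * 2^(-d[i] / 4)
    i <- cats == "dominance_CO"
    muCg[i] <- muCO[i]; muCo[i] <- muCO[i]
    i <- cats == "dominance_CG"
    muCg[i] <- muCG[i]; muCo[i] <- muCG[i]
    i <- cats == "compensatory_drift"
    cd <- rnorm(sum(i), 0, scenario@divergence) +
        sample(c(-1, 1), sum(i), TRUE) * pmax(scenario@divergence, 0.5)
    muCg[i] <- base[i] * 2^(cd / 2); muCo[i] <- base[i] * 2^(-cd / 2)
    i <- which(cats %in% c("transgressive_one", "transgressive_both"))
    if (length(i)) {
        up <- sample(c(TRUE, FALSE), length(i), TRUE)
        extreme <- ifelse(up, pmax(muCG[i], muCO[i]) * 2,
                          pmin(muCG[i], muCO[i]) / 2)
        one <- cats[i] == "transgressive_one"
        whichSub <- sample(c("cg", "co"), length(i), TRUE)
        muCg[i] <- ifelse(!one | whichSub == "cg", extreme, muCg[i])
        muCo[i] <- ifelse(!one | whichSub == "co", extreme, muCo[i])
    }

    genes <- sprintf("g%05d", seq_len(n))
    size <- 1 / disp
    drawNB <- function(mu, k) {
        m <- matrix(rnbinom(n * k, mu = rep(mu, k), size = rep(size, k)),
                    nrow = n)
        rownames(m) <- genes
        m
    }
    k <- scenario@nAccessions
    parents <- cbind(drawNB(muCG, k), drawNB(muCO, k))
    colnames(parents) <- c(sprintf("CG_%d", seq_len(k)),
                           sprintf("CO_%d", seq_len(k)))
    sd <- DataFrame(species = rep(c("CG", "CO"), each = k),
                    accession = colnames(parents),
                    row.names = colnames(parents))
    parentsEC <- ExpressionCounts(parents, sampleData = sd)

    kT <- scenario@nTetraploid
    fac <- if (scenario@sharedAccessionSd > 0)
        matrix(rlnorm(n * kT, 0, scenario@sharedAccessionSd), nrow = n)
    else matrix(1, n, kT)
    co <- matrix(rnbinom(n * kT, mu = rep(muCo, kT) * fac,
                         size = rep(size, kT)), nrow = n)
    cg <- matrix(rnbinom(n * kT, mu = rep(muCg, kT) * fac,
                         size = rep(size, kT)), nrow = n)
    dimnames(co) <- dimnames(cg) <-
        list(genes, sprintf("Cbp_%02d", seq_len(kT)))
    phased <- PhasedCounts(co, cg)

    truth <- data.frame(gene = genes, category = cats, muCG = muCG,
                        muCO = muCO, muCg = muCg, muCo = muCo,
                        dispersion = disp, stringsAsFactors = FALSE)
    metadata(parentsEC)$groundTruth <- truth
    metadata(phased)$groundTruth <- truth
    list(parents = parentsEC, phased = phased, truth = truth)
}

#' Draw beta-binomial counts
#'
#' `k ~ BB(n, b, phi)` in the bias/overdispersion parameterization
#' (`alpha = (0.5 + b)/phi`, `beta = (0.5 - b)/phi`); `phi = 0`
#' degenerates to `Binomial(n, 0.5 + b)`.
#'
#' @param n vector of totals.
#' @param b bias in (-0.5, 0.5).
#' @param phi overdispersion, >= 0.
#' @return Integer vector of successes, one per element of `n`.
#' @export
rBetaBinom <- function(n, b, phi) {
    stopifnot(b > -0.5, b < 0.5, phi >= 0)
    if (phi == 0) return(rbinom(length(n), n, 0.5 + b))
    a <- (0.5 + b) / phi
    be <- (0.5 - b) / phi
    rbinom(length(n), n, rbeta(length(n), a, be))
}

#' Simulate per-gene mutation placement between homeologues
#'
#' For each gene a total `n` of mutations on the homeologue pair is drawn
#' (Poisson unless `fixedN`) and `k` of them are placed on the Cg copy by
#' a beta-binomial with the scenario's `(b, phi)`.
#'
#' @param scenario a [MutationScenario-class].
#' @param seed integer seed.
#' @return A list with `counts` (data.frame `gene`, `class`, `n`, `k`)
#'   and `truth` (the scenario parameters as a one-row data.frame).
#' @export
simulateMutations <- function(scenario, seed = 1L) {
    stopifnot(is(scenario, "MutationScenario"))
    validObject(scenario)
    set.seed(as.integer(seed))
    nTot <- if (scenario@fixedN) rep(as.integer(scenario@meanMutations),
                                     scenario@nGenes)
            else rpois(scenario@nGenes, scenario@meanMutations)
    k <- rBetaBinom(nTot, scenario@b, scenario@phi)
    counts <- data.frame(gene = sprintf("g%05d", seq_len(scenario@nGenes)),
                         class = scenario@mutationClass, n = nTot, k = k,
                         stringsAsFactors = FALSE)
    truth <- data.frame(class = scenario@mutationClass, b = scenario@b,
                        phi = scenario@phi, stringsAsFactors = FALSE)
    list(counts = counts, truth = truth)
}

#' Simulate per-SNP DNA allelic counts
#'
#' Emulates genomic (DNA) read counts over the two subgenome alleles used
#' to screen SNPs for mapping bias: a `1 - biasFraction` share of SNPs
#' draws reads at the fair 0.5 ratio, the rest at `biasProb`.
#'
#' @param nSnps number of SNPs.
#' @param biasFraction fraction of truly biased SNPs in \[0, 1\].
#' @param seed integer seed.
#' @param depth mean sequencing depth (Poisson).
#' @param biasProb allelic probability at biased SNPs.
#' @param snpsPerGene SNPs are assigned to genes in blocks of this size.
#' @return data.frame `snp`, `gene`, `count_co`, `count_cg`,
#'   `trueBiased`.
#' @export
simulateDnaAllelicCounts <- function(nSnps, biasFraction = 0, seed = 1L,
                                     depth = 60, biasProb = 0.8,
                                     snpsPerGene = 5L) {
    stopifnot(biasFraction >= 0, biasFraction <= 1)
    set.seed(as.integer(seed))
    biased <- runif(nSnps) < biasFraction
    p <- ifelse(biased, biasProb, 0.5)
    total <- rpois(nSnps, depth)
    co <- rbinom(nSnps, total, p)
    data.frame(snp = sprintf("s%06d", seq_len(nSnps)),
               gene = sprintf("g%05d", (seq_len(nSnps) - 1) %/% snpsPerGene + 1),
               count_co = co, count_cg = total - co, trueBiased = biased,
               stringsAsFactors = FALSE)
}

#' Simulate gene positions along scaffolds
#'
#' Genes are laid head-to-tail with exponential intergenic spacing; used
#' by the spatial-clustering resampling test.
#'
#' @param nGenes number of genes (ids match [simulateExpression()]).
#' @param nScaffolds scaffolds to spread genes over.
#' @param meanLength,meanSpacing mean gene length and intergenic gap (bp).
#' @param seed integer seed.
#' @return A named [GenomicRanges::GRanges].
#' @export
simulateGenePositions <- function(nGenes, nScaffolds = 8L, meanLength = 2000,
                                  meanSpacing = 3000, seed = 1L) {
    set.seed(as.integer(seed))
    scaf <- sort(sample(seq_len(nScaffolds), nGenes, replace = TRUE))
    len <- pmax(200L, as.integer(rpois(nGenes, meanLength)))
    gap <- as.integer(rexp(nGenes, 1 / meanSpacing))
    starts <- integer(nGenes)
    pos <- integer(nScaffolds)
    for (i in seq_len(nGenes)) {
        s <- scaf[i]
        starts[i] <- pos[s] + gap[i] + 1L
        pos[s] <- starts[i] + len[i]
    }
    gr <- GRanges(paste0("scaffold_", scaf),
                  IRanges(start = starts, width = len))
    names(gr) <- sprintf("g%05d", seq_len(nGenes))
    gr
}

#' @importFrom stats rexp
NULL
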