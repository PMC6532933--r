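#' @import methods
#' @importFrom stats as.formula binom.test coef fisher.test lm median optim
#'   optimize p.adjust pbinom phyper pchisq pf pt quantile rbeta rbinom
#'   rlnorm rnbinom rnorm rpois runif sd setNames t.test var wilcox.test
#'   cor.test complete.cases
#' @importFrom utils read.delim write.table packageVersion
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData
#' @importFrom GenomicRanges GRanges seqnames start end width mid
#' @importFrom IRanges IRanges
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' Gene-by-sample expression counts
#'
#' `ExpressionCounts` extends
#' [SummarizedExperiment::SummarizedExperiment] with a single
#' `"counts"` assay of non-negative integers.  Column metadata carries the
#' sample sheet (at least `species`; typically also `population`, `tissue`
#' and `accession`).  Library sizes are the column sums of the raw counts.
#'
#' @slot .Data see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("ExpressionCounts", contains = "SummarizedExperiment")

setValidity("ExpressionCounts", function(object) {
    msg <- character()
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- assay(object, "counts")
        if (anyNA(m)) msg <- c(msg, "counts must not contain NA")
        else {
            if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
            if (any(m != round(m))) msg <- c(msg, "counts must be integers")
        }
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene ids")
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionCounts object
#'
#' @param counts integer matrix, genes in rows, samples in columns.
#' @param sampleData data.frame of per-sample metadata, one row per column
#'   of `counts` (matched by row name or order).
#' @return An [ExpressionCounts-class] object.
#' @export
ExpressionCounts <- function(counts, sampleData = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("sample%d", seq_len(ncol(counts)))
    if (is.null(sampleData))
        sampleData <- DataFrame(row.names = colnames(counts))
    se <- SummarizedExperiment(assays = list(counts = counts),
                               colData = as(sampleData, "DataFrame"))
    new("ExpressionCounts", se)
}

#' Phased homeologue counts
#'
#' Per-gene, per-accession counts attributed to each of the two subgenomes
#' of an allotetraploid: the assay `"co"` holds counts on the
#' *C. orientalis*-derived copy and `"cg"` counts on the
#' *C. grandiflora*-derived copy.  Columns are tetraploid accessions.
#' Missing (gene, accession) observations are `NA`, never zero.
#'
#' @export
setClass("PhasedCounts", contains = "SummarizedExperiment")

setValidity("PhasedCounts", function(object) {
    msg <- character()
    need <- c("co", "cg")
    if (!all(need %in% assayNames(object)))
        msg <- c(msg, "assays 'co' and 'cg' are required")
    else {
        for (a in need) {
            m <- assay(object, a)
            ok <- !is.na(m)
            if (any(m[ok] < 0))
                msg <- c(msg, sprintf("assay '%s' has negative counts", a))
        }
        if (!identical(is.na(assay(object, "co")), is.na(assay(object, "cg"))))
            msg <- c(msg, "co/cg missingness must agree")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene ids")
    if (length(msg)) msg else TRUE
})

#' Construct a PhasedCounts object
#'
#' @param co,cg numeric matrices (genes x accessions) of homeologue counts;
#'   `NA` marks unobserved pairs.
#' @param accessionData optional per-accession metadata.
#' @return A [PhasedCounts-class] object.
#' @export
PhasedCounts <- function(co, cg, accessionData = NULL) {
    co <- as.matrix(co); cg <- as.matrix(cg)
    stopifnot(identical(dim(co), dim(cg)))
    if (is.null(colnames(co)))
        colnames(co) <- colnames(cg) <- sprintf("acc%d", seq_len(ncol(co)))
    if (is.null(accessionData))
        accessionData <- DataFrame(row.names = colnames(co))
    se <- SummarizedExperiment(assays = list(co = co, cg = cg),
                               colData = as(accessionData, "DataFrame"))
    new("PhasedCounts", se)
}

#' Run configuration
#'
#' Holds the tunable parameters shared across the pipeline.  All
#' randomness in the package flows from `rngSeed`.
#'
#' @slot fdrThreshold FDR below which a contrast is called significant
#'   (default 0.05).
#' @slot pseudoCount added to counts before normalization/log-ratios
#'   (default 1).
#' @slot bootstrapReps bootstrap replicates for confidence intervals
#'   (default 1000).
#' @slot rngSeed integer seed.
#' @slot deEngine `"builtin_ttest"` or `"external_calls"`.
#' @slot tissues character vector of tissue labels.
#' @export
setClass("RunConfig",
    representation(fdrThreshold = "numeric", pseudoCount = "numeric",
                   bootstrapReps = "integer", rngSeed = "integer",
                   deEngine = "character", tissues = "character"),
    prototype(fdrThreshold = 0.05, pseudoCount = 1, bootstrapReps = 1000L,
              rngSeed = 1L, deEngine = "builtin_ttest",
              tissues = c("flower", "leaf", "root")))

setValidity("RunConfig", function(object) {
    msg <- character()
    if (length(object@fdrThreshold) != 1 || object@fdrThreshold <= 0 ||
        object@fdrThreshold >= 1)
        msg <- c(msg, "fdrThreshold must lie strictly in (0, 1)")
    if (object@pseudoCount < 0)
        msg <- c(msg, "pseudoCount must be non-negative")
    if (object@bootstrapReps < 1L)
        msg <- c(msg, "bootstrapReps must be >= 1")
    if (!object@deEngine %in% c("builtin_ttest", "external_calls"))
        msg <- c(msg, "unknown deEngine")
    if (length(msg)) msg else TRUE
})

#' Construct a RunConfig
#'
#' @param fdrThreshold,pseudoCount,bootstrapReps,rngSeed,deEngine,tissues
#'   see [RunConfig-class].
#' @return A validated `RunConfig`.
#' @export
RunConfig <- function(fdrThreshold = 0.05, pseudoCount = 1,
                      bootstrapReps = 1000L, rngSeed = 1L,
                      deEngine = "builtin_ttest",
                      tissues = c("flower", "leaf", "root")) {
    new("RunConfig", fdrThreshold = fdrThreshold, pseudoCount = pseudoCount,
        bootstrapReps = as.integer(bootstrapReps),
        rngSeed = as.integer(rngSeed), deEngine = deEngine,
        tissues = as.character(tissues))
}

#' Regulatory architecture of a simulated gene set
#'
#' Describes the ground-truth regulatory scenario used by
#' [simulateExpression()]: the mixture of per-gene expression-pattern
#' categories, the magnitude of parental divergence, the negative-binomial
#' dispersion, and the design size.
#'
#' @slot proportions named numeric vector over the categories
#'   `no_difference`, `legacy`, `intermediate`, `dominance_CO`,
#'   `dominance_CG`, `compensatory_drift`, `reverse`, `transgressive_one`,
#'   `transgressive_both`; must sum to 1.
#' @slot divergence mean absolute parental divergence, log2 units.
#' @slot cisFraction fraction of divergent regulation that is cis-acting
#'   (used by mixed scenarios).
#' @slot dispersion negative-binomial dispersion (1/size); per-gene values
#'   are drawn log-normally around this.
#' @slot nGenes,nAccessions,nTetraploid design sizes.
#' @slot baseMeanLog meanlog of the log-normal base expression level (CPM
#'   scale).
#' @slot sharedAccessionSd sd of a shared per-accession log-normal factor
#'   applied to both homeologues (models homeologues sharing cells; 0
#'   disables).
#' @export
setClass("RegulatoryScenario",
    representation(proportions = "numeric", divergence = "numeric",
                   cisFraction = "numeric", dispersion = "numeric",
                   nGenes = "integer", nAccessions = "integer",
                   nTetraploid = "integer", baseMeanLog = "numeric",
                   sharedAccessionSd = "numeric"))

.regCategories <- c("no_difference", "legacy", "intermediate",
                    "dominance_CO", "dominance_CG", "compensatory_drift",
                    "reverse", "transgressive_one", "transgressive_both")

setValidity("RegulatoryScenario", function(object) {
    msg <- character()
    p <- object@proportions
    if (!setequal(names(p), .regCategories))
        msg <- c(msg, "proportions must be named over the nine categories")
    else if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
        msg <- c(msg, "proportions must be non-negative and sum to 1")
    if (object@cisFraction < 0 || object@cisFraction > 1)
        msg <- c(msg, "cisFraction must lie in [0, 1]")
    if (object@dispersion <= 0)
        msg <- c(msg, "dispersion must be positive")
    if (object@nGenes < 1L || object@nAccessions < 1L ||
        object@nTetraploid < 1L)
        msg <- c(msg, "design sizes must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct a RegulatoryScenario
#'
#' Defaults emulate the study design this package targets: four accessions
#' per parental species, sixteen tetraploid accessions, a moderate
#' biological dispersion typical of inbred plant lines, and a category mix
#' close to what is observed in allopolyploid flower tissue (a majority of
#' genes with no difference, a few percent of legacy, dominance,
#' compensatory-drift and reverse genes, and roughly ten percent
#' transgressive).
#'
#' @param proportions see [RegulatoryScenario-class]; a partial named
#'   vector is completed with zeros.
#' @param divergence,cisFraction,dispersion,nGenes,nAccessions,nTetraploid,baseMeanLog,sharedAccessionSd
#'   see [RegulatoryScenario-class].
#' @return A validated `RegulatoryScenario`.
#' @export
RegulatoryScenario <- function(proportions = c(no_difference = 0.60,
                                   legacy = 0.045, intermediate = 0.126,
                                   dominance_CO = 0.038, dominance_CG = 0.012,
                                   compensatory_drift = 0.038, reverse = 0.005,
                                   transgressive_one = 0.103,
                                   transgressive_both = 0.033),
                               divergence = 1, cisFraction = 1,
                               dispersion = 0.05, nGenes = 2000L,
                               nAccessions = 4L, nTetraploid = 16L,
                               baseMeanLog = log(100),
                               sharedAccessionSd = 0) {
    full <- setNames(numeric(length(.regCategories)), .regCategories)
    stopifnot(all(names(proportions) %in% .regCategories))
    full[names(proportions)] <- proportions
    new("RegulatoryScenario", proportions = full, divergence = divergence,
        cisFraction = cisFraction, dispersion = dispersion,
        nGenes = as.integer(nGenes), nAccessions = as.integer(nAccessions),
        nTetraploid = as.integer(nTetraploid), baseMeanLog = baseMeanLog,
        sharedAccessionSd = sharedAccessionSd)
}

#' Mutation-placement scenario
#'
#' Ground truth for [simulateMutations()]: per-gene totals `n` and the
#' beta-binomial placement of `k` mutations on the Cg homeologue with bias
#' `b` and overdispersion `phi` (`phi = 0` degenerates to the binomial).
#'
#' @slot nGenes number of genes.
#' @slot meanMutations Poisson mean of per-gene totals (or a fixed total
#'   when `fixedN` is `TRUE`).
#' @slot fixedN logical; use `meanMutations` as a constant total.
#' @slot b placement bias in (-0.5, 0.5); probability on Cg is `0.5 + b`.
#' @slot phi overdispersion, non-negative.
#' @slot class `"SYN"` or `"DEL"`.
#' @export
setClass("MutationScenario",
    representation(nGenes = "integer", meanMutations = "numeric",
                   fixedN = "logical", b = "numeric", phi = "numeric",
                   mutationClass = "character"))

setValidity("MutationScenario", function(object) {
    msg <- character()
    if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
    if (object@b <= -0.5 || object@b >= 0.5)
        msg <- c(msg, "b must lie strictly in (-0.5, 0.5)")
    if (object@phi < 0) msg <- c(msg, "phi must be non-negative")
    if (!object@mutationClass %in% c("SYN", "DEL", "TOL"))
        msg <- c(msg, "class must be SYN, DEL or TOL")
    if (length(msg)) msg else TRUE
})

#' Construct a MutationScenario
#'
#' @param nGenes,meanMutations,fixedN,b,phi,class see
#'   [MutationScenario-class].
#' @return A validated `MutationScenario`.
#' @export
MutationScenario <- function(nGenes = 5000L, meanMutations = 5, fixedN = FALSE,
                             b = 0, phi = 0, class = "SYN") {
    new("MutationScenario", nGenes = as.integer(nGenes),
        meanMutations = meanMutations, fixedN = fixedN, b = b, phi = phi,
        mutationClass = class)
}

#' Fitted mutation-placement model
#'
#' Result of [fitMutationModel()], [fitJointSynDel()] or
#' [bootstrapCI()].  The single-class lattice is M1 (binomial, no bias),
#' M2 (binomial with bias `b`), M3 (beta-binomial, no bias), M4
#' (beta-binomial with bias); the joint family shares or frees (`b`,
#' `phi`) between the SYN and DEL classes.
#'
#' @slot model model identifier.
#' @slot b,phi point estimates (single-class fits; `NA` where fixed at the
#'   null).
#' @slot logLik maximized log-likelihood.
#' @slot df number of free parameters.
#' @slot nGenes genes contributing to the likelihood.
#' @slot perClass named list of per-class `(b, phi)` estimates for joint
#'   fits.
#' @slot ci matrix of percentile bootstrap bounds (rows = parameters).
#' @slot boundary logical flag: an estimate sits on the parameter boundary.
#' @export
setClass("BetaBinomFit",
    representation(model = "character", b = "numeric", phi = "numeric",
                   logLik = "numeric", df = "integer", nGenes = "integer",
                   perClass = "list", ci = "matrix", boundary = "logical"),
    prototype(perClass = list(), ci = matrix(numeric(), 0, 2,
                  dimnames = list(NULL, c("2.5%", "97.5%"))),
              boundary = FALSE))

setMethod("show", "ExpressionCounts", function(object) {
    cat(sprintf("ExpressionCounts: %d genes x %d samples\n",
                nrow(object), ncol(object)))
    if (ncol(colData(object)))
        cat("  sample metadata:", paste(colnames(colData(object)),
                                        collapse = ", "), "\n")
    ls <- librarySizes(object)
    cat(sprintf("  library sizes: %s .. %s\n",
                format(min(ls)), format(max(ls))))
})

setMethod("show", "PhasedCounts", function(object) {
    nObs <- sum(!is.na(assay(object, "co")))
    cat(sprintf("PhasedCounts: %d genes x %d accessions (%d observed pairs)\n",
                nrow(object), ncol(object), nObs))
})

setMethod("show", "RunConfig", function(object) {
    cat("RunConfig\n",
        sprintf("  fdrThreshold : %g\n", object@fdrThreshold),
        sprintf("  pseudoCount  : %g\n", object@pseudoCount),
        sprintf("  bootstrapReps: %d\n", object@bootstrapReps),
        sprintf("  rngSeed      : %d\n", object@rngSeed),
        sprintf("  deEngine     : %s\n", object@deEngine),
        sprintf("  tissues      : %s\n",
                paste(object@tissues, collapse = ", ")), sep = "")
})

setMethod("show", "BetaBinomFit", function(object) {
    cat(sprintf("BetaBinomFit [%s]  logLik = %.3f  (df = %d, genes = %d)\n",
                object@model, object@logLik, object@df, object@nGenes))
    if (!is.na(object@b) || !is.na(object@phi))
        cat(sprintf("  b = %s, phi = %s%s\n",
                    format(object@b, digits = 4),
                    format(object@phi, digits = 4),
                    if (object@boundary) "  [boundary]" else ""))
    if (length(object@perClass))
        for (cl in names(object@perClass)) {
            est <- object@perClass[[cl]]
            cat(sprintf("  %s: b = %s, phi = %s\n", cl,
                        format(est[["b"]], digits = 4),
                        format(est[["phi"]], digits = 4)))
        }
    if (nrow(object@ci)) {
        cat("  bootstrap 95% CI:\n")
        for (p in rownames(object@ci))
            cat(sprintf("    %-8s [%s, %s]\n", p,
                        format(object@ci[p, 1], digits = 4),
                        format(object@ci[p, 2], digits = 4)))
    }
})

#' Library sizes of a count container
#'
#' @param x an [ExpressionCounts-class] or [PhasedCounts-class] object.
#' @return For `ExpressionCounts`, the per-sample column sums of raw
#'   counts.  For `PhasedCounts`, a two-row matrix of per-accession
#'   subgenome library sizes (`NA` pairs ignored).
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))

#' @rdname librarySizes
setMethod("librarySizes", "ExpressionCounts", function(x)
    colSums(assay(x, "counts")))

#' @rdname librarySizes
setMethod("librarySizes", "PhasedCounts", function(x)
    rbind(co = colSums(assay(x, "co"), na.rm = TRUE),
          cg = colSums(assay(x, "cg"), na.rm = TRUE)))

#' Homeologue count accessors
#'
#' @param x a [PhasedCounts-class] object.
#' @return The genes x accessions matrix for one subgenome.
#' @export
setGeneric("coCounts", function(x) standardGeneric("coCounts"))
#' @rdname coCounts
setMethod("coCounts", "PhasedCounts", function(x) assay(x, "co"))
#' @rdname coCounts
#' @export
setGeneric("cgCounts", function(x) standardGeneric("cgCounts"))
#' @rdname coCounts
setMethod("cgCounts", "PhasedCounts", function(x) assay(x, "cg"))

#' Ground truth attached to a simulated object
#'
#' @param x a simulated container produced by the `simulate*` functions.
#' @return The `data.frame` of per-gene ground truth stored at simulation
#'   time, or `NULL` when `x` was not simulated.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname groundTruth
setMethod("groundTruth", "ANY", function(x) metadata(x)$groundTruth)
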