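## Beta-binomial model of mutation placement between homeologues.
##
## For each gene, n mutations fall on the homeologue pair and k of them
## on the Cg copy.  The placement is modeled as k ~ BB(n, b, phi) in the
## bias/overdispersion parameterization
##   alpha = (0.5 + b) / phi,   beta = (0.5 - b) / phi,
## so b in (-0.5, 0.5) is the accumulation bias towards Cg and phi >= 0
## the overdispersion of the per-gene placement probability; phi -> 0
## recovers Binomial(n, 0.5 + b).  The single-class model lattice is
##   M1: B(n, 0.5)        no bias, no overdispersion (0 free parameters)
##   M2: B(n, 0.5 + b)    bias only (1)
##   M3: BB(n, 0, phi)    overdispersion only (1)
##   M4: BB(n, b, phi)    both (2)
## and the joint SYN/DEL family shares or frees (b, phi) between the
## synonymous and deleterious mutation classes.

.PHI_EPS <- 1e-10

.asNK <- function(data) {
    if (is.data.frame(data)) {
        stopifnot(all(c("n", "k") %in% colnames(data)))
        data <- data[data$n > 0, , drop = FALSE]
        list(n = data$n, k = data$k)
    } else stop("data must be a data.frame with columns n and k")
}

#' Beta-binomial log-likelihood
#'
#' Sum over genes of the log BB(n, b, phi) probability mass; at
#' `phi = 0` the exact binomial log-pmf with `p = 0.5 + b` is used
#' (the continuous limit).
#'
#' @param data data.frame with columns `n`, `k` (genes with `n = 0` are
#'   dropped; they carry no information).
#' @param b bias, strictly inside (-0.5, 0.5).
#' @param phi overdispersion, >= 0.
#' @return The log-likelihood (scalar).
#' @export
loglikBetaBinom <- function(data, b, phi) {
    if (b <= -0.5 || b >= 0.5) stop("b outside (-0.5, 0.5)")
    if (phi < 0) stop("phi must be non-negative")
    d <- .asNK(data)
    n <- d$n; k <- d$k
    stopifnot(all(k >= 0), all(k <= n))
    if (phi < .PHI_EPS)
        return(sum(dbinom(k, n, 0.5 + b, log = TRUE)))
    a <- (0.5 + b) / phi
    be <- (0.5 - b) / phi
    sum(lchoose(n, k) + lbeta(k + a, n - k + be) - lbeta(a, be))
}

## Vectorized internal version on (n, k) vectors; theta on the working
## scale (qlogis(0.5 + b), log phi).
.bbLL <- function(n, k, b, phi) {
    if (phi < .PHI_EPS) return(sum(dbinom(k, n, 0.5 + b, log = TRUE)))
    a <- (0.5 + b) / phi; be <- (0.5 - b) / phi
    sum(lchoose(n, k) + lbeta(k + a, n - k + be) - lbeta(a, be))
}

.maximize <- function(fn, starts) {
    best <- NULL
    for (s in starts) {
        res <- tryCatch(
            if (length(s) == 1L)
                optim(s, fn, method = "Brent", lower = -25, upper = 10,
                      control = list(fnscale = -1))
            else
                optim(s, fn, control = list(fnscale = -1, maxit = 2000,
                                            reltol = 1e-10)),
            error = function(e) NULL)
        if (!is.null(res) && (is.null(best) || res$value > best$value))
            best <- res
    }
    if (is.null(best)) stop("optimization failed to converge")
    best
}

.bStarts <- function(n, k) {
    pHat <- sum(k) / sum(n)
    qlogis(min(max(pHat, 1e-4), 1 - 1e-4))
}

#' Fit a single-class mutation-placement model
#'
#' Maximum-likelihood fit of one of M1-M4 (see [loglikBetaBinom()]).
#' M2's bias has a closed-form estimate; M3 and M4 are maximized
#' numerically on the (logit, log) working scale with multiple starts,
#' and the `phi = 0` boundary is always evaluated so that estimates on
#' the boundary are found and flagged.
#'
#' @param data data.frame with columns `n`, `k`.
#' @param model `"M1"`, `"M2"`, `"M3"` or `"M4"`.
#' @return A [BetaBinomFit-class].
#' @export
fitMutationModel <- function(data, model = c("M4", "M1", "M2", "M3")) {
    model <- match.arg(model)
    d <- .asNK(data)
    n <- d$n; k <- d$k
    if (!length(n)) stop("no genes with n >= 1")
    if (model %in% c("M3", "M4") && !any(n >= 2))
        stop(model, " needs at least one gene with n >= 2")
    boundary <- FALSE
    if (model == "M1") {
        b <- NA_real_; phi <- NA_real_; df <- 0L
        ll <- .bbLL(n, k, 0, 0)
    } else if (model == "M2") {
        pHat <- sum(k) / sum(n)
        boundary <- pHat <= 0 || pHat >= 1
        pHat <- min(max(pHat, 1e-9), 1 - 1e-9)
        b <- pHat - 0.5; phi <- NA_real_; df <- 1L
        ll <- .bbLL(n, k, b, 0)
    } else if (model == "M3") {
        opt <- .maximize(function(t) .bbLL(n, k, 0, exp(t)),
                         list(log(0.05), log(0.5), log(2)))
        ll0 <- .bbLL(n, k, 0, 0)
        if (ll0 >= opt$value) {
            b <- NA_real_; phi <- 0; ll <- ll0; boundary <- TRUE
        } else {
            b <- NA_real_; phi <- exp(opt$par); ll <- opt$value
        }
        df <- 1L
    } else {
        t1 <- .bStarts(n, k)
        opt <- .maximize(function(t) .bbLL(n, k, plogis(t[1]) - 0.5,
                                           exp(t[2])),
                         list(c(t1, log(0.05)), c(t1, log(0.5)),
                              c(0, log(0.1))))
        ## phi = 0 boundary candidate (the M2 maximum)
        pHat <- min(max(sum(k) / sum(n), 1e-9), 1 - 1e-9)
        llB <- .bbLL(n, k, pHat - 0.5, 0)
        if (llB >= opt$value) {
            b <- pHat - 0.5; phi <- 0; ll <- llB; boundary <- TRUE
        } else {
            b <- plogis(opt$par[1]) - 0.5; phi <- exp(opt$par[2])
            ll <- opt$value
        }
        df <- 2L
    }
    new("BetaBinomFit", model = model, b = b, phi = phi, logLik = ll,
        df = df, nGenes = length(n), boundary = boundary)
}

.lrt <- function(fitNull, fitAlt, label) {
    stat <- 2 * (fitAlt@logLik - fitNull@logLik)
    if (stat < -1e-6)
        stop("log-likelihood decreased from ", fitNull@model, " to ",
             fitAlt@model, "; optimizer failure")
    stat <- max(stat, 0)
    df <- fitAlt@df - fitNull@df
    data.frame(comparison = label, statistic = stat, df = df,
               p = pchisq(stat, df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
}

#' Hierarchical likelihood-ratio model selection (M1-M4)
#'
#' Steps up the lattice M1 -> {M2, M3} -> M4 with chi-square LRTs at
#' level `alpha` (degrees of freedom = difference in free parameters).
#' If neither one-parameter extension improves on M1, the direct
#' two-parameter test M1 vs M4 is also tried.  The chi-square reference
#' for tests freeing `phi` is conservative because `phi = 0` sits on the
#' parameter boundary; `boundaryMixture = TRUE` halves those p-values
#' (the 0.5 chi2(0) + 0.5 chi2(1) mixture).
#'
#' @param data data.frame with columns `n`, `k`.
#' @param alpha test level.
#' @param boundaryMixture use the boundary mixture reference for phi
#'   tests.
#' @return List: `model` (chosen id), `fits` (list of the four
#'   [BetaBinomFit-class] objects), `trail` (data.frame of the tests
#'   performed).
#' @export
selectModelHlrt <- function(data, alpha = 0.05, boundaryMixture = FALSE) {
    fits <- list(M1 = fitMutationModel(data, "M1"),
                 M2 = fitMutationModel(data, "M2"),
                 M3 = fitMutationModel(data, "M3"),
                 M4 = fitMutationModel(data, "M4"))
    adjPhi <- function(row) {
        if (boundaryMixture) row$p <- row$p / 2
        row
    }
    t12 <- .lrt(fits$M1, fits$M2, "M1 vs M2")
    t13 <- adjPhi(.lrt(fits$M1, fits$M3, "M1 vs M3"))
    trail <- rbind(t12, t13)
    sig2 <- t12$p < alpha; sig3 <- t13$p < alpha
    if (!sig2 && !sig3) {
        t14 <- .lrt(fits$M1, fits$M4, "M1 vs M4")
        trail <- rbind(trail, t14)
        model <- if (t14$p < alpha) "M4" else "M1"
    } else {
        inter <- if (sig2 && sig3) {
            if (fits$M2@logLik >= fits$M3@logLik) "M2" else "M3"
        } else if (sig2) "M2" else "M3"
        t4 <- .lrt(fits[[inter]], fits$M4, paste(inter, "vs M4"))
        if (inter == "M2") t4 <- adjPhi(t4)
        trail <- rbind(trail, t4)
        model <- if (t4$p < alpha) "M4" else inter
    }
    list(model = model, fits = fits, trail = trail)
}

#' Joint SYN/DEL model fits and selection
#'
#' Fits the four joint models of the synonymous and deleterious
#' mutation classes: `joint_null` (shared `b` and `phi`), `joint_b`
#' (class-specific bias, shared `phi`), `joint_phi` (shared bias,
#' class-specific `phi`) and `joint_both` (all four parameters free),
#' then selects among them by hierarchical LRTs at level `alpha`.
#' Reported `Delta` quantities are `b_DEL - b_SYN` and
#' `phi_DEL - phi_SYN` from the fully free fit.
#'
#' @param syn,del data.frames with columns `n`, `k` for each class.
#' @param alpha test level.
#' @return List: `model` (selected id), `fit` (a [BetaBinomFit-class]
#'   of the fully free model, with per-class estimates and deltas),
#'   `logLik` (named vector over the four joint models), `trail`.
#' @export
fitJointSynDel <- function(syn, del, alpha = 0.05) {
    ds <- .asNK(syn); dd <- .asNK(del)
    if (!length(ds$n)) stop("empty SYN table")
    if (!length(dd$n)) stop("empty DEL table")
    if (!any(ds$n >= 2) || !any(dd$n >= 2))
        stop("each class needs a gene with n >= 2 to free phi")

    ## fully free: two independent M4 fits
    fS <- fitMutationModel(data.frame(n = ds$n, k = ds$k), "M4")
    fD <- fitMutationModel(data.frame(n = dd$n, k = dd$k), "M4")
    llBoth <- fS@logLik + fD@logLik

    llFun <- function(bS, phiS, bD, phiD)
        .bbLL(ds$n, ds$k, bS, phiS) + .bbLL(dd$n, dd$k, bD, phiD)
    tS <- .bStarts(ds$n, ds$k); tD <- .bStarts(dd$n, dd$k)

    optNull <- .maximize(function(t) llFun(plogis(t[1]) - 0.5, exp(t[2]),
                                           plogis(t[1]) - 0.5, exp(t[2])),
                         list(c((tS + tD) / 2, log(0.1)),
                              c(0, log(0.5))))
    optB <- .maximize(function(t) llFun(plogis(t[1]) - 0.5, exp(t[3]),
                                        plogis(t[2]) - 0.5, exp(t[3])),
                      list(c(tS, tD, log(0.1)),
                           c(optNull$par[1], optNull$par[1],
                             optNull$par[2])))
    optPhi <- .maximize(function(t) llFun(plogis(t[1]) - 0.5, exp(t[2]),
                                          plogis(t[1]) - 0.5, exp(t[3])),
                        list(c((tS + tD) / 2, log(0.1), log(0.1)),
                             c(optNull$par[1], optNull$par[2],
                               optNull$par[2])))
    ll <- c(joint_null = optNull$value,
            joint_b = max(optB$value, optNull$value),
            joint_phi = max(optPhi$value, optNull$value),
            joint_both = max(llBoth, optB$value, optPhi$value,
                             optNull$value))
    dfs <- c(joint_null = 2L, joint_b = 3L, joint_phi = 3L, joint_both = 4L)

    mkFit <- function(id) new("BetaBinomFit", model = id, b = NA_real_,
                              phi = NA_real_, logLik = ll[[id]],
                              df = dfs[[id]],
                              nGenes = length(ds$n) + length(dd$n))
    tB <- .lrt(mkFit("joint_null"), mkFit("joint_b"), "null vs free b")
    tP <- .lrt(mkFit("joint_null"), mkFit("joint_phi"), "null vs free phi")
    trail <- rbind(tB, tP)
    sigB <- tB$p < alpha; sigP <- tP$p < alpha
    if (!sigB && !sigP) {
        tBoth <- .lrt(mkFit("joint_null"), mkFit("joint_both"),
                      "null vs free both")
        trail <- rbind(trail, tBoth)
        model <- if (tBoth$p < alpha) "joint_both" else "joint_null"
    } else {
        inter <- if (sigB && sigP) {
            if (ll[["joint_b"]] >= ll[["joint_phi"]]) "joint_b"
            else "joint_phi"
        } else if (sigB) "joint_b" else "joint_phi"
        t4 <- .lrt(mkFit(inter), mkFit("joint_both"),
                   paste(inter, "vs free both"))
        trail <- rbind(trail, t4)
        model <- if (t4$p < alpha) "joint_both" else inter
    }

    fit <- new("BetaBinomFit", model = model, b = NA_real_, phi = NA_real_,
               logLik = ll[[model]], df = dfs[[model]],
               nGenes = length(ds$n) + length(dd$n),
               perClass = list(SYN = c(b = fS@b, phi = fS@phi),
                               DEL = c(b = fD@b, phi = fD@phi)))
    attr(fit, "delta") <- c(db = fD@b - fS@b, dphi = fD@phi - fS@phi)
    list(model = model, fit = fit, logLik = ll, trail = trail,
         delta = c(db = fD@b - fS@b, dphi = fD@phi - fS@phi))
}

#' Percentile bootstrap confidence intervals
#'
#' Genes (the likelihood unit) are resampled with replacement and the
#' model refitted; 2.5/97.5 percentile bounds are reported.  With `del`
#' supplied, both classes are resampled and the per-class parameters and
#' their differences (`db`, `dphi`) are bootstrapped.  Replicates whose
#' fit fails are redrawn (count logged).
#'
#' @param data data.frame with columns `n`, `k` (SYN class for joint
#'   bootstraps).
#' @param model single-class model id (ignored when `del` is given; the
#'   fully free joint model is used).
#' @param reps bootstrap replicates (>= 100 recommended).
#' @param seed integer seed.
#' @param del optional DEL-class data.frame for joint bootstraps.
#' @return A [BetaBinomFit-class] with the `ci` slot filled; the matrix
#'   of replicate estimates is attached as attribute `"replicates"`.
#' @export
bootstrapCI <- function(data, model = "M4", reps = 1000, seed = 1L,
                        del = NULL) {
    set.seed(as.integer(seed))
    if (reps < 2)
        warning("reps < 2: degenerate interval equal to the point estimate")
    redrawn <- 0L
    if (is.null(del)) {
        fit <- fitMutationModel(data, model)
        d <- data[data$n > 0, , drop = FALSE]
        one <- function() {
            repeat {
                idx <- sample(nrow(d), replace = TRUE)
                f <- tryCatch(fitMutationModel(d[idx, , drop = FALSE], model),
                              error = function(e) NULL)
                if (!is.null(f)) return(c(b = f@b, phi = f@phi))
                redrawn <<- redrawn + 1L
            }
        }
        est <- c(b = fit@b, phi = fit@phi)
    } else {
        jt <- fitJointSynDel(data, del)
        fit <- jt$fit
        dS <- data[data$n > 0, , drop = FALSE]
        dD <- del[del$n > 0, , drop = FALSE]
        one <- function() {
            repeat {
                iS <- sample(nrow(dS), replace = TRUE)
                iD <- sample(nrow(dD), replace = TRUE)
                f <- tryCatch({
                    fS <- fitMutationModel(dS[iS, , drop = FALSE], "M4")
                    fD <- fitMutationModel(dD[iD, , drop = FALSE], "M4")
                    c(b_SYN = fS@b, phi_SYN = fS@phi, b_DEL = fD@b,
                      phi_DEL = fD@phi, db = fD@b - fS@b,
                      dphi = fD@phi - fS@phi)
                }, error = function(e) NULL)
                if (!is.null(f)) return(f)
                redrawn <<- redrawn + 1L
            }
        }
        pc <- fit@perClass
        est <- c(b_SYN = pc$SYN[["b"]], phi_SYN = pc$SYN[["phi"]],
                 b_DEL = pc$DEL[["b"]], phi_DEL = pc$DEL[["phi"]],
                 db = pc$DEL[["b"]] - pc$SYN[["b"]],
                 dphi = pc$DEL[["phi"]] - pc$SYN[["phi"]])
    }
    proto <- one()
    mat <- rbind(proto,
                 t(vapply(seq_len(max(reps, 1) - 1L), function(i) one(),
                          proto)))
    est <- est[!is.na(est)]
    mat <- mat[, names(est), drop = FALSE]
    rownames(mat) <- NULL
    if (redrawn > 0) message(redrawn, " bootstrap replicate(s) redrawn")
    ci <- t(apply(mat, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE))
    colnames(ci) <- c("2.5%", "97.5%")
    if (reps < 2) ci[] <- cbind(est, est)
    fit@ci <- ci
    attr(fit, "replicates") <- mat
    fit
}

#' Proportion of deleterious mutations per genome/subgenome
#'
#' `proportion = DEL / annotated sites`, computed per (group,
#' accession); relative to the total of annotated sites so that missing
#' data cancels.
#'
#' @param annotation data.frame with columns `group` (species, population
#'   or subgenome label), `accession`, `del`, `annotated`.
#' @return data.frame `group`, `accession`, `proportion`; rows with zero
#'   annotated sites are excluded with a message.
#' @export
proportionDeleterious <- function(annotation) {
    need <- c("group", "accession", "del", "annotated")
    if (!all(need %in% colnames(annotation)))
        stop("missing column(s): ",
             paste(setdiff(need, colnames(annotation)), collapse = ", "))
    zero <- annotation$annotated == 0
    if (any(zero))
        message(sum(zero), " row(s) with zero annotated sites excluded")
    a <- annotation[!zero, , drop = FALSE]
    data.frame(group = a$group, accession = a$accession,
               proportion = a$del / a$annotated,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' @importFrom stats dbinom plogis qlogis
NULL
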