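test_that("the beta-binomial log-likelihood matches analytic anchors", {
    ## B(2, 0.5) at k = 1 has probability 0.5
    expect_equal(loglikBetaBinom(data.frame(n = 2, k = 1), b = 0, phi = 0),
                 log(0.5))
    ## n = 1 carries no overdispersion information: log(0.5) for any phi
    for (phi in c(0, 0.3, 2))
        expect_equal(loglikBetaBinom(data.frame(n = 1, k = 1), 0, phi),
                     log(0.5))
    expect_error(loglikBetaBinom(data.frame(n = 2, k = 1), b = 0.7, 0),
                 "outside")
    expect_error(loglikBetaBinom(data.frame(n = 2, k = 1), 0, -1),
                 "non-negative")
})

test_that("the log-likelihood equals an independent log-gamma oracle", {
    set.seed(601)
    for (i in 1:20) {
        n <- sample(1:30, 5, replace = TRUE)
        k <- vapply(n, function(nn) sample(0:nn, 1), 0L)
        b <- runif(1, -0.4, 0.4); phi <- runif(1, 0.01, 2)
        expect_equal(loglikBetaBinom(data.frame(n = n, k = k), b, phi),
                     sum(bbLogPmfOracle(k, n, b, phi)))
    }
})

test_that("the beta-binomial pmf sums to one", {
    set.seed(602)
    for (i in 1:15) {
        n <- sample(1:25, 1)
        b <- runif(1, -0.45, 0.45); phi <- runif(1, 0, 3)
        ll <- vapply(0:n, function(k)
            loglikBetaBinom(data.frame(n = n, k = k), b, phi), 0)
        expect_equal(sum(exp(ll)), 1)
    }
})

test_that("phi -> 0 converges to the binomial likelihood", {
    set.seed(603)
    n <- sample(1:10, 20, replace = TRUE)
    k <- rbinom(20, n, 0.55)
    d <- data.frame(n = n, k = k)
    llBin <- loglikBetaBinom(d, 0.05, 0)
    llNear <- sum(bbLogPmfOracle(k, n, 0.05, 1e-8))
    expect_lt(abs(llBin - llNear), 1e-6)
})

test_that("M2 recovers the null bias within two standard errors", {
    m <- simulateMutations(MutationScenario(nGenes = 5000, b = 0, phi = 0,
                                            meanMutations = 5), seed = 604)
    fit <- fitMutationModel(m$counts, "M2")
    se <- sqrt(0.25 / sum(m$counts$n))
    expect_lt(abs(fit@b), 2 * se)
    expect_false(fit@boundary)
})

test_that("M4 recovers (b, phi) and the bootstrap covers the truth", {
    m <- simulateMutations(MutationScenario(nGenes = 2000, b = 0.1,
                                            phi = 0.2, meanMutations = 10),
                           seed = 605)
    fit <- bootstrapCI(m$counts, "M4", reps = 100, seed = 606)
    expect_equal(fit@b, 0.1, tolerance = 0.03)
    expect_equal(fit@phi, 0.2, tolerance = 0.1)
    expect_true(fit@ci["b", 1] <= 0.1 && fit@ci["b", 2] >= 0.1)
    expect_true(fit@ci["phi", 1] <= 0.2 && fit@ci["phi", 2] >= 0.2)
})

test_that("degenerate all-successes data hits the boundary and is flagged", {
    d <- data.frame(n = rep(3, 20), k = rep(3, 20))
    fit <- fitMutationModel(d, "M2")
    expect_true(fit@boundary)
    expect_gt(fit@b, 0.49)
})

test_that("log-likelihoods respect the model nesting on random datasets", {
    set.seed(607)
    for (i in 1:8) {
        b <- runif(1, -0.2, 0.2); phi <- runif(1, 0, 0.6)
        m <- simulateMutations(MutationScenario(nGenes = 400, b = b,
                                                phi = phi,
                                                meanMutations = 6),
                               seed = 607 + i)
        f <- lapply(c("M1", "M2", "M3", "M4"), fitMutationModel,
                    data = m$counts)
        ll <- vapply(f, function(x) x@logLik, 0)
        tol <- 1e-6
        expect_gte(ll[2] + tol, ll[1])  # M2 >= M1
        expect_gte(ll[3] + tol, ll[1])  # M3 >= M1
        expect_gte(ll[4] + tol, ll[2])  # M4 >= M2
        expect_gte(ll[4] + tol, ll[3])  # M4 >= M3
    }
})

test_that("models needing overdispersion require a gene with n >= 2", {
    d <- data.frame(n = rep(1, 10), k = rbinom(10, 1, 0.5))
    expect_error(fitMutationModel(d, "M3"), "n >= 2")
    expect_error(fitMutationModel(d, "M4"), "n >= 2")
    expect_silent(fitMutationModel(d, "M2"))
    expect_error(fitMutationModel(data.frame(n = integer(), k = integer()),
                                  "M1"), "no genes")
})

test_that("the hierarchical LRT keeps M1 on null data and finds M4", {
    set.seed(608)
    chosen <- vapply(1:40, function(i) {
        m <- simulateMutations(MutationScenario(nGenes = 300, b = 0,
                                                phi = 0, meanMutations = 6),
                               seed = 7000 + i)
        selectModelHlrt(m$counts)$model
    }, "")
    expect_gt(mean(chosen == "M1"), 0.8)

    m4 <- simulateMutations(MutationScenario(nGenes = 5000, b = 0.15,
                                             phi = 0.5, meanMutations = 8),
                            seed = 609)
    sel <- selectModelHlrt(m4$counts)
    expect_equal(sel$model, "M4")
    expect_true(all(c("statistic", "df", "p") %in% colnames(sel$trail)))
})

test_that("joint SYN/DEL selection keeps the shared model when parameters
           are equal and recovers negative deltas otherwise", {
    syn <- simulateMutations(MutationScenario(nGenes = 1500, b = 0.1,
                                              phi = 0.3, meanMutations = 8),
                             seed = 610)
    delSame <- simulateMutations(MutationScenario(nGenes = 1500, b = 0.1,
                                                  phi = 0.3,
                                                  meanMutations = 8,
                                                  class = "DEL"),
                                 seed = 611)
    jtSame <- fitJointSynDel(syn$counts, delSame$counts)
    expect_equal(jtSame$model, "joint_null")

    ## the regime reported for deleterious mutations: smaller bias and
    ## smaller overdispersion than synonymous ones
    delLess <- simulateMutations(MutationScenario(nGenes = 1500, b = 0.02,
                                                  phi = 0.05,
                                                  meanMutations = 8,
                                                  class = "DEL"),
                                 seed = 612)
    jt <- fitJointSynDel(syn$counts, delLess$counts)
    expect_lt(jt$delta[["db"]], 0)
    expect_lt(jt$delta[["dphi"]], 0)
    expect_true(jt$model %in% c("joint_b", "joint_phi", "joint_both"))

    expect_error(fitJointSynDel(syn$counts,
                                data.frame(n = integer(), k = integer())),
                 "empty DEL")
})

test_that("bootstraps are deterministic given the seed and degenerate at
           one replicate", {
    m <- simulateMutations(MutationScenario(nGenes = 400, b = 0.05,
                                            phi = 0.1, meanMutations = 6),
                           seed = 613)
    b1 <- bootstrapCI(m$counts, "M2", reps = 60, seed = 614)
    b2 <- bootstrapCI(m$counts, "M2", reps = 60, seed = 614)
    expect_identical(b1@ci, b2@ci)
    expect_warning(b0 <- bootstrapCI(m$counts, "M2", reps = 1, seed = 615),
                   "degenerate")
    expect_equal(unname(b0@ci["b", 1]), b0@b)
})

test_that("joint bootstrap reports per-class parameters and deltas", {
    syn <- simulateMutations(MutationScenario(nGenes = 400, b = 0.1,
                                              phi = 0.3, meanMutations = 8),
                             seed = 616)
    del <- simulateMutations(MutationScenario(nGenes = 400, b = 0,
                                              phi = 0.05, meanMutations = 8,
                                              class = "DEL"), seed = 617)
    bc <- bootstrapCI(syn$counts, reps = 30, seed = 618, del = del$counts)
    expect_setequal(rownames(bc@ci),
                    c("b_SYN", "phi_SYN", "b_DEL", "phi_DEL", "db", "dphi"))
    expect_lt(bc@ci["db", 2], 0.05)  # db clearly negative-ish
})

test_that("deleterious proportions are ratios to annotated sites", {
    ann <- data.frame(group = c("Cbp_Co", "Cbp_Cg", "CG"),
                      accession = "a1",
                      del = c(10L, 6L, 2L),
                      annotated = c(1000L, 1000L, 0L))
    expect_message(pr <- proportionDeleterious(ann), "zero annotated")
    expect_equal(pr$proportion[pr$group == "Cbp_Co"], 0.01)
    expect_false("CG" %in% pr$group)
    expect_error(proportionDeleterious(ann[, -3]), "missing column")

    ## ordering recovery: planted Co > Cg proportion in every accession
    set.seed(619)
    acc <- paste0("a", 1:8)
    sim <- rbind(data.frame(group = "Cbp_Co", accession = acc,
                            del = rbinom(8, 10000, 0.012),
                            annotated = 10000L),
                 data.frame(group = "Cbp_Cg", accession = acc,
                            del = rbinom(8, 10000, 0.008),
                            annotated = 10000L))
    pr2 <- proportionDeleterious(sim)
    co <- pr2$proportion[pr2$group == "Cbp_Co"]
    cg <- pr2$proportion[pr2$group == "Cbp_Cg"]
    expect_true(all(co > cg))
})
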