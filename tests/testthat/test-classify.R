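## Helpers to enumerate direction vectors
dirLevels <- c("up", "down", "ns")

randomMeans <- function() abs(rnorm(4, 100, 50)) + 1

test_that("unphased classification reproduces the canonical patterns", {
    ## all ns -> no difference
    r <- classifyUnphased("ns", "ns", "ns", 10, 10, 10)
    expect_equal(r$category, "no_difference")
    ## Cbp = CO, Cbp != CG, CG != CO -> dominance of CO
    r <- classifyUnphased("down", "ns", "up", 10, 20, 10)
    expect_equal(r$category, "dominance_CO")
    ## mirrored dominance
    r <- classifyUnphased("ns", "up", "up", 20, 20, 10)
    expect_equal(r$category, "dominance_CG")
    ## Cbp above both parents, significant vs the closer one
    r <- classifyUnphased("up", "up", "up", 40, 20, 10)
    expect_equal(r$category, "transgressive")
    ## Cbp strictly between, different from both
    r <- classifyUnphased("down", "up", "up", 15, 20, 10)
    expect_equal(r$category, "intermediate")
})

test_that("unphased classification is total over all 27 direction vectors", {
    set.seed(201)
    grid <- expand.grid(a = dirLevels, b = dirLevels, c = dirLevels,
                        stringsAsFactors = FALSE)
    for (rep in 1:5) {
        m <- randomMeans()
        r <- classifyUnphased(grid$a, grid$b, grid$c,
                              rep(m[1], 27), rep(m[2], 27), rep(m[3], 27))
        expect_false(any(is.na(r$category)))
        expect_true(all(r$category %in% c("no_difference", "intermediate",
                                          "dominance_CG", "dominance_CO",
                                          "transgressive")))
    }
})

test_that("phased classification reproduces the seven canonical patterns", {
    ## contrasts: CG:CO, Cg:Co, Cg:CG, Cg:CO, Co:CG, Co:CO
    expect_equal(classifyPhased("ns", "ns", "ns", "ns", "ns", "ns",
                                10, 10, 10, 10)$category, "no_difference")
    ## legacy: parents differ, each subgenome tracks its own parent
    r <- classifyPhased("up", "up", "ns", "up", "down", "ns",
                        meanCG = 40, meanCO = 10, meanCg = 40, meanCo = 10)
    expect_equal(r$category, "legacy")
    ## reverse
    r <- classifyPhased("up", "down", "down", "ns", "ns", "up",
                        meanCG = 40, meanCO = 10, meanCg = 10, meanCo = 40)
    expect_equal(r$category, "reverse")
    ## compensatory drift: parents equal, subgenomes diverge
    r <- classifyPhased("ns", "up", "up", "up", "down", "down",
                        meanCG = 20, meanCO = 20, meanCg = 30, meanCo = 10)
    expect_equal(r$category, "compensatory_drift")
    ## dominance of the CG background (6a by default)
    r <- classifyPhased("up", "ns", "ns", "up", "ns", "up",
                        meanCG = 40, meanCO = 10, meanCg = 40, meanCo = 40)
    expect_equal(r$category, "dominance")
    expect_equal(r$subcategory, "6a")
    ## the same pattern towards CO is 6b
    r <- classifyPhased("up", "ns", "down", "ns", "down", "ns",
                        meanCG = 40, meanCO = 10, meanCg = 10, meanCo = 10)
    expect_equal(r$subcategory, "6b")
    ## intermediate: both subgenomes strictly inside, different from both
    r <- classifyPhased("up", "ns", "down", "up", "down", "up",
                        meanCG = 40, meanCO = 10, meanCg = 25, meanCo = 25)
    expect_equal(r$category, "intermediate")
    ## transgressive: one subgenome above both parents
    r <- classifyPhased("up", "up", "up", "up", "ns", "up",
                        meanCG = 40, meanCO = 10, meanCg = 90, meanCo = 40)
    expect_equal(r$category, "transgressive")
    expect_equal(r$subcategory, "7a")
})

test_that("the phased decision table is total over all 729 vectors", {
    set.seed(202)
    grid <- expand.grid(d1 = dirLevels, d2 = dirLevels, d3 = dirLevels,
                        d4 = dirLevels, d5 = dirLevels, d6 = dirLevels,
                        stringsAsFactors = FALSE)
    for (rep in 1:3) {
        m <- randomMeans()
        r <- classifyPhased(grid$d1, grid$d2, grid$d3, grid$d4, grid$d5,
                            grid$d6, rep(m[1], 729), rep(m[2], 729),
                            rep(m[3], 729), rep(m[4], 729))
        expect_equal(nrow(r), 729)
        expect_false(any(is.na(r$category)))
        expect_true(all(r$category %in% c("no_difference", "legacy",
                                          "reverse", "intermediate",
                                          "compensatory_drift", "dominance",
                                          "transgressive", "ambiguous")))
    }
})

test_that("swapping parental and subgenome labels maps categories correctly", {
    set.seed(203)
    grid <- expand.grid(d1 = dirLevels, d2 = dirLevels, d3 = dirLevels,
                        d4 = dirLevels, d5 = dirLevels, d6 = dirLevels,
                        stringsAsFactors = FALSE)
    flip <- c(up = "down", down = "up", ns = "ns")
    m <- randomMeans()
    orig <- classifyPhased(grid$d1, grid$d2, grid$d3, grid$d4, grid$d5,
                           grid$d6, rep(m[1], 729), rep(m[2], 729),
                           rep(m[3], 729), rep(m[4], 729))
    ## CG<->CO and Cg<->Co: CG':CO' = flip(CG:CO), Cg':Co' = flip(Cg:Co),
    ## Cg':CG' = Co:CO, Cg':CO' = Co:CG, Co':CG' = Cg:CO, Co':CO' = Cg:CG
    sw <- classifyPhased(unname(flip[grid$d1]), unname(flip[grid$d2]),
                         grid$d6, grid$d5, grid$d4, grid$d3,
                         rep(m[2], 729), rep(m[1], 729),
                         rep(m[4], 729), rep(m[3], 729))
    expect_equal(sw$category, orig$category)
    subSwap <- c("6a" = "6b", "6b" = "6a", "7a" = "7b", "7b" = "7a",
                 "7c" = "7c")
    expSub <- ifelse(orig$subcategory == "", "",
                     unname(subSwap[orig$subcategory]))
    expect_equal(sw$subcategory, expSub)
})

test_that("classification recovers scenario proportions under perfect power", {
    sc <- RegulatoryScenario(nGenes = 4000)
    truth <- simulateExpression(sc, seed = 204)$truth
    ## perfect-power calls straight from the true means
    d <- truth
    r <- classifyPhased(trueDirection(d$muCG, d$muCO),
                        trueDirection(d$muCg, d$muCo),
                        trueDirection(d$muCg, d$muCG),
                        trueDirection(d$muCg, d$muCO),
                        trueDirection(d$muCo, d$muCG),
                        trueDirection(d$muCo, d$muCO),
                        d$muCG, d$muCO, d$muCg, d$muCo, gene = d$gene)
    map <- c(no_difference = "no_difference", legacy = "legacy",
             reverse = "reverse", intermediate = "intermediate",
             dominance_CO = "dominance", dominance_CG = "dominance",
             compensatory_drift = "compensatory_drift",
             transgressive_one = "transgressive",
             transgressive_both = "transgressive")
    expected <- unname(map[truth$category])
    expect_gt(mean(r$category == expected), 0.95)
})

test_that("tissue conservation flags and pairwise agreement are computed", {
    asg <- data.frame(gene = rep(c("g1", "g2", "g3"), each = 3),
                      tissue = rep(c("flower", "leaf", "root"), 3),
                      category = c(rep("no_difference", 3),
                                   c("legacy", "legacy", "dominance"),
                                   c("reverse", "reverse", "reverse")))
    tc <- tissueConservation(asg)
    expect_equal(tc$perGene$conserved[tc$perGene$gene == "g1"], TRUE)
    expect_equal(tc$perGene$conserved[tc$perGene$gene == "g2"], FALSE)
    expect_equal(tc$pairwise["flower", "leaf"], 1)
    expect_equal(tc$pairwise["leaf", "root"], 2 / 3)
})

test_that("agreement under independent shuffles matches sum of squared freqs", {
    set.seed(205)
    cats <- c("a", "b", "c")
    p <- c(0.5, 0.3, 0.2)
    n <- 4000
    asg <- data.frame(gene = rep(sprintf("g%04d", 1:n), 2),
                      tissue = rep(c("t1", "t2"), each = n),
                      category = c(sample(cats, n, TRUE, p),
                                   sample(cats, n, TRUE, p)))
    tc <- tissueConservation(asg)
    expect_equal(tc$pairwise["t1", "t2"], sum(p^2), tolerance = 0.03)
})

test_that("a gene missing from one tissue is flagged partial", {
    asg <- data.frame(gene = c("g1", "g1", "g2"),
                      tissue = c("t1", "t2", "t1"),
                      category = "legacy")
    tc <- tissueConservation(asg)
    expect_true(tc$perGene$partial[tc$perGene$gene == "g2"])
    expect_true(tc$perGene$conserved[tc$perGene$gene == "g2"])
})

test_that("category proportions renormalize over DE genes only", {
    asg <- data.frame(category = c(rep("no_difference", 60),
                                   rep("legacy", 25),
                                   rep("dominance", 15)),
                      subcategory = c(rep("", 85), rep("6a", 10),
                                      rep("6b", 5)))
    pr <- categoryProportions(asg)
    expect_equal(pr$prop_all[pr$category == "no_difference"], 0.6)
    expect_equal(pr$prop_de_only[pr$category == "legacy"], 25 / 40)
    expect_true(is.na(pr$prop_de_only[pr$category == "no_difference"]))
    ds <- attr(pr, "dominanceShare")
    expect_equal(unname(ds[["6a"]]), 2 / 3)
    expect_error(categoryProportions(asg[0, ]), "no classified")
    one <- categoryProportions(data.frame(category = rep("legacy", 5)))
    expect_equal(one$prop_all, 1)
})
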