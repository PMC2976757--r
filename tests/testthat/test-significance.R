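test_that("dispersion is the RMS correlation change over pairs", {
    C <- randomCorMatrix(6)
    expect_equal(dispersion(corSet(C, C), rownames(C)), 0)

    # single pair flipping from +1 to -1: sqrt(((1 - (-1))^2)/2) = sqrt(2),
    # the maximum of the statistic
    expect_equal(dispersion(corSet(cor2(1), cor2(-1)), c("g1", "g2")),
                 sqrt(2), tolerance = 1e-12)

    set.seed(8)
    C1 <- randomCorMatrix(10); C2 <- randomCorMatrix(10)
    genes <- rownames(C1)
    expect_equal(dispersion(corSet(C1, C2), genes),
                 bruteDispersion(C1, C2, genes), tolerance = 1e-12)
    # invariant under gene reordering
    expect_equal(dispersion(corSet(C1, C2), rev(genes)),
                 dispersion(corSet(C1, C2), genes))
    expect_error(dispersion(corSet(C1, C2), c("g1", "nope")), "nope")
    expect_error(dispersion(corSet(C1, C2), "g1"), "at least 2")
})

test_that("between-set dispersion covers cross pairs only and is symmetric", {
    set.seed(9)
    C1 <- randomCorMatrix(9); C2 <- randomCorMatrix(9)
    A <- paste0("g", 1:4); B <- paste0("g", 5:9)
    expect_equal(dispersionBetween(corSet(C1, C2), A, B),
                 bruteDispersionBetween(C1, C2, A, B), tolerance = 1e-12)
    expect_equal(dispersionBetween(corSet(C1, C2), B, A),
                 dispersionBetween(corSet(C1, C2), A, B))
    expect_equal(dispersionBetween(corSet(C1, C1), A, B), 0)
    expect_error(dispersionBetween(corSet(C1, C2), A, c("g4", "g5")),
                 "overlap")
})

test_that("multi-condition dispersion reduces to the two-condition form", {
    set.seed(10)
    C1 <- randomCorMatrix(7); C2 <- randomCorMatrix(7); C3 <- randomCorMatrix(7)
    g <- rownames(C1)
    expect_equal(dispersion(corSet(C1, C2), g),
                 bruteDispersion(C1, C2, g), tolerance = 1e-12)
    expect_equal(dispersion(corSet(C1, C1, C1), g), 0)
    expect_gt(dispersion(corSet(C1, C2, C3), g), 0)
})

test_that("permutation p-values follow the exceedance-count convention", {
    pv <- permutationPValue(249, 1000)
    expect_equal(pv$p, 0.249)
    expect_equal(pv$text, "0.249")
    pv0 <- permutationPValue(0, 1000)
    expect_equal(pv0$p, 0)
    expect_equal(pv0$text, "< 0.001")
    expect_equal(permutationPValue(0, 200)$text, "< 0.005")
    expect_equal(permutationPValue(200, 200)$p, 1)
})

test_that("the permutation test is seed-reproducible and label-invariant", {
    sim <- simulateExpression(
        SimulationScenario(nBackground = 20L, blockSizes = c(15L, 15L),
                           withinCor = matrix(c(0.8, 0.8, 0, 0.8), 2, 2),
                           samplesPerCondition = c(15L, 15L)), seed = 3)
    lab <- moduleLabels(sim$truth)
    lab[lab == "block1"] <- "blue"; lab[lab == "block2"] <- "red"
    mods <- ModuleAssignment(lab)

    r1 <- permutationTest(sim$data, mods, nPerm = 100, seed = 7)
    r2 <- permutationTest(sim$data, mods, nPerm = 100, seed = 7)
    expect_identical(r1$nExceed, r2$nExceed)
    r3 <- permutationTest(sim$data, mods, nPerm = 100, seed = 8)
    expect_false(identical(r1$nExceed, r3$nExceed))

    # relabelling modules changes no dispersion value
    swapped <- lab
    swapped[lab == "blue"] <- "red"; swapped[lab == "red"] <- "blue"
    r4 <- permutationTest(sim$data, ModuleAssignment(swapped),
                          nPerm = 10, seed = 7)
    expect_equal(sort(r4$dispersion), sort(r1$dispersion))

    # the changed block is significant, the conserved one is not extreme
    blue <- r1[r1$targetType == "module" & r1$module1 == "blue", ]
    expect_equal(blue$pValue, 0)
    expect_equal(blue$pText, "< 0.01")
})

test_that("p-values are invariant to rescaling the dispersion statistic", {
    sim <- simulateExpression(
        SimulationScenario(nBackground = 25L, blockSizes = 15L,
                           withinCor = matrix(c(0.6, 0), 1, 2),
                           samplesPerCondition = c(12L, 12L)), seed = 4)
    mods <- ModuleAssignment(moduleLabels(sim$truth))
    r <- permutationTest(sim$data, mods, nPerm = 50, seed = 2,
                         returnNull = TRUE)
    null <- S4Vectors::metadata(r)$null
    for (const in c(0.1, 3, 1e6)) {
        expect_equal(colSums(const * null >= const * r$dispersion[1]),
                     setNames(r$nExceed, colnames(null)))
    }
})

test_that("an unassigned-only assignment warns and returns nothing", {
    x <- randomSet(p = 5, n = 6, seed = 5)
    grey <- ModuleAssignment(setNames(rep("grey", 5), rownames(x)))
    expect_warning(r <- permutationTest(x, grey, nPerm = 5), "no assigned")
    expect_equal(nrow(r), 0)
})

test_that("null p-values for pre-fixed gene sets are approximately uniform", {
    set.seed(100)
    ps <- replicate(60, {
        seed <- sample.int(1e6, 1)
        sim <- simulateExpression(
            SimulationScenario(nBackground = 30L,
                               samplesPerCondition = c(20L, 20L)),
            seed = seed)
        mods <- ModuleAssignment(setNames(
            c(rep("blue", 15), rep("grey", 15)), rownames(sim$data)))
        permutationTest(sim$data, mods, nPerm = 60, seed = seed + 1)$pValue
    })
    # Kolmogorov-Smirnov sanity check against uniformity
    expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("data-selected gene sets give anti-conservative p-values", {
    # the documented caveat: picking the most dispersed of many random
    # sets from null data, then testing it, yields a small p-value,
    # while the same test on a pre-fixed set is unremarkable
    sim <- simulateExpression(
        SimulationScenario(nBackground = 120L,
                           samplesPerCondition = c(15L, 15L)), seed = 6)
    cors <- computeCorrelations(sim$data)
    set.seed(60)
    sets <- replicate(40, sample(rownames(sim$data), 15), simplify = FALSE)
    obs <- vapply(sets, function(g) dispersion(cors, g), numeric(1))
    selected <- sets[[which.max(obs)]]
    prefixed <- sets[[1]]
    test1 <- function(genes) {
        lab <- setNames(rep("grey", nrow(sim$data)), rownames(sim$data))
        lab[genes] <- "blue"
        permutationTest(sim$data, ModuleAssignment(lab), nPerm = 100,
                        seed = 9)$pValue
    }
    pSel <- test1(selected); pFix <- test1(prefixed)
    expect_lt(pSel, 0.05)
    expect_lt(pSel, pFix)
})
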