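test_that("correlations are computed per condition from that condition's samples", {
    x <- randomSet(p = 4, n = 8, seed = 2)
    cors <- computeCorrelations(x, method = "pearson")
    cm <- correlationMatrices(cors)
    expect_named(cm, c("cond1", "cond2"))

    # textbook covariance / sd computation, gene pair by gene pair
    m <- assay(x)
    for (k in 1:2) {
        sel <- sampleConditions(x) == paste0("cond", k)
        for (i in 1:3) for (j in (i + 1):4) {
            a <- m[i, sel]; b <- m[j, sel]
            hand <- sum((a - mean(a)) * (b - mean(b))) /
                sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
            expect_equal(cm[[k]][i, j], hand, tolerance = 1e-12)
        }
    }
    expect_equal(diag(cm[[1]]), setNames(rep(1, 4), rownames(m)))
    expect_equal(cm[[1]], t(cm[[1]]))

    # duplicated gene rows correlate exactly 1 in every condition
    dup <- rbind(m, gDup = m[1, ])
    xd <- CoexDiffSet(dup, as.character(sampleConditions(x)))
    cd <- correlationMatrices(computeCorrelations(xd, "pearson"))
    expect_equal(cd[[1]]["g1", "gDup"], 1)
    expect_equal(cd[[2]]["g1", "gDup"], 1)

    # spearman equals pearson on ranks within each condition
    cs <- correlationMatrices(computeCorrelations(x, "spearman"))
    sel <- sampleConditions(x) == "cond1"
    ranks <- t(apply(m[, sel], 1, rank))
    expect_equal(cs[[1]], cor(t(ranks)), tolerance = 1e-12)
})

test_that("within-condition-constant genes error by default and drop on request", {
    x <- randomSet(p = 5, n = 6, seed = 4)
    m <- assay(x)
    m[2, sampleConditions(x) == "cond2"] <- 7   # constant in one condition
    xc <- CoexDiffSet(m, as.character(sampleConditions(x)))
    expect_error(computeCorrelations(xc), "g2")
    expect_warning(cors <- computeCorrelations(xc, dropConstant = TRUE), "g2")
    expect_false("g2" %in% rownames(correlationMatrices(cors)[[1]]))
    expect_true(all(is.finite(correlationMatrices(cors)[[1]])))
})

test_that("signed square is the odd sign-preserving square", {
    expect_identical(signedSquare(0), 0)
    expect_identical(signedSquare(-0.5), -0.25)
    expect_identical(signedSquare(1), 1)
    expect_identical(signedSquare(-1), -1)
    g <- seq(-1, 1, by = 0.01)
    expect_equal(signedSquare(-g), -signedSquare(g))
    expect_true(all(abs(signedSquare(g)) <= abs(g)))
})

test_that("standard adjacency matches the signed-squared change formula", {
    expect_equal(
        adjacency(differenceAdjacency(corSet(cor2(1), cor2(-1)),
                                      beta = 1))["g1", "g2"], 1)
    expect_equal(
        adjacency(differenceAdjacency(corSet(cor2(0.7), cor2(0.7)),
                                      beta = 5))["g1", "g2"], 0)
    # (0.5 * |0.81 - 0.01|)^2 = 0.16
    expect_equal(
        adjacency(differenceAdjacency(corSet(cor2(0.9), cor2(0.1)),
                                      beta = 2))["g1", "g2"],
        0.16, tolerance = 1e-12)

    three <- corSet(cor2(0.5), cor2(0.1), cor2(0))
    expect_error(differenceAdjacency(three, variant = "standard"),
                 "exactly 2 conditions")
    expect_error(differenceAdjacency(corSet(cor2(0.5), cor2(0.1)),
                                     beta = 0), "positive integer")
})

test_that("strict variant thresholds before differencing", {
    expect_equal(
        adjacency(differenceAdjacency(corSet(cor2(1), cor2(-1)),
                                      beta = 7, variant = "strict"))["g1", "g2"],
        1)
    # 0.5 * |0.9^4 - 0.3^4| = 0.324
    expect_equal(
        adjacency(differenceAdjacency(corSet(cor2(0.9), cor2(0.3)),
                                      beta = 4, variant = "strict"))["g1", "g2"],
        0.324, tolerance = 1e-12)
    # algebraic identity: strict at beta 2 == standard at beta 1
    for (s in 1:5) {
        set.seed(s)
        cors <- corSet(randomCorMatrix(6), randomCorMatrix(6))
        expect_equal(
            adjacency(differenceAdjacency(cors, beta = 2, variant = "strict")),
            adjacency(differenceAdjacency(cors, beta = 1)),
            tolerance = 1e-14)
    }
})

test_that("multi-condition adjacency reduces exactly to the two-condition form", {
    for (s in 1:100) {
        set.seed(s)
        p <- sample(3:8, 1)
        cors <- corSet(randomCorMatrix(p), randomCorMatrix(p))
        beta <- sample(1:8, 1)
        expect_lt(max(abs(
            adjacency(differenceAdjacency(cors, beta, variant = "multi")) -
            adjacency(differenceAdjacency(cors, beta)))), 1e-12)
    }

    C <- randomCorMatrix(5)
    expect_equal(max(adjacency(differenceAdjacency(
        corSet(C, C, C), beta = 3, variant = "multi"))), 0)

    # one pair with signed-squared values (1, 0, -1):
    # sqrt((1/4) * ((1-0)^2 + 0 + (-1-0)^2)) = sqrt(0.5)
    d <- adjacency(differenceAdjacency(
        corSet(cor2(1), cor2(0), cor2(-1)), beta = 1,
        variant = "multi"))["g1", "g2"]
    expect_equal(d, sqrt(0.5), tolerance = 1e-12)
})

test_that("TOM dissimilarity matches a naive triple-loop reference", {
    # empty network: no shared neighbours, maximal dissimilarity
    z <- matrix(0, 3, 3, dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
    Dz <- new("DifferenceAdjacency", adjacency = z, beta = 1L,
              variant = "standard")
    expect_equal(dissimilarity(tomDissimilarity(Dz)),
                 1 - diag(3) - 0 * z, ignore_attr = TRUE)

    # complete network on 3 genes: t12 = 1 - (1 + 1)/(2 + 1 - 1) = 0
    o <- 1 - diag(3); dimnames(o) <- dimnames(z)
    Do <- new("DifferenceAdjacency", adjacency = o, beta = 1L,
              variant = "standard")
    expect_equal(max(abs(dissimilarity(tomDissimilarity(Do)))), 0)

    for (p in c(20, 30)) {
        set.seed(p)
        D <- matrix(runif(p * p), p, p)
        D <- (D + t(D)) / 2; diag(D) <- 0
        dimnames(D) <- list(paste0("g", 1:p), paste0("g", 1:p))
        obj <- new("DifferenceAdjacency", adjacency = D, beta = 1L,
                   variant = "standard")
        T <- dissimilarity(tomDissimilarity(obj))
        expect_lt(max(abs(T - bruteTOM(D))), 1e-10)
        expect_true(all(T >= 0 & T <= 1))
        expect_equal(diag(T), setNames(rep(0, p), rownames(D)))
    }
})

test_that("no-TOM dissimilarity is the plain complement", {
    cors <- corSet(cor2(1), cor2(-1))
    D <- differenceAdjacency(cors, beta = 1)
    expect_equal(dissimilarity(noTomDissimilarity(D))["g1", "g2"], 0)
    cors0 <- corSet(cor2(0.4), cor2(0.4))
    D0 <- differenceAdjacency(cors0, beta = 1)
    expect_equal(dissimilarity(noTomDissimilarity(D0))["g1", "g2"], 1)
})

test_that("D and T stay in [0,1] across random inputs and beta values", {
    for (s in 1:50) {
        set.seed(s)
        p <- sample(4:12, 1)
        cors <- corSet(randomCorMatrix(p), randomCorMatrix(p))
        beta <- sample(1:12, 1)
        for (v in c("standard", "strict", "multi")) {
            D <- differenceAdjacency(cors, beta = beta, variant = v)
            A <- adjacency(D)
            expect_true(all(A >= 0 & A <= 1) && all(diag(A) == 0))
            T1 <- dissimilarity(tomDissimilarity(D))
            T2 <- dissimilarity(noTomDissimilarity(D))
            expect_true(all(T1 >= 0 & T1 <= 1) && all(diag(T1) == 0))
            expect_true(all(T2 >= 0 & T2 <= 1) && all(diag(T2) == 0))
        }
    }
})

test_that("larger beta never increases any adjacency entry", {
    set.seed(42)
    cors <- corSet(randomCorMatrix(8), randomCorMatrix(8))
    prev <- adjacency(differenceAdjacency(cors, beta = 1))
    for (beta in 2:12) {
        cur <- adjacency(differenceAdjacency(cors, beta = beta))
        expect_true(all(cur <= prev + 1e-15))
        prev <- cur
    }
})

test_that("permuting gene order permutes all matrices identically", {
    x <- randomSet(p = 6, n = 10, seed = 9)
    perm <- c(4, 1, 6, 2, 5, 3)
    xp <- CoexDiffSet(assay(x)[perm, ],
                      as.character(sampleConditions(x)))
    co <- computeCorrelations(x); cop <- computeCorrelations(xp)
    g <- rownames(x)[perm]
    expect_equal(correlationMatrices(cop)[[1]],
                 correlationMatrices(co)[[1]][g, g])
    D <- differenceAdjacency(co, 3); Dp <- differenceAdjacency(cop, 3)
    expect_equal(adjacency(Dp), adjacency(D)[g, g])
    expect_equal(dissimilarity(tomDissimilarity(Dp)),
                 dissimilarity(tomDissimilarity(D))[g, g],
                 tolerance = 1e-12)
})

test_that("module-to-module change surfaces in TOM but not within-block no-TOM", {
    # two conserved blocks whose coupling is lost vs a control where
    # the coupling persists: within-block no-TOM dissimilarity cannot
    # tell them apart, while within-block TOM dissimilarity drops when
    # the coupling is lost (shared rewired neighbourhood)
    mk <- function(r2) SimulationScenario(
        nBackground = 100L, blockSizes = c(30L, 30L),
        withinCor = matrix(0.7, 2, 2),
        couplings = data.frame(blockA = 1L, blockB = 2L,
                               r1 = 0.6, r2 = r2),
        samplesPerCondition = c(40L, 40L))
    lost <- simulateExpression(mk(0), seed = 5)
    kept <- simulateExpression(mk(0.6), seed = 5)
    blk <- moduleLabels(lost$truth) == "block1"
    tomWithin <- function(sim) {
        D <- differenceAdjacency(computeCorrelations(sim$data), beta = 1)
        T <- dissimilarity(tomDissimilarity(D))
        mean(T[blk, blk][upper.tri(T[blk, blk])])
    }
    noTomWithin <- function(sim) {
        D <- differenceAdjacency(computeCorrelations(sim$data), beta = 1)
        T <- dissimilarity(noTomDissimilarity(D))
        mean(T[blk, blk][upper.tri(T[blk, blk])])
    }
    expect_lt(tomWithin(lost), tomWithin(kept) - 0.005)
    expect_lt(abs(noTomWithin(lost) - noTomWithin(kept)), 0.02)
})
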