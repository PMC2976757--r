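# Shared fixtures and independent brute-force oracles.

# random expression set: p genes, n samples per condition
randomSet <- function(p = 6, n = 10, conditions = 2, seed = 1) {
    set.seed(seed)
    m <- matrix(rnorm(p * n * conditions), nrow = p)
    rownames(m) <- paste0("g", seq_len(p))
    colnames(m) <- paste0("s", seq_len(ncol(m)))
    CoexDiffSet(m, rep(paste0("cond", seq_len(conditions)), each = n))
}

# a CorrelationSet built from explicit matrices
corSet <- function(..., method = "pearson") {
    mats <- list(...)
    if (is.null(names(mats)) || any(names(mats) == ""))
        names(mats) <- paste0("cond", seq_along(mats))
    new("CorrelationSet", correlations = mats, method = method)
}

# 2x2 correlation matrix with a given off-diagonal value
cor2 <- function(r, genes = c("g1", "g2")) {
    matrix(c(1, r, r, 1), 2, 2, dimnames = list(genes, genes))
}

# random valid correlation matrix of size p (via a random dataset)
randomCorMatrix <- function(p, n = 15) {
    C <- stats::cor(matrix(rnorm(n * p), ncol = p))
    dimnames(C) <- list(paste0("g", seq_len(p)), paste0("g", seq_len(p)))
    C
}

# naive O(p^3) topological-overlap dissimilarity with explicit index
# ranges: numerator over k not in {i, j}, connectivity over k != i
bruteTOM <- function(D) {
    p <- nrow(D)
    k <- numeric(p)
    for (i in seq_len(p)) k[i] <- sum(D[i, -i])
    T <- matrix(0, p, p, dimnames = dimnames(D))
    for (i in seq_len(p)) {
        for (j in seq_len(p)) {
            if (i == j) next
            num <- D[i, j]
            for (kk in seq_len(p)) {
                if (kk == i || kk == j) next
                num <- num + D[i, kk] * D[kk, j]
            }
            T[i, j] <- 1 - num / (min(k[i], k[j]) + 1 - D[i, j])
        }
    }
    T
}

# naive pair-loop dispersion statistics (two conditions)
bruteDispersion <- function(C1, C2, genes) {
    acc <- 0; np <- 0
    for (a in seq_along(genes)) {
        for (b in seq_along(genes)) {
            if (b <= a) next
            acc <- acc + (C1[genes[a], genes[b]] -
                          C2[genes[a], genes[b]])^2 / 2
            np <- np + 1
        }
    }
    sqrt(acc / np)
}

bruteDispersionBetween <- function(C1, C2, genesA, genesB) {
    acc <- 0; np <- 0
    for (a in genesA) {
        for (b in genesB) {
            acc <- acc + (C1[a, b] - C2[a, b])^2 / 2
            np <- np + 1
        }
    }
    sqrt(acc / np)
}

# a reduced planted-block scenario that keeps tests fast
smallScenarioA <- function(seed = 1) {
    SimulationScenario(nBackground = 300L, blockSizes = 50L,
                       withinCor = matrix(c(0.8, 0), 1, 2),
                       samplesPerCondition = c(30L, 30L), seed = seed)
}

adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)
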