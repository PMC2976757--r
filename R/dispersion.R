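.checkGenes <- function(cors, genes, what = "genes") {
    known <- rownames(correlationMatrices(cors)[[1]])
    bad <- setdiff(genes, known)
    if (length(bad) > 0)
        stop("unknown ", what, ": ",
             paste(utils::head(bad, 5), collapse = ", "))
}

# RMS correlation change over a set of index pairs given as two
# equal-length index vectors (i, j). For two conditions this is
# sqrt(mean((c1 - c2)^2 / 2)); for n conditions the squared deviation
# from the per-pair consensus mean correlation, normalised by (n - 1),
# which reduces to the two-condition form exactly.
.dispersionPairs <- function(mats, i, j) {
    n <- length(mats)
    vals <- vapply(mats, function(C) C[cbind(i, j)],
                   numeric(length(i)))
    if (length(i) == 1) vals <- matrix(vals, nrow = 1)
    cbar <- rowMeans(vals)
    sqrt(mean(rowSums((vals - cbar)^2) / (n - 1)))
}

#' Within-set dispersion: RMS correlation change over gene pairs
#'
#' A scalar summary of how much the pairwise correlations among a set
#' of genes differ between conditions:
#' \deqn{\sqrt{\frac{1}{|P|} \sum_{(i,j) \in P}
#'   \frac{(c^{[1]}_{ij} - c^{[2]}_{ij})^2}{2}}}
#' over all unordered distinct pairs P in the set. Zero exactly when
#' every pairwise correlation is identical across conditions; maximal
#' (\eqn{\sqrt 2}) when every pair flips from +1 to -1. For more than
#' two conditions the squared deviation from the per-pair mean
#' correlation, normalised by n - 1, is used (experimental; reduces to
#' the two-condition form at n = 2).
#'
#' The absolute normalisation is a convention: permutation p-values
#' from \code{\link{permutationTest}} are invariant to scaling the
#' statistic by any positive constant.
#'
#' @param cors a \linkS4class{CorrelationSet}.
#' @param genes character vector of >= 2 gene ids.
#' @return nonnegative scalar.
#' @export
dispersion <- function(cors, genes) {
    stopifnot(is(cors, "CorrelationSet"))
    genes <- unique(genes)
    if (length(genes) < 2) stop("need at least 2 genes")
    .checkGenes(cors, genes)
    mats <- lapply(correlationMatrices(cors),
                   function(C) C[genes, genes, drop = FALSE])
    p <- length(genes)
    ut <- which(upper.tri(mats[[1]]), arr.ind = TRUE)
    .dispersionPairs(mats, ut[, 1], ut[, 2])
}

#' Module-to-module dispersion: RMS correlation change across two sets
#'
#' The same statistic as \code{\link{dispersion}} computed over the
#' |A| x |B| cross pairs of two disjoint gene sets only. Detects a
#' change in the correlation *between* two modules even when the
#' correlation structure within each is conserved.
#'
#' @param cors a \linkS4class{CorrelationSet}.
#' @param genesA,genesB disjoint non-empty gene sets.
#' @return nonnegative scalar, symmetric in (A, B).
#' @export
dispersionBetween <- function(cors, genesA, genesB) {
    stopifnot(is(cors, "CorrelationSet"))
    genesA <- unique(genesA); genesB <- unique(genesB)
    if (length(genesA) < 1 || length(genesB) < 1)
        stop("both gene sets must be non-empty")
    if (length(intersect(genesA, genesB)) > 0)
        stop("gene sets overlap: ",
             paste(utils::head(intersect(genesA, genesB), 5),
                   collapse = ", "))
    .checkGenes(cors, c(genesA, genesB))
    g <- rownames(correlationMatrices(cors)[[1]])
    ia <- match(genesA, g); ib <- match(genesB, g)
    idx <- expand.grid(i = ia, j = ib)
    .dispersionPairs(correlationMatrices(cors), idx$i, idx$j)
}

#' Permutation p-value and its printed form
#'
#' The p-value is the fraction of permutations whose dispersion
#' reached or exceeded the observed value, \code{nExceed / nPerm}
#' (e.g. 249 exceedances in 1000 permutations gives p = 0.249). Zero
#' exceedances are reported as \code{"< 1/nPerm"} (e.g. "< 0.001" at
#' 1000 permutations), never as an exact zero.
#'
#' @param nExceed number of permutations with dispersion >= observed.
#' @param nPerm total number of permutations.
#' @return list with numeric \code{p} and character \code{text}.
#' @examples
#' permutationPValue(249, 1000)  # p = 0.249
#' permutationPValue(0, 1000)    # "< 0.001"
#' @export
permutationPValue <- function(nExceed, nPerm) {
    stopifnot(nPerm >= 1, nExceed >= 0, nExceed <= nPerm)
    p <- nExceed / nPerm
    text <- if (nExceed == 0) {
        paste0("< ", format(1 / nPerm, scientific = FALSE, trim = TRUE))
    } else {
        format(p, scientific = FALSE, trim = TRUE)
    }
    list(p = p, text = text)
}

# Standardize each gene to zero mean / unit variance within each
# condition, so that after pooling, mean or variance differences
# between conditions cannot masquerade as correlation change under
# label permutation.
.scaleWithinCondition <- function(m, cond) {
    for (k in levels(cond)) {
        sel <- cond == k
        sub <- m[, sel, drop = FALSE]
        mu <- rowMeans(sub)
        sd <- apply(sub, 1, stats::sd)
        if (any(sd == 0))
            stop("gene(s) constant within condition '", k,
                 "' cannot be scaled: ",
                 paste(utils::head(rownames(m)[sd == 0], 5),
                       collapse = ", "))
        m[, sel] <- (sub - mu) / sd
    }
    m
}

#' Permutation significance test of module coexpression change
#'
#' Tests whether each module's dispersion (and, optionally, each
#' module pair's module-to-module dispersion) is larger than expected
#' when the condition labels carry no information. Each gene is first
#' standardized to zero mean and unit variance within each condition;
#' each permutation then reassigns the pooled samples to conditions
#' uniformly at random, preserving the original group sizes, and the
#' dispersion statistics are recomputed on the permuted data. The
#' p-value for a target is the fraction of permutations reaching at
#' least the observed dispersion (\code{\link{permutationPValue}}).
#'
#' Interpretation caveat: modules that were themselves *selected* by
#' the clustering on the same data are the most extreme features of
#' that data, so their permutation p-values are anti-conservative;
#' treat them as a sanity filter against unsuitable tuning-parameter
#' choices (beta, tree-cut settings), not as calibrated significance.
#' P-values for gene sets fixed before seeing the data are calibrated.
#'
#' @param x a \linkS4class{CoexDiffSet}.
#' @param modules a \linkS4class{ModuleAssignment}; unassigned
#'   ("grey") genes are ignored.
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed making the permutations reproducible.
#' @param includePairs also test every unordered module pair with
#'   \code{\link{dispersionBetween}} (default TRUE).
#' @param method correlation estimator, matching the one used to build
#'   the network.
#' @param adjust add a Benjamini-Hochberg adjusted column
#'   (\code{pAdjusted}); off by default, mirroring the usual practice
#'   of reporting raw permutation p-values per target.
#' @param returnNull keep the per-target null dispersion samples in
#'   \code{metadata(result)$null}.
#' @return A \linkS4class{DispersionResults} with one row per module
#'   and (optionally) per module pair: \code{targetType},
#'   \code{module1}, \code{module2} (NA for within-module rows),
#'   \code{dispersion}, \code{nPerm}, \code{nExceed}, \code{pValue},
#'   \code{pText}.
#' @export
permutationTest <- function(x, modules, nPerm = 1000L, seed = 1L,
                            includePairs = TRUE,
                            method = c("spearman", "pearson"),
                            adjust = FALSE, returnNull = FALSE) {
    stopifnot(is(x, "CoexDiffSet"), is(modules, "ModuleAssignment"),
              nPerm >= 1)
    method <- match.arg(method)
    nPerm <- as.integer(nPerm)
    lab <- moduleLabels(modules)[rownames(x)]
    mods <- names(moduleSizes(modules))
    mods <- setdiff(mods[mods %in% lab], "grey")
    if (length(mods) == 0) {
        warning("no assigned modules to test")
        res <- DataFrame(targetType = character(0),
                         module1 = character(0), module2 = character(0),
                         dispersion = numeric(0), nPerm = integer(0),
                         nExceed = integer(0), pValue = numeric(0),
                         pText = character(0))
        return(new("DispersionResults", res))
    }
    geneSets <- lapply(mods, function(mod) names(lab)[lab == mod])
    names(geneSets) <- mods
    used <- unlist(geneSets, use.names = FALSE)
    cond <- sampleConditions(x)

    targets <- data.frame(targetType = "module", module1 = mods,
                          module2 = NA_character_,
                          stringsAsFactors = FALSE)
    if (includePairs && length(mods) > 1) {
        prs <- utils::combn(mods, 2)
        targets <- rbind(targets, data.frame(
            targetType = "module_pair", module1 = prs[1, ],
            module2 = prs[2, ], stringsAsFactors = FALSE))
    }

    statsFor <- function(cors) {
        vapply(seq_len(nrow(targets)), function(r) {
            if (targets$targetType[r] == "module")
                dispersion(cors, geneSets[[targets$module1[r]]])
            else
                dispersionBetween(cors,
                                  geneSets[[targets$module1[r]]],
                                  geneSets[[targets$module2[r]]])
        }, numeric(1))
    }
    corsOf <- function(m, cond) {
        mats <- lapply(levels(cond), function(k) {
            C <- stats::cor(t(m[, cond == k, drop = FALSE]),
                            method = method)
            C <- (C + t(C)) / 2; diag(C) <- 1; C
        })
        names(mats) <- levels(cond)
        new("CorrelationSet", correlations = mats, method = method)
    }

    sub <- assay(x)[used, , drop = FALSE]
    observed <- statsFor(corsOf(sub, cond))
    scaled <- .scaleWithinCondition(sub, cond)

    nullMat <- matrix(NA_real_, nrow = nPerm, ncol = nrow(targets))
    .withSeed(seed, {
        for (b in seq_len(nPerm)) {
            permCond <- cond[sample(length(cond))]
            nullMat[b, ] <- statsFor(corsOf(scaled, permCond))
        }
    })
    nExceed <- colSums(nullMat >= rep(observed, each = nPerm))
    pv <- lapply(nExceed, permutationPValue, nPerm = nPerm)

    res <- DataFrame(targetType = targets$targetType,
                     module1 = targets$module1,
                     module2 = targets$module2,
                     dispersion = observed, nPerm = nPerm,
                     nExceed = as.integer(nExceed),
                     pValue = vapply(pv, `[[`, numeric(1), "p"),
                     pText = vapply(pv, `[[`, character(1), "text"))
    if (adjust) res$pAdjusted <- stats::p.adjust(res$pValue, "BH")
    res <- new("DispersionResults", res)
    metadata(res)$nPerm <- nPerm
    metadata(res)$seed <- seed
    if (returnNull) {
        colnames(nullMat) <- ifelse(is.na(targets$module2),
            targets$module1,
            paste(targets$module1, targets$module2, sep = ":"))
        metadata(res)$null <- nullMat
    }
    res
}

# Evaluate expr under a temporary RNG state seeded with 'seed',
# restoring the caller's state afterwards.
.withSeed <- function(seed, expr) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        set.seed(NULL)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    eval.parent(substitute(expr))
}
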