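#' Per-condition correlation matrices
#'
#' Computes one gene-gene correlation matrix per condition, each from
#' that condition's samples only. Spearman rank correlation is the
#' default to reduce sensitivity to outliers; Pearson is available.
#'
#' Genes that are constant within any condition have undefined
#' correlations there. By default this is a hard error naming the
#' offending genes; with \code{dropConstant = TRUE} such genes are
#' removed from all conditions with a warning, so that no NaN can
#' propagate into the downstream adjacency.
#'
#' @param x a \linkS4class{CoexDiffSet}.
#' @param method correlation estimator, \code{"spearman"} (default) or
#'   \code{"pearson"}.
#' @param dropConstant drop within-condition-constant genes instead of
#'   erroring.
#' @return A \linkS4class{CorrelationSet}.
#' @export
computeCorrelations <- function(x, method = c("spearman", "pearson"),
                                dropConstant = FALSE) {
    stopifnot(is(x, "CoexDiffSet"))
    validObject(x)
    method <- match.arg(method)
    m <- assay(x)
    cond <- sampleConditions(x)

    constant <- Reduce(`|`, lapply(levels(cond), function(k) {
        sub <- m[, cond == k, drop = FALSE]
        apply(sub, 1, function(v) max(v) == min(v))
    }))
    if (any(constant)) {
        genes <- rownames(m)[constant]
        shown <- paste(utils::head(genes, 5), collapse = ", ")
        if (length(genes) > 5) shown <- paste0(shown, ", ...")
        if (!dropConstant)
            stop(length(genes), " gene(s) are constant within a ",
                 "condition (undefined correlation): ", shown,
                 ". Use dropConstant = TRUE to remove them.")
        warning("dropping ", length(genes),
                " within-condition-constant gene(s): ", shown)
        m <- m[!constant, , drop = FALSE]
    }

    mats <- lapply(levels(cond), function(k) {
        C <- stats::cor(t(m[, cond == k, drop = FALSE]), method = method)
        C <- (C + t(C)) / 2
        diag(C) <- 1
        C
    })
    names(mats) <- levels(cond)
    new("CorrelationSet", correlations = mats, method = method)
}

#' Signed square transform
#'
#' \code{sign(c) * c^2}, so that correlation changes equal in explained
#' variance (r-squared) receive equal weight regardless of sign.
#'
#' @param x numeric vector or matrix of correlations in [-1, 1].
#' @return transformed values, same shape; odd in \code{x}.
#' @examples
#' signedSquare(c(-1, -0.5, 0, 1))  # -1 -0.25 0 1
#' @export
signedSquare <- function(x) sign(x) * x^2

#' Adjacency matrix of coexpression change
#'
#' Turns per-condition correlations into a weighted network of
#' correlation change. Three variants:
#' \describe{
#'   \item{standard}{two conditions;
#'     \eqn{d_{ij} = (\frac{1}{2}|s^{[1]}_{ij} - s^{[2]}_{ij}|)^\beta}
#'     with \eqn{s = sign(c) c^2} the signed-squared correlation.}
#'   \item{multi}{n >= 2 conditions; root-mean-square deviation of the
#'     signed-squared correlations from their consensus
#'     \eqn{c^{[0]}_{ij} = \frac{1}{n}\sum_k s^{[k]}_{ij}}, normalised
#'     by \eqn{2(n-1)} so that it reduces exactly to the standard form
#'     at n = 2, then raised to \eqn{\beta}.}
#'   \item{strict}{two conditions; the soft threshold is applied to the
#'     correlations before differencing,
#'     \eqn{d_{ij} = \frac{1}{2}|sign(c^{[1]})|c^{[1]}|^\beta -
#'     sign(c^{[2]})|c^{[2]}|^\beta|}: less sensitive to subtle
#'     changes, picks up only strikingly rewired, strongly coexpressed
#'     modules. At \eqn{\beta = 2} identical to standard at
#'     \eqn{\beta = 1}.}
#' }
#'
#' Beta is a stringency/tuning parameter: larger values downweight
#' small correlation changes. With larger sample sizes smaller
#' correlation changes are statistically meaningful, so smaller beta
#' values are appropriate; significance must always be confirmed
#' downstream with \code{\link{permutationTest}}.
#'
#' @param cors a \linkS4class{CorrelationSet}.
#' @param beta positive integer soft threshold (default 6).
#' @param variant \code{"standard"} (default), \code{"multi"} or
#'   \code{"strict"}.
#' @return A \linkS4class{DifferenceAdjacency}.
#' @export
differenceAdjacency <- function(cors, beta = 6L,
                                variant = c("standard", "multi",
                                            "strict")) {
    stopifnot(is(cors, "CorrelationSet"))
    variant <- match.arg(variant)
    if (length(beta) != 1 || !is.finite(beta) || beta < 1 ||
        beta != round(beta))
        stop("'beta' must be a positive integer")
    beta <- as.integer(beta)
    mats <- correlationMatrices(cors)
    n <- length(mats)
    if (variant %in% c("standard", "strict") && n != 2)
        stop("variant '", variant, "' requires exactly 2 conditions ",
             "(got ", n, "); use variant = 'multi'")

    D <- switch(variant,
        standard = {
            s <- lapply(mats, signedSquare)
            (0.5 * abs(s[[1]] - s[[2]]))^beta
        },
        strict = {
            tr <- lapply(mats, function(C) sign(C) * abs(C)^beta)
            0.5 * abs(tr[[1]] - tr[[2]])
        },
        multi = {
            s <- lapply(mats, signedSquare)
            c0 <- Reduce(`+`, s) / n
            ss <- Reduce(`+`, lapply(s, function(m) (m - c0)^2))
            sqrt(ss / (2 * (n - 1)))^beta
        })
    D <- pmin(pmax((D + t(D)) / 2, 0), 1)
    diag(D) <- 0
    new("DifferenceAdjacency", adjacency = D, beta = beta,
        variant = variant)
}

#' Topological-overlap dissimilarity of the difference network
#'
#' \deqn{t_{ij} = 1 - \frac{\sum_{k \notin \{i,j\}} d_{ik} d_{kj} +
#'   d_{ij}}{\min(\sum_k d_{ik}, \sum_k d_{jk}) + 1 - d_{ij}}}
#'
#' Two genes are similar (low t) when their correlations to the same
#' large group of genes change between conditions -- whether or not
#' their own pairwise correlation changes. This is what lets the
#' method group genes whose within-module correlation is rewired
#' (criterion i) and genes whose correlation to a *different* module
#' is rewired while their own module is conserved (criterion ii).
#'
#' The numerator sum excludes k = i and k = j (the zero diagonal of D
#' enforces this automatically); connectivities sum over all k. Under
#' this convention t is guaranteed to lie in [0, 1].
#'
#' @param D a \linkS4class{DifferenceAdjacency}.
#' @return A \linkS4class{DissimilarityMatrix}, variant \code{"tom"}.
#' @export
tomDissimilarity <- function(D) {
    stopifnot(is(D, "DifferenceAdjacency"))
    A <- adjacency(D)
    if (any(!is.finite(A))) stop("adjacency has non-finite entries")
    k <- rowSums(A)
    num <- A %*% A + A          # diag(A) = 0 drops k = i, j terms
    den <- outer(k, k, pmin) + 1 - A
    T <- 1 - num / den
    T <- pmin(pmax((T + t(T)) / 2, 0), 1)
    diag(T) <- 0
    new("DissimilarityMatrix", dissimilarity = T, variant = "tom")
}

#' Plain complement dissimilarity (no topological overlap)
#'
#' \eqn{T_{alt} = 1 - D}. Cheaper than the topological overlap, but
#' sensitive only to within-module correlation change: genes whose own
#' pairwise correlations are conserved stay maximally dissimilar even
#' when they share a rewired neighbourhood, so module-to-module
#' correlation changes are not detected with this variant.
#'
#' @param D a \linkS4class{DifferenceAdjacency}.
#' @return A \linkS4class{DissimilarityMatrix}, variant \code{"no_tom"}.
#' @export
noTomDissimilarity <- function(D) {
    stopifnot(is(D, "DifferenceAdjacency"))
    T <- 1 - adjacency(D)
    diag(T) <- 0
    new("DissimilarityMatrix", dissimilarity = T, variant = "no_tom")
}
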