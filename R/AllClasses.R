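#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
NULL

#' CoexDiffSet: expression data with a sample-to-condition assignment
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a
#' genes x samples expression matrix (assay \code{"exprs"}) and a
#' \code{condition} factor in \code{colData}. Validity requires all
#' values finite, unique gene and sample identifiers, at least two
#' conditions and at least three samples per condition (pairwise
#' correlation is meaningless below that).
#'
#' @aliases CoexDiffSet-class
#' @export
setClass("CoexDiffSet", contains = "SummarizedExperiment")

setValidity("CoexDiffSet", function(object) {
    m <- assay(object)
    if (!is.numeric(m))
        return("expression values must be numeric")
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
        return("gene identifiers must be present and unique")
    if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
        return("sample identifiers must be present and unique")
    bad <- which(!is.finite(m), arr.ind = TRUE)
    if (nrow(bad) > 0) {
        return(sprintf(
            "non-finite expression value for gene '%s', sample '%s'",
            rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
    }
    if (!"condition" %in% colnames(colData(object)))
        return("colData must contain a 'condition' column")
    cond <- sampleConditions(object)
    if (nlevels(cond) < 2)
        return("at least two distinct conditions are required")
    n <- table(cond)
    if (any(n < 3))
        return(sprintf(
            "every condition needs >= 3 samples; offending: %s",
            paste(names(n)[n < 3], collapse = ", ")))
    TRUE
})

#' Per-condition gene-gene correlation matrices
#'
#' One square symmetric correlation matrix per condition, all over the
#' same ordered gene set, with unit diagonal and entries in [-1, 1].
#'
#' @slot correlations named list of gene x gene correlation matrices,
#'   one per condition.
#' @slot method correlation estimator used (\code{"pearson"} or
#'   \code{"spearman"}).
#' @aliases CorrelationSet-class
#' @export
setClass("CorrelationSet",
    representation(correlations = "list", method = "character"))

setValidity("CorrelationSet", function(object) {
    mats <- object@correlations
    if (length(mats) < 2)
        return("need correlation matrices for at least two conditions")
    if (is.null(names(mats)) || anyDuplicated(names(mats)))
        return("correlation matrices must be uniquely named by condition")
    g <- rownames(mats[[1]])
    for (k in seq_along(mats)) {
        C <- mats[[k]]
        if (!is.matrix(C) || nrow(C) != ncol(C))
            return("correlation matrices must be square")
        if (!identical(rownames(C), g) || !identical(colnames(C), g))
            return("all correlation matrices must share one gene ordering")
        if (max(abs(C - t(C))) > 1e-8)
            return("correlation matrices must be symmetric")
        if (any(abs(C) > 1 + 1e-8))
            return("correlation entries must lie in [-1, 1]")
        if (max(abs(diag(C) - 1)) > 1e-8)
            return("correlation diagonal must equal 1")
    }
    if (!object@method %in% c("pearson", "spearman"))
        return("method must be 'pearson' or 'spearman'")
    TRUE
})

#' Soft-thresholded adjacency matrix of coexpression change
#'
#' Square symmetric matrix with entries in [0, 1] and zero diagonal;
#' entry (i, j) quantifies how strongly the correlation of genes i and
#' j differs between conditions, raised to the soft threshold beta.
#'
#' @slot adjacency the gene x gene matrix D.
#' @slot beta positive integer soft-threshold exponent.
#' @slot variant \code{"standard"}, \code{"strict"} or \code{"multi"}.
#' @aliases DifferenceAdjacency-class
#' @export
setClass("DifferenceAdjacency",
    representation(adjacency = "matrix", beta = "integer",
                   variant = "character"))

setValidity("DifferenceAdjacency", function(object) {
    D <- object@adjacency
    if (nrow(D) != ncol(D)) return("adjacency must be square")
    if (any(!is.finite(D))) return("adjacency entries must be finite")
    if (min(D) < 0 || max(D) > 1)
        return("adjacency entries must lie in [0, 1]")
    if (any(diag(D) != 0)) return("adjacency diagonal must be 0")
    if (max(abs(D - t(D))) > 1e-12) return("adjacency must be symmetric")
    if (object@beta < 1L) return("beta must be a positive integer")
    if (!object@variant %in% c("standard", "strict", "multi"))
        return("variant must be standard, strict or multi")
    TRUE
})

#' Gene-gene dissimilarity used for module extraction
#'
#' Entries in [0, 1], zero diagonal; either the topological-overlap
#' dissimilarity of the difference network (\code{"tom"}) or its plain
#' complement 1 - D (\code{"no_tom"}).
#'
#' @slot dissimilarity the gene x gene matrix T.
#' @slot variant \code{"tom"} or \code{"no_tom"}.
#' @aliases DissimilarityMatrix-class
#' @export
setClass("DissimilarityMatrix",
    representation(dissimilarity = "matrix", variant = "character"))

setValidity("DissimilarityMatrix", function(object) {
    T <- object@dissimilarity
    if (nrow(T) != ncol(T)) return("dissimilarity must be square")
    if (any(!is.finite(T))) return("dissimilarity entries must be finite")
    if (min(T) < 0 || max(T) > 1)
        return("dissimilarity entries must lie in [0, 1]")
    if (any(diag(T) != 0)) return("dissimilarity diagonal must be 0")
    if (!object@variant %in% c("tom", "no_tom"))
        return("variant must be 'tom' or 'no_tom'")
    TRUE
})

#' Gene-to-module assignment
#'
#' A named character vector of module labels, one per gene. Module
#' labels follow a fixed colour sequence ordered by decreasing module
#' size; genes in no module carry the reserved label \code{"grey"}.
#'
#' @slot labels named character vector, gene id -> module label.
#' @slot params list echoing the clustering parameters used.
#' @aliases ModuleAssignment-class
#' @export
setClass("ModuleAssignment",
    representation(labels = "character", params = "list"))

setValidity("ModuleAssignment", function(object) {
    l <- object@labels
    if (is.null(names(l)) || anyDuplicated(names(l)))
        return("labels must be named by unique gene ids")
    if (any(is.na(l)) || any(l == ""))
        return("every gene must carry a module label")
    TRUE
})

#' Dispersion test results
#'
#' A \linkS4class{DataFrame} subclass with one row per tested module or
#' module pair: the observed dispersion, the number of permutations,
#' the exceedance count, the permutation p-value (nExceed / nPerm) and
#' its printed form (zero exceedances print as "< 1/nPerm").
#'
#' @aliases DispersionResults-class
#' @export
setClass("DispersionResults", contains = "DFrame")
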