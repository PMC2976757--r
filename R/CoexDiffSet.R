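#' Construct a CoexDiffSet
#'
#' @param values numeric matrix, genes as rows and samples as columns;
#'   rownames are gene identifiers and colnames sample identifiers.
#' @param condition condition label for every sample: an unnamed vector
#'   aligned with the columns of \code{values}, or a named vector /
#'   two-column data.frame mapping sample id to condition.
#' @return A \linkS4class{CoexDiffSet}.
#' @examples
#' m <- matrix(rnorm(60), nrow = 10,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
#' cds <- CoexDiffSet(m, rep(c("wt", "mut"), each = 3))
#' sampleConditions(cds)
#' @export
CoexDiffSet <- function(values, condition) {
    values <- as.matrix(values)
    if (is.data.frame(condition)) {
        if (ncol(condition) != 2)
            stop("a condition data.frame must have two columns: ",
                 "sample id, condition label")
        condition <- stats::setNames(as.character(condition[[2]]),
                                     as.character(condition[[1]]))
    }
    if (!is.null(names(condition))) {
        missing <- setdiff(colnames(values), names(condition))
        if (length(missing) > 0)
            stop("sample(s) without a condition assignment: ",
                 paste(missing, collapse = ", "))
        extra <- setdiff(names(condition), colnames(values))
        if (length(extra) > 0)
            stop("condition map names sample(s) absent from the ",
                 "expression matrix: ", paste(extra, collapse = ", "))
        condition <- condition[colnames(values)]
    } else if (length(condition) != ncol(values)) {
        stop("'condition' must have one entry per sample")
    }
    se <- SummarizedExperiment(
        assays = SimpleList(exprs = values),
        colData = DataFrame(condition = factor(unname(condition)),
                            row.names = colnames(values)))
    new("CoexDiffSet", se)
}

#' @rdname sampleConditions
#' @export
setGeneric("sampleConditions", function(x) standardGeneric("sampleConditions"))

#' Condition factor of a CoexDiffSet
#'
#' @param x a \linkS4class{CoexDiffSet}.
#' @return factor of condition labels, one per sample.
#' @export
setMethod("sampleConditions", "CoexDiffSet", function(x) {
    factor(colData(x)$condition)
})

setMethod("show", "CoexDiffSet", function(object) {
    cond <- sampleConditions(object)
    cat("CoexDiffSet:", nrow(object), "genes x", ncol(object), "samples\n")
    cat("conditions:",
        paste(sprintf("%s (n=%d)", levels(cond), table(cond)),
              collapse = ", "), "\n")
})

#' @rdname correlationMatrices
#' @export
setGeneric("correlationMatrices",
           function(x) standardGeneric("correlationMatrices"))

#' Extract the per-condition correlation matrices
#'
#' @param x a \linkS4class{CorrelationSet}.
#' @return named list of correlation matrices, one per condition.
#' @export
setMethod("correlationMatrices", "CorrelationSet",
          function(x) x@correlations)

#' @rdname corMethod
#' @export
setGeneric("corMethod", function(x) standardGeneric("corMethod"))

#' Correlation estimator of a CorrelationSet
#' @param x a \linkS4class{CorrelationSet}.
#' @return \code{"pearson"} or \code{"spearman"}.
#' @export
setMethod("corMethod", "CorrelationSet", function(x) x@method)

setMethod("show", "CorrelationSet", function(object) {
    cat("CorrelationSet (", object@method, "): ",
        nrow(object@correlations[[1]]), " genes, conditions: ",
        paste(names(object@correlations), collapse = ", "), "\n", sep = "")
})

#' @rdname adjacency
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' Adjacency matrix of coexpression change
#' @param x a \linkS4class{DifferenceAdjacency}.
#' @return the gene x gene matrix D.
#' @export
setMethod("adjacency", "DifferenceAdjacency", function(x) x@adjacency)

#' @rdname softThreshold
#' @export
setGeneric("softThreshold", function(x) standardGeneric("softThreshold"))

#' Soft threshold exponent used to build an adjacency
#' @param x a \linkS4class{DifferenceAdjacency}.
#' @return integer beta.
#' @export
setMethod("softThreshold", "DifferenceAdjacency", function(x) x@beta)

setMethod("show", "DifferenceAdjacency", function(object) {
    cat("DifferenceAdjacency (", object@variant, "): ",
        nrow(object@adjacency), " genes, beta = ", object@beta, "\n",
        sep = "")
})

#' @rdname dissimilarity
#' @export
setGeneric("dissimilarity", function(x) standardGeneric("dissimilarity"))

#' Dissimilarity matrix used for clustering
#' @param x a \linkS4class{DissimilarityMatrix}.
#' @return the gene x gene matrix T.
#' @export
setMethod("dissimilarity", "DissimilarityMatrix",
          function(x) x@dissimilarity)

setMethod("show", "DissimilarityMatrix", function(object) {
    cat("DissimilarityMatrix (", object@variant, "): ",
        nrow(object@dissimilarity), " genes\n", sep = "")
})

#' @rdname moduleLabels
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))

#' Gene-to-module labels
#' @param x a \linkS4class{ModuleAssignment}.
#' @return named character vector, gene id -> module label.
#' @export
setMethod("moduleLabels", "ModuleAssignment", function(x) x@labels)

#' @rdname moduleSizes
#' @export
setGeneric("moduleSizes", function(x) standardGeneric("moduleSizes"))

#' Module sizes, largest first (the reserved "grey" label last)
#' @param x a \linkS4class{ModuleAssignment}.
#' @return named integer vector of module sizes.
#' @export
setMethod("moduleSizes", "ModuleAssignment", function(x) {
    tab <- table(x@labels)
    grey <- tab[names(tab) == "grey"]
    tab <- sort(tab[names(tab) != "grey"], decreasing = TRUE)
    out <- c(tab, grey)
    stats::setNames(as.integer(out), names(out))
})

setMethod("show", "ModuleAssignment", function(object) {
    sz <- moduleSizes(object)
    cat("ModuleAssignment:", length(object@labels), "genes,",
        sum(names(sz) != "grey"), "modules\n")
    print(sz)
})
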