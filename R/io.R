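.sepFor <- function(file, sep) {
    if (!is.null(sep)) return(sep)
    if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
}

#' Read a genes x samples expression table
#'
#' Delimited text, first column gene identifiers, header row sample
#' identifiers. Tab-separated by default; a \code{.csv} extension
#' switches to commas.
#'
#' @param file path to the table.
#' @param sep field separator; inferred from the extension if NULL.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
readExpression <- function(file, sep = NULL) {
    df <- utils::read.delim(file, sep = .sepFor(file, sep),
                            check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2)
        stop("expression file '", file,
             "' needs a gene-id column plus sample columns")
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
        stop("duplicated gene id(s) in '", file, "': ",
             paste(utils::head(unique(ids[duplicated(ids)]), 5),
                   collapse = ", "))
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    m
}

#' Read a sample-to-condition map
#'
#' Two-column delimited text: sample identifier, condition label. A
#' header row is accepted and detected.
#'
#' @inheritParams readExpression
#' @return named character vector, sample id -> condition label.
#' @export
readConditionMap <- function(file, sep = NULL) {
    df <- utils::read.delim(file, sep = .sepFor(file, sep),
                            header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) != 2)
        stop("condition map '", file, "' must have exactly 2 columns")
    if (tolower(df[1, 1]) %in% c("sample", "sample_id", "id"))
        df <- df[-1, , drop = FALSE]
    if (anyDuplicated(df[[1]]))
        stop("sample(s) listed more than once in '", file, "': ",
             paste(utils::head(unique(df[[1]][duplicated(df[[1]])]), 5),
                   collapse = ", "))
    stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Read an expression table and condition map into a CoexDiffSet
#'
#' @param exprFile expression table (see \code{\link{readExpression}}).
#' @param conditionFile condition map (see
#'   \code{\link{readConditionMap}}).
#' @param sep field separator; inferred per file if NULL.
#' @return a \linkS4class{CoexDiffSet}.
#' @export
readDataset <- function(exprFile, conditionFile, sep = NULL) {
    CoexDiffSet(readExpression(exprFile, sep),
                readConditionMap(conditionFile, sep))
}

#' Write a CoexDiffSet back to delimited text
#'
#' @param x a \linkS4class{CoexDiffSet}.
#' @param exprFile,conditionFile output paths.
#' @return invisibly, the input.
#' @export
writeDataset <- function(x, exprFile, conditionFile) {
    df <- data.frame(gene_id = rownames(x), assay(x),
                     check.names = FALSE)
    utils::write.table(df, exprFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(
        data.frame(sample_id = colnames(x),
                   condition = as.character(sampleConditions(x))),
        conditionFile, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(x)
}

#' Write a gene-to-module table
#'
#' Columns \code{gene_id}, \code{module_label}.
#'
#' @param modules a \linkS4class{ModuleAssignment}.
#' @param file output path (TSV).
#' @return invisibly, the input.
#' @export
writeModules <- function(modules, file) {
    lab <- moduleLabels(modules)
    utils::write.table(
        data.frame(gene_id = names(lab), module_label = unname(lab)),
        file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(modules)
}

#' Read a gene-to-module table written by \code{\link{writeModules}}
#'
#' @param file TSV with columns gene_id, module_label.
#' @return a \linkS4class{ModuleAssignment}.
#' @export
readModules <- function(file) {
    df <- utils::read.delim(file, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "module_label") %in% colnames(df)))
        stop("'", file, "' needs columns gene_id, module_label")
    new("ModuleAssignment",
        labels = stats::setNames(df$module_label, df$gene_id),
        params = list(source = file))
}

#' Write a dispersion result table
#'
#' Columns \code{target_type}, \code{module1}, \code{module2},
#' \code{observed_dispersion}, \code{n_perm}, \code{n_exceed},
#' \code{p_value_text}.
#'
#' @param res a \linkS4class{DispersionResults}.
#' @param file output path (TSV).
#' @return invisibly, the input.
#' @export
writeDispersion <- function(res, file) {
    utils::write.table(
        data.frame(target_type = res$targetType, module1 = res$module1,
                   module2 = ifelse(is.na(res$module2), "",
                                    res$module2),
                   observed_dispersion = res$dispersion,
                   n_perm = res$nPerm, n_exceed = res$nExceed,
                   p_value_text = res$pText),
        file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(res)
}

#' Write a square gene x gene matrix as delimited text
#'
#' Gene identifiers appear as both the header and the first column.
#'
#' @param m matrix, or a \linkS4class{DifferenceAdjacency} /
#'   \linkS4class{DissimilarityMatrix}.
#' @param file output path (TSV).
#' @return invisibly, the matrix written.
#' @export
writeMatrixTSV <- function(m, file) {
    if (is(m, "DifferenceAdjacency")) m <- adjacency(m)
    if (is(m, "DissimilarityMatrix")) m <- dissimilarity(m)
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(m)
}
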