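#' Full differential-coexpression run
#'
#' Bundles the outputs of \code{\link{runPipeline}}: the module
#' assignment, the dispersion test table, the intermediate network
#' matrices and the fully resolved configuration (so any result is
#' reproducible from the object alone).
#'
#' @slot modules a \linkS4class{ModuleAssignment}.
#' @slot dispersionResults a \linkS4class{DispersionResults}.
#' @slot correlations the per-condition \linkS4class{CorrelationSet}.
#' @slot adjacency the \linkS4class{DifferenceAdjacency}.
#' @slot dissimilarityMatrix the \linkS4class{DissimilarityMatrix}.
#' @slot config list of all resolved parameters.
#' @aliases CoexDiffRun-class
#' @export
setClass("CoexDiffRun",
    representation(modules = "ModuleAssignment",
                   dispersionResults = "DispersionResults",
                   correlations = "CorrelationSet",
                   adjacency = "DifferenceAdjacency",
                   dissimilarityMatrix = "DissimilarityMatrix",
                   config = "list"))

setMethod("show", "CoexDiffRun", function(object) {
    cfg <- object@config
    cat("CoexDiffRun |", cfg$nGenes, "genes,", cfg$nSamples,
        "samples |", cfg$correlation, "correlation, beta =",
        cfg$beta, ", variant =", cfg$variant, ", dissimilarity =",
        cfg$dissimilarity, "\n")
    show(object@modules)
    sig <- object@dispersionResults
    if (nrow(sig) > 0) {
        cat("dispersion test:", sum(sig$targetType == "module"),
            "modules,", sum(sig$targetType == "module_pair"),
            "module pairs,", cfg$nPerm, "permutations (seed",
            cfg$seed, ")\n")
    }
})

#' @rdname runPipeline
#' @param x a \linkS4class{CoexDiffRun} (for the accessors).
#' @export
setGeneric("resultModules", function(x) standardGeneric("resultModules"))

#' @rdname runPipeline
#' @export
setMethod("resultModules", "CoexDiffRun", function(x) x@modules)

#' @rdname runPipeline
#' @export
setGeneric("resultDispersion",
           function(x) standardGeneric("resultDispersion"))

#' @rdname runPipeline
#' @export
setMethod("resultDispersion", "CoexDiffRun",
          function(x) x@dispersionResults)

#' Run the complete differential-coexpression pipeline
#'
#' Executes the five stages in order on a \linkS4class{CoexDiffSet}:
#' per-condition correlations, soft-thresholded adjacency of
#' correlation change, dissimilarity (topological overlap by default),
#' module extraction, and the permutation dispersion test of every
#' module (and module pair). Identical input and parameters give
#' identical output.
#'
#' @param x a \linkS4class{CoexDiffSet}, or the list returned by
#'   \code{\link{simulateExpression}} (its \code{data} element is
#'   used).
#' @param correlation correlation estimator
#'   (\code{\link{computeCorrelations}}).
#' @param beta soft threshold (\code{\link{differenceAdjacency}}).
#' @param variant adjacency variant: \code{"standard"},
#'   \code{"multi"} or \code{"strict"}; with more than two conditions
#'   \code{"multi"} is required.
#' @param dissimilarity \code{"tom"} or \code{"no_tom"}.
#' @param cut clustering method: \code{"dynamic"}, \code{"static"} or
#'   \code{"pam"} (\code{\link{clusterModules}}).
#' @param cutHeight,minModuleSize,k,gapFraction clustering parameters,
#'   see \code{\link{clusterModules}}.
#' @param nPerm,includePairs,seed permutation-test parameters, see
#'   \code{\link{permutationTest}}.
#' @param dropConstant forwarded to
#'   \code{\link{computeCorrelations}}.
#' @param verbose log the resolved configuration and stage progress
#'   via \code{message()}.
#' @return A \linkS4class{CoexDiffRun}.
#' @examples
#' sim <- simulateExpression(SimulationScenario(
#'     nBackground = 60L, blockSizes = 40L,
#'     withinCor = matrix(c(0.8, 0), 1, 2),
#'     samplesPerCondition = c(20L, 20L)), seed = 7)
#' run <- runPipeline(sim$data, beta = 2, nPerm = 50, verbose = FALSE)
#' moduleSizes(resultModules(run))
#' @export
runPipeline <- function(x, correlation = c("spearman", "pearson"),
                        beta = 6L,
                        variant = c("standard", "multi", "strict"),
                        dissimilarity = c("tom", "no_tom"),
                        cut = c("dynamic", "static", "pam"),
                        cutHeight = NULL, minModuleSize = 20L,
                        k = NULL, gapFraction = 0.1, nPerm = 1000L,
                        includePairs = TRUE, seed = 1L,
                        dropConstant = FALSE, verbose = TRUE) {
    if (is.list(x) && !is.null(x$data)) x <- x$data
    stopifnot(is(x, "CoexDiffSet"))
    correlation <- match.arg(correlation)
    variant <- match.arg(variant)
    dissimilarity <- match.arg(dissimilarity)
    cut <- match.arg(cut)
    cond <- sampleConditions(x)
    if (nlevels(cond) > 2 && variant != "multi")
        stop(nlevels(cond), " conditions require variant = 'multi'")

    cfg <- list(nGenes = nrow(x), nSamples = ncol(x),
                conditions = stats::setNames(as.integer(table(cond)),
                                             levels(cond)),
                correlation = correlation, beta = as.integer(beta),
                variant = variant, dissimilarity = dissimilarity,
                cut = cut, cutHeight = cutHeight,
                minModuleSize = as.integer(minModuleSize), k = k,
                gapFraction = gapFraction, nPerm = as.integer(nPerm),
                includePairs = includePairs, seed = as.integer(seed),
                dropConstant = dropConstant)
    log <- function(...) if (verbose) message(...)
    log("config: ", paste(names(cfg), vapply(cfg, function(v)
        paste(format(unlist(v)), collapse = "/"), character(1)),
        sep = "=", collapse = " "))

    log("step 1: ", correlation, " correlations in ", nlevels(cond),
        " conditions")
    cors <- computeCorrelations(x, method = correlation,
                                dropConstant = dropConstant)
    log("step 2: ", variant, " adjacency of correlation change, beta = ",
        beta)
    D <- differenceAdjacency(cors, beta = beta, variant = variant)
    log("step 3: ", dissimilarity, " dissimilarity")
    T <- if (dissimilarity == "tom") tomDissimilarity(D)
         else noTomDissimilarity(D)
    log("step 4: module extraction (", cut, ", minModuleSize = ",
        minModuleSize, ")")
    modules <- clusterModules(T, method = cut,
                              minModuleSize = minModuleSize,
                              cutHeight = cutHeight, k = k,
                              gapFraction = gapFraction)
    sz <- moduleSizes(modules)
    log("         ", sum(names(sz) != "grey"), " module(s): ",
        paste(sprintf("%s(%d)", names(sz), sz), collapse = " "))
    log("step 5: dispersion permutation test (", nPerm,
        " permutations, seed ", seed, ")")
    keep <- names(moduleLabels(modules))
    disp <- permutationTest(x[keep[keep %in% rownames(x)], ],
                            modules, nPerm = nPerm, seed = seed,
                            includePairs = includePairs,
                            method = correlation)

    new("CoexDiffRun", modules = modules, dispersionResults = disp,
        correlations = cors, adjacency = D, dissimilarityMatrix = T,
        config = cfg)
}

#' Write the result bundle of a run to a directory
#'
#' Writes \code{modules.tsv}, \code{dispersion.tsv} and
#' \code{run_config.txt} (every resolved parameter, one per line) into
#' \code{dir}. Output files are written atomically via temporary
#' files, so a failure leaves no partial result behind.
#'
#' @param run a \linkS4class{CoexDiffRun}.
#' @param dir output directory, created if needed.
#' @param matrices also write \code{adjacency.tsv} and
#'   \code{dissimilarity.tsv} (large for many genes).
#' @return invisibly, the paths written.
#' @export
writeRun <- function(run, dir, matrices = FALSE) {
    stopifnot(is(run, "CoexDiffRun"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    emit <- function(fun, obj, name) {
        tmp <- tempfile(tmpdir = dir)
        fun(obj, tmp)
        final <- file.path(dir, name)
        file.rename(tmp, final)
        final
    }
    paths <- c(
        emit(writeModules, run@modules, "modules.tsv"),
        emit(writeDispersion, run@dispersionResults, "dispersion.tsv"),
        emit(function(cfg, f) writeLines(paste(names(cfg),
            vapply(cfg, function(v) paste(format(unlist(v)),
                collapse = ","), character(1)), sep = "\t"), f),
            run@config, "run_config.txt"))
    if (matrices) {
        paths <- c(paths,
            emit(writeMatrixTSV, run@adjacency, "adjacency.tsv"),
            emit(writeMatrixTSV, run@dissimilarityMatrix,
                 "dissimilarity.tsv"))
    }
    invisible(paths)
}
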