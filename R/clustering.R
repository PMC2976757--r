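#' Construct a module assignment by hand
#'
#' Useful for testing pre-defined gene sets with
#' \code{\link{permutationTest}} without running the clustering, and
#' for loading external module definitions.
#'
#' @param labels named character vector, gene id -> module label; use
#'   \code{"grey"} for unassigned genes.
#' @param params optional list recording how the assignment was made.
#' @return A \linkS4class{ModuleAssignment}.
#' @examples
#' ModuleAssignment(c(g1 = "blue", g2 = "blue", g3 = "grey"))
#' @export
ModuleAssignment <- function(labels, params = list(source = "manual")) {
    new("ModuleAssignment", labels = labels, params = params)
}

.MODULE_COLOURS <- c(
    "turquoise", "blue", "brown", "yellow", "green", "red", "black",
    "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
    "cyan", "midnightblue", "lightcyan", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown",
    "steelblue", "paleturquoise", "violet", "darkolivegreen",
    "darkmagenta")

# Map raw integer cluster ids to colour labels by descending size;
# cluster id 0 is reserved for unassigned genes and becomes "grey".
.colourise <- function(cl, genes) {
    lab <- rep("grey", length(cl))
    ids <- setdiff(unique(cl), 0L)
    if (length(ids) > 0) {
        ord <- ids[order(-tabulate(match(cl, ids))[seq_along(ids)],
                         ids)]
        cols <- c(.MODULE_COLOURS,
                  paste0("module", seq_len(max(0,
                      length(ord) - length(.MODULE_COLOURS)))))
        for (i in seq_along(ord)) lab[cl == ord[i]] <- cols[i]
    }
    stats::setNames(lab, genes)
}

# Adaptive branch decomposition of an average-linkage dendrogram.
#
# A subtree is a candidate module when it holds >= minSize leaves and
# its attachment gap -- the merge height at which it joins the rest of
# the tree minus its own top merge height -- exceeds gapFraction times
# a robust height scale (max height minus median height: the spread of
# the upper half of the dendrogram, where unassigned background
# agglomerates; the raw range is dominated by incidental low pairs).
# Maximal candidates are then resolved top-down: a candidate splits
# into its two children only when both children hold >= minSize leaves
# and detach from each other at least as strongly as the candidate
# detaches from the rest of the tree (the signature of two distinct
# tight branches sharing an ancestor); otherwise it is kept whole.
# Leaves under no candidate stay unassigned (0).
.dynamicCut <- function(hc, minSize, gapFraction = 0.1) {
    nGene <- length(hc$order)
    nNode <- nGene - 1L
    h <- hc$height
    hscale <- max(h) - stats::median(h)
    if (nNode < 2 || hscale <= 0)
        return(list(cl = rep(0L, nGene), shed = integer(0)))
    minGap <- gapFraction * hscale

    size <- integer(nNode)
    subh <- numeric(nNode)     # top merge height inside the subtree
    parent <- integer(nNode)   # 0 for the root
    for (v in seq_len(nNode)) {
        for (ch in hc$merge[v, ]) {
            if (ch < 0) next
            parent[ch] <- v
        }
        kids <- hc$merge[v, ]
        size[v] <- sum(ifelse(kids < 0, 1L, size[pmax(kids, 1L)]))
        subh[v] <- h[v]
    }
    gap <- numeric(nNode)
    hasParent <- parent > 0
    gap[hasParent] <- h[parent[hasParent]] - subh[hasParent]
    candidate <- size >= minSize & gap >= minGap & parent > 0

    # leaves under each node, computed on demand
    leavesOf <- function(v) {
        out <- integer(0)
        stack <- v
        while (length(stack) > 0) {
            x <- stack[length(stack)]
            stack <- stack[-length(stack)]
            kids <- hc$merge[x, ]
            for (ch in kids) {
                if (ch < 0) out <- c(out, -ch) else stack <- c(stack, ch)
            }
        }
        out
    }

    # maximal candidates: candidates none of whose ancestors qualify
    isMaximal <- function(v) {
        p <- parent[v]
        while (p > 0) {
            if (candidate[p]) return(FALSE)
            p <- parent[p]
        }
        TRUE
    }

    # Descend from a candidate towards tighter sub-branches. A branch
    # splits into two sub-branches when both hold >= minSize leaves
    # and both detach by at least splitRatio of the branch's own
    # attachment gap; a lone large sub-branch meeting the same bar is
    # followed down (shedding straggler leaves); otherwise the branch
    # is reported whole.
    splitRatio <- 0.3
    modules <- list()
    maximals <- integer(0)
    resolve <- function(v) {
        repeat {
            kids <- hc$merge[v, ]
            internal <- kids[kids > 0]
            big <- internal[size[internal] >= minSize]
            thr <- splitRatio * gap[v]
            if (length(big) == 2 && all(gap[big] >= thr)) {
                resolve(big[1])
                resolve(big[2])
                return(invisible(NULL))
            }
            if (length(big) == 1 && gap[big] >= thr) {
                v <- big
                next
            }
            modules[[length(modules) + 1L]] <<- leavesOf(v)
            return(invisible(NULL))
        }
    }
    for (v in which(candidate)) {
        if (isMaximal(v)) {
            maximals <- c(maximals, v)
            resolve(v)
        }
    }

    cl <- rep(0L, nGene)
    for (i in seq_along(modules)) cl[modules[[i]]] <- i
    # leaves inside a maximal candidate but shed while descending its
    # chain towards the reported modules
    shed <- setdiff(unlist(lapply(maximals, leavesOf)), which(cl > 0))
    list(cl = cl, shed = shed)
}

# Standardised separation of a 2-medoid split of one module: the mean
# cross-child dissimilarity minus the mean within-child dissimilarity,
# in units of the pooled within-child standard deviation. Near zero
# for a homogeneous module (PAM can only chase exchangeable noise),
# strongly positive when the module is really a union of two distinct
# tight groups, and negative when the "module" is anti-cohesive --
# members mutually distant but glued together by cross-pairs, the
# signature of a chaining artifact rather than a module.
.pamSplit <- function(T, genes) {
    sub <- T[genes, genes]
    cl <- cluster::pam(stats::as.dist(sub), k = 2, diss = TRUE,
                       cluster.only = TRUE)
    n1 <- sum(cl == 1); n2 <- sum(cl == 2)
    if (min(n1, n2) < 2) return(list(score = 0, members = NULL))
    w1 <- sub[cl == 1, cl == 1]
    w2 <- sub[cl == 2, cl == 2]
    within <- c(w1[upper.tri(w1)], w2[upper.tri(w2)])
    cross <- as.vector(sub[cl == 1, cl == 2])
    s <- stats::sd(within)
    if (s == 0) return(list(score = 0, members = NULL))
    list(score = (mean(cross) - mean(within)) / s,
         members = split(genes, cl))
}

# PAM-based refinement of the branch-decomposition modules (indices
# into the rows of T): reject anti-cohesive clusters
# (score <= -coherence) as unassigned, and recursively accept
# 2-medoid splits whose children both reach minSize and whose
# separation score is >= splitBar.
.refineModules <- function(T, cl, minSize, splitBar = 0.5,
                           coherence = 0.25) {
    queue <- setdiff(unique(cl), 0L)
    out <- cl
    nextId <- max(cl) + 1L
    while (length(queue) > 0) {
        id <- queue[1]; queue <- queue[-1]
        members <- which(out == id)
        if (length(members) < 4) next
        sp <- .pamSplit(T, members)
        if (sp$score <= -coherence) {
            out[members] <- 0L
        } else if (length(members) >= 2 * minSize &&
                   sp$score >= splitBar &&
                   !is.null(sp$members) &&
                   min(lengths(sp$members)) >= minSize) {
            out[sp$members[[2]]] <- nextId
            queue <- c(queue, id, nextId)
            nextId <- nextId + 1L
        }
    }
    out
}

# Reject entangled module pairs: two clusters whose mean cross
# dissimilarity is below their pooled mean internal dissimilarity
# attract each other more strongly than either coheres -- together
# they form a bipartite complex, not two modules. (Genuine module
# pairs produced by the PAM refinement always separate, since the
# split is only accepted when cross exceeds within.)
.rejectEntangled <- function(T, cl) {
    ids <- setdiff(unique(cl), 0L)
    drop <- integer(0)
    if (length(ids) >= 2) {
        prs <- utils::combn(ids, 2)
        for (q in seq_len(ncol(prs))) {
            m1 <- which(cl == prs[1, q]); m2 <- which(cl == prs[2, q])
            w1 <- T[m1, m1]; w2 <- T[m2, m2]
            within <- mean(c(w1[upper.tri(w1)], w2[upper.tri(w2)]))
            if (mean(T[m1, m2]) < within)
                drop <- union(drop, prs[, q])
        }
    }
    cl[cl %in% drop] <- 0L
    cl
}

# Hybrid-style assignment stage for the leaves shed while descending
# a candidate chain (pool): each is re-attached to its closest
# surviving module, provided it sits clearly below the typical
# unassigned gene's distance to that module. Any attachment that
# would turn a module anti-cohesive (see .pamSplit) is reverted
# wholesale.
.attachStragglers <- function(T, cl, pool, coherence = 0.25) {
    ids <- setdiff(unique(cl), 0L)
    pool <- pool[cl[pool] == 0L]
    if (length(ids) == 0 || length(pool) == 0) return(cl)
    grey <- which(cl == 0L)
    a <- vapply(ids, function(id)
        rowMeans(T[grey, which(cl == id), drop = FALSE]),
        numeric(length(grey)))
    a <- matrix(a, nrow = length(grey))
    poolRow <- match(pool, grey)
    best <- ids[max.col(-a[poolRow, , drop = FALSE],
                        ties.method = "first")]
    out <- cl
    for (j in seq_along(ids)) {
        cap <- stats::median(a[, j])
        take <- pool[best == ids[j] & a[poolRow, j] < cap]
        if (length(take) == 0) next
        out[take] <- ids[j]
        if (.pamSplit(T, which(out == ids[j]))$score <= -coherence)
            out[take] <- 0L
    }
    out
}

#' Extract differentially coexpressed modules from a dissimilarity
#'
#' Clusters genes on a coexpression-change dissimilarity, by standard
#' hierarchical clustering with average linkage followed by a tree cut
#' (adaptive by default, or a fixed height), or by partitioning around
#' medoids (PAM).
#'
#' For the hierarchical methods, clusters smaller than
#' \code{minModuleSize} are merged into the reserved unassigned label
#' \code{"grey"}; the adaptive cut additionally leaves genes outside
#' any tight branch unassigned. PAM assigns every gene to one of the
#' \code{k} medoid clusters (no unassigned label) with the
#' deterministic BUILD initialisation. All paths are deterministic for
#' fixed input and parameters; average-linkage merge ties follow the
#' fixed ordering of \code{\link[stats]{hclust}}.
#'
#' @param tdiss a \linkS4class{DissimilarityMatrix}.
#' @param method \code{"dynamic"} (adaptive branch decomposition,
#'   default), \code{"static"} (fixed-height cut) or \code{"pam"}.
#' @param minModuleSize minimum module size (default 20); smaller
#'   clusters are unassigned.
#' @param cutHeight cut height in (0, 1], required for
#'   \code{method = "static"}.
#' @param k number of clusters, required for \code{method = "pam"}.
#' @param gapFraction sensitivity of the adaptive cut: a branch
#'   qualifies as a module when the height gap separating it from the
#'   rest of the dendrogram exceeds this fraction of the robust
#'   dendrogram height scale (default 0.1).
#' @param refine apply the PAM-like refinement stage after the
#'   adaptive cut (default TRUE): a module that 2-medoid partitioning
#'   reveals to be the union of two well-separated groups (both of
#'   module size) is split, recursively; a cluster whose members are
#'   mutually *more* distant than they are to the other half -- an
#'   anti-cohesive chaining artifact, not a module -- is unassigned.
#' @return A \linkS4class{ModuleAssignment}.
#' @export
clusterModules <- function(tdiss,
                           method = c("dynamic", "static", "pam"),
                           minModuleSize = 20L, cutHeight = NULL,
                           k = NULL, gapFraction = 0.1,
                           refine = TRUE) {
    stopifnot(is(tdiss, "DissimilarityMatrix"))
    method <- match.arg(method)
    T <- dissimilarity(tdiss)
    if (any(!is.finite(T))) stop("dissimilarity has non-finite entries")
    genes <- rownames(T)
    if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(T)))
    minModuleSize <- as.integer(minModuleSize)
    params <- list(method = method, minModuleSize = minModuleSize,
                   cutHeight = cutHeight, k = k,
                   gapFraction = gapFraction, refine = refine,
                   dissimilarityVariant = tdiss@variant)

    if (method == "pam") {
        if (is.null(k)) stop("method = 'pam' requires 'k'")
        cl <- cluster::pam(stats::as.dist(T), k = k, diss = TRUE,
                           cluster.only = TRUE)
        return(new("ModuleAssignment", labels = .colourise(cl, genes),
                   params = params))
    }

    if (nrow(T) < minModuleSize) {
        warning("fewer genes (", nrow(T), ") than minModuleSize (",
                minModuleSize, "); all genes unassigned")
        return(new("ModuleAssignment",
                   labels = stats::setNames(rep("grey", nrow(T)), genes),
                   params = params))
    }

    hc <- stats::hclust(stats::as.dist(T), method = "average")
    # average linkage is monotone; absorb floating-point jitter in the
    # merge heights (equal-distance ties) so cutree accepts the tree
    if (is.unsorted(hc$height)) hc$height <- cummax(hc$height)
    if (method == "static") {
        if (is.null(cutHeight) || cutHeight <= 0 || cutHeight > 1)
            stop("method = 'static' requires cutHeight in (0, 1]")
        cl <- stats::cutree(hc, h = cutHeight)
        small <- names(table(cl))[table(cl) < minModuleSize]
        cl[cl %in% as.integer(small)] <- 0L
    } else {
        dc <- .dynamicCut(hc, minModuleSize, gapFraction)
        cl <- dc$cl
        if (refine) {
            cl <- .refineModules(T, cl, minModuleSize)
            cl <- .rejectEntangled(T, cl)
            cl <- .attachStragglers(T, cl, dc$shed)
        }
        sizes <- tabulate(cl)
        cl[cl %in% which(sizes < minModuleSize)] <- 0L
    }
    new("ModuleAssignment", labels = .colourise(cl, genes),
        params = params)
}

#' Per-module, per-condition mean expression
#'
#' Differentially coexpressed modules typically show little difference
#' in mean expression between conditions -- the signal is in the
#' correlation structure, not the level. This summary makes that easy
#' to check.
#'
#' @param x a \linkS4class{CoexDiffSet}.
#' @param modules a \linkS4class{ModuleAssignment} covering the genes
#'   of \code{x}.
#' @return data.frame with columns \code{module}, \code{size} and one
#'   mean-expression column per condition (unassigned genes included
#'   as \code{"grey"}).
#' @export
moduleMeanExpression <- function(x, modules) {
    stopifnot(is(x, "CoexDiffSet"), is(modules, "ModuleAssignment"))
    lab <- moduleLabels(modules)
    missing <- setdiff(rownames(x), names(lab))
    if (length(missing) > 0)
        stop("module assignment lacks gene(s): ",
             paste(utils::head(missing, 5), collapse = ", "))
    lab <- lab[rownames(x)]
    cond <- sampleConditions(x)
    m <- assay(x)
    mods <- names(moduleSizes(modules))
    mods <- mods[mods %in% lab]
    out <- data.frame(module = mods,
                      size = as.integer(table(lab)[mods]))
    for (k in levels(cond)) {
        out[[paste0("mean_", k)]] <- vapply(mods, function(mod) {
            mean(m[lab == mod, cond == k, drop = FALSE])
        }, numeric(1))
    }
    rownames(out) <- NULL
    out
}
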