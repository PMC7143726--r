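#' @include preprocess.R
NULL

.asWeighted <- function(x, transform = "sqrt") {
    if (is.matrix(x) && !is.null(attr(x, "precursorMz"))) return(x)
    normalizeForCosine(x, transform = transform)
}

#' Modified cosine similarity between two MS/MS spectra
#'
#' The shift-aware cosine at the heart of molecular networking. Candidate
#' fragment pairs are those aligning directly (\eqn{|m_a - m_b| \le} tol)
#' or after shifting one spectrum by the precursor-mass difference
#' \eqn{\Delta = p_a - p_b} (\eqn{|m_a - m_b - \Delta| \le} tol), so a
#' single modification moving a subset of fragments still scores. A
#' one-to-one matching is chosen greedily by descending product of peak
#' weights, each peak used at most once; the score is the sum of matched
#' weight products and lies in [0, 1] for unit-norm weights.
#'
#' @param specA,specB [Spectrum-class]/[ConsensusNode-class] objects, or
#'   weight matrices from [normalizeForCosine()].
#' @param fragmentTol fragment m/z tolerance in Da (default 0.5).
#' @param transform intensity transform applied when weighting raw
#'   spectra; see [normalizeForCosine()].
#' @return list with elements \code{cosine} (numeric in [0,1]) and
#'   \code{matchedPeaks} (integer).
#' @examples
#' a <- Spectrum("a", 500, mz = c(100, 200, 300), intensity = c(1, 2, 3))
#' modifiedCosine(a, a)$cosine  # 1
#' @export
modifiedCosine <- function(specA, specB, fragmentTol = 0.5,
                           transform = "sqrt") {
    wa <- .asWeighted(specA, transform)
    wb <- .asWeighted(specB, transform)
    delta <- attr(wa, "precursorMz") - attr(wb, "precursorMz")
    mzA <- wa[, "mz"]; wA <- wa[, "weight"]
    mzB <- wb[, "mz"]; wB <- wb[, "weight"]
    d <- outer(mzA, mzB, "-")
    cand <- abs(d) <= fragmentTol | abs(d - delta) <= fragmentTol
    if (!any(cand)) return(list(cosine = 0, matchedPeaks = 0L))
    idx <- which(cand, arr.ind = TRUE)
    score <- wA[idx[, 1L]] * wB[idx[, 2L]]
    ord <- order(-score, idx[, 1L], idx[, 2L])
    idx <- idx[ord, , drop = FALSE]; score <- score[ord]
    usedA <- logical(length(mzA)); usedB <- logical(length(mzB))
    total <- 0; nmatch <- 0L
    for (k in seq_along(score)) {
        i <- idx[k, 1L]; j <- idx[k, 2L]
        if (!usedA[i] && !usedB[j]) {
            usedA[i] <- TRUE; usedB[j] <- TRUE
            total <- total + score[k]
            nmatch <- nmatch + 1L
        }
    }
    list(cosine = min(total, 1), matchedPeaks = nmatch)
}

#' All-pairs modified cosine scores between consensus nodes
#'
#' @param nodes list of [ConsensusNode-class] objects.
#' @param fragmentTol fragment tolerance (Da).
#' @param transform intensity transform for weighting.
#' @return data.frame with columns \code{nodeA}, \code{nodeB} (nodeA <
#'   nodeB), \code{cosine}, \code{matchedPeaks}, one row per unordered
#'   node pair with at least one candidate peak pair.
#' @keywords internal
.allPairScores <- function(nodes, fragmentTol = 0.5, transform = "sqrt") {
    n <- length(nodes)
    ids <- vapply(nodes, nodeId, character(1))
    weighted <- lapply(nodes, .asWeighted, transform = transform)
    res <- vector("list", n * (n - 1L) %/% 2L)
    k <- 0L
    for (i in seq_len(max(0L, n - 1L))) {
        for (j in seq.int(i + 1L, n)) {
            sc <- modifiedCosine(weighted[[i]], weighted[[j]],
                                 fragmentTol = fragmentTol)
            if (sc$matchedPeaks > 0L) {
                k <- k + 1L
                a <- ids[i]; b <- ids[j]
                if (a > b) { tmp <- a; a <- b; b <- tmp }
                res[[k]] <- list(a, b, sc$cosine, sc$matchedPeaks)
            }
        }
    }
    if (k == 0L)
        return(data.frame(nodeA = character(), nodeB = character(),
                          cosine = numeric(), matchedPeaks = integer(),
                          stringsAsFactors = FALSE))
    res <- res[seq_len(k)]
    data.frame(
        nodeA = vapply(res, `[[`, character(1), 1L),
        nodeB = vapply(res, `[[`, character(1), 2L),
        cosine = vapply(res, `[[`, numeric(1), 3L),
        matchedPeaks = vapply(res, `[[`, integer(1), 4L),
        stringsAsFactors = FALSE)
}

.mutualTopK <- function(edges, topK) {
    if (!nrow(edges) || is.infinite(topK)) return(edges)
    nodes <- unique(c(edges$nodeA, edges$nodeB))
    topOf <- vector("list", length(nodes))
    names(topOf) <- nodes
    long <- rbind(
        data.frame(self = edges$nodeA, other = edges$nodeB,
                   cosine = edges$cosine, stringsAsFactors = FALSE),
        data.frame(self = edges$nodeB, other = edges$nodeA,
                   cosine = edges$cosine, stringsAsFactors = FALSE))
    # rank partners by descending cosine, node id breaking ties
    for (nd in nodes) {
        sub <- long[long$self == nd, , drop = FALSE]
        sub <- sub[order(-sub$cosine, sub$other), , drop = FALSE]
        topOf[[nd]] <- utils::head(sub$other, topK)
    }
    keep <- mapply(function(a, b)
        (b %in% topOf[[a]]) && (a %in% topOf[[b]]),
        edges$nodeA, edges$nodeB)
    edges[keep, , drop = FALSE]
}

.components <- function(ids, edges) {
    g <- igraph::graph_from_data_frame(
        d = edges[, c("nodeA", "nodeB")], directed = FALSE,
        vertices = data.frame(name = ids, stringsAsFactors = FALSE))
    comp <- igraph::components(g)$membership
    as.integer(comp[ids])
}

#' Build the molecular network from consensus nodes
#'
#' Applies the full network-construction procedure: (1) score all node
#' pairs with [modifiedCosine()]; (2) drop edges with cosine below
#' \code{minCosine} or fewer than \code{minMatchedPeaks} matched fragments;
#' (3) keep an edge only if each endpoint lies in the other's top
#' \code{topK} most similar partners (mutual top-K rule); (4) while any
#' connected component (molecular family) exceeds \code{maxFamilySize},
#' remove that family's lowest-cosine edge (ties broken by lower matched
#' peaks, then lexicographic node-id pair) and recompute components.
#'
#' @param nodes list of [ConsensusNode-class] objects (already
#'   precursor-window filtered).
#' @param minCosine minimum edge cosine score (default 0.65).
#' @param minMatchedPeaks minimum matched fragment pairs, inclusive
#'   (default 4).
#' @param topK mutual top-K neighbour rank (default 10).
#' @param maxFamilySize molecular-family size cap (default 500).
#' @param fragmentTol fragment tolerance in Da (default 0.5).
#' @param transform intensity transform for weighting.
#' @return A [MolecularNetwork-class]; singleton nodes keep their own
#'   family ids.
#' @export
buildNetwork <- function(nodes, minCosine = 0.65, minMatchedPeaks = 4,
                         topK = 10, maxFamilySize = 500, fragmentTol = 0.5,
                         transform = "sqrt") {
    if (!length(nodes))
        stop("need at least one consensus node")
    if (minCosine < 0 || minCosine > 1)
        stop("'minCosine' must lie in [0, 1]")
    ids <- vapply(nodes, nodeId, character(1))
    edges <- .allPairScores(nodes, fragmentTol = fragmentTol,
                            transform = transform)
    edges <- edges[edges$cosine >= minCosine &
                   edges$matchedPeaks >= minMatchedPeaks, , drop = FALSE]
    edges <- .mutualTopK(edges, topK)
    # family-size capping: remove weakest edges of oversized families
    repeat {
        comp <- .components(ids, edges)
        names(comp) <- ids
        sizes <- table(comp)
        big <- as.integer(names(sizes)[sizes > maxFamilySize])
        if (!length(big) || !nrow(edges)) break
        inBig <- comp[edges$nodeA] %in% big
        cand <- which(inBig)
        o <- cand[order(edges$cosine[cand], edges$matchedPeaks[cand],
                        edges$nodeA[cand], edges$nodeB[cand])][1L]
        edges <- edges[-o, , drop = FALSE]
    }
    comp <- .components(ids, edges)
    names(comp) <- ids
    rownames(edges) <- NULL
    new("MolecularNetwork", nodes = nodes, edges = edges, familyId = comp)
}
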