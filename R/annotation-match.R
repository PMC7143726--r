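#' @include networking.R annotation-mass.R
NULL

#' Match a node against a spectral library
#'
#' Library spectra are filtered in the same manner as the input data
#' (precursor-window removal, identical intensity weighting) before the
#' modified cosine is computed, and hits must clear both the score and the
#' matched-peak thresholds. Hits are returned sorted by descending score.
#'
#' @param queryNode a [ConsensusNode-class] or [Spectrum-class].
#' @param librarySpectra list of [Spectrum-class] library entries (their
#'   \code{spectrumId} is the compound name, as parsed from MGF
#'   \code{NAME} headers).
#' @param minScore minimum cosine score (default 0.65).
#' @param minMatched minimum matched peaks, inclusive (default 4).
#' @param fragmentTol fragment tolerance in Da (default 0.5).
#' @param window precursor-window half-width applied to the library
#'   entries (Da, default 17).
#' @param transform intensity transform for weighting.
#' @return data.frame of hits: \code{node_id}, \code{kind}
#'   (\code{"library_hit"}), \code{name}, \code{score},
#'   \code{matched_peaks}; empty (with a warning) for an empty library.
#' @export
libraryMatch <- function(queryNode, librarySpectra, minScore = 0.65,
                         minMatched = 4, fragmentTol = 0.5, window = 17,
                         transform = "sqrt") {
    empty <- data.frame(node_id = character(), kind = character(),
                        name = character(), score = numeric(),
                        matched_peaks = integer(), stringsAsFactors = FALSE)
    if (!length(librarySpectra)) {
        warning("empty spectral library; no annotation possible")
        return(empty)
    }
    qid <- if (is(queryNode, "ConsensusNode")) nodeId(queryNode)
           else spectrumId(queryNode)
    q <- removePrecursorWindow(queryNode, window)
    qw <- tryCatch(normalizeForCosine(q, transform = transform),
                   error = function(e) NULL)
    if (is.null(qw)) return(empty)
    hits <- lapply(librarySpectra, function(lib) {
        libF <- removePrecursorWindow(lib, window)
        lw <- tryCatch(normalizeForCosine(libF, transform = transform),
                       error = function(e) NULL)
        if (is.null(lw)) return(NULL)
        sc <- modifiedCosine(qw, lw, fragmentTol = fragmentTol)
        if (sc$cosine > minScore && sc$matchedPeaks >= minMatched)
            data.frame(node_id = qid, kind = "library_hit",
                       name = spectrumId(lib), score = sc$cosine,
                       matched_peaks = sc$matchedPeaks,
                       stringsAsFactors = FALSE)
        else NULL
    })
    out <- do.call(rbind, hits)
    if (is.null(out)) return(empty)
    out <- out[order(-out$score, out$name), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Default analogue mass-shift table
#'
#' Named neutral-mass deltas for common biosynthetic modifications:
#' deoxygenation (\code{-O}), acetylation (\code{+C2H2O}) and
#' deacetylation (\code{-C2H2O}).
#'
#' @return named numeric vector of mass shifts in Da.
#' @export
analogueDeltas <- function() {
    c("-O"     = -monoisotopicMass("O"),
      "+C2H2O" = monoisotopicMass("C2H2O"),
      "-C2H2O" = -monoisotopicMass("C2H2O"))
}

#' Find mass-shift analogues of a reference node
#'
#' Decodes every node's neutral mass from its precursor m/z and charge
#' (\eqn{M = z(m/z - m_p)}) and annotates nodes whose neutral-mass
#' difference from the reference matches a named delta within
#' \code{massTol}. By default the search is restricted to the reference's
#' molecular family, where structural analogues are expected to cluster.
#' The relation is symmetric up to sign: if B is the \code{+C2H2O}
#' analogue of A, then A is the \code{-C2H2O} analogue of B. A candidate
#' within \code{massTol} of the reference itself (delta 0) is never
#' called.
#'
#' @param network a [MolecularNetwork-class].
#' @param referenceNodeId node id of the reference compound.
#' @param deltas named numeric vector of neutral-mass shifts (Da); see
#'   [analogueDeltas()].
#' @param massTol matching tolerance in Da (default 0.01).
#' @param sameFamily restrict candidates to the reference's molecular
#'   family (default TRUE).
#' @return data.frame: \code{node_id}, \code{kind} (\code{"analogue"}),
#'   \code{name} (the delta label), \code{mass_delta} (observed neutral
#'   difference), \code{reference_node}.
#' @export
findAnalogues <- function(network, referenceNodeId,
                          deltas = analogueDeltas(), massTol = 0.01,
                          sameFamily = TRUE) {
    nodes <- networkNodes(network)
    ids <- vapply(nodes, nodeId, character(1))
    if (!referenceNodeId %in% ids)
        stop("unknown reference node: ", referenceNodeId)
    neutral <- vapply(nodes, function(n)
        neutralFromMz(precursorMz(n), charge(n)), numeric(1))
    refNeutral <- neutral[match(referenceNodeId, ids)]
    cand <- ids != referenceNodeId
    if (sameFamily) {
        fam <- familyIds(network)
        cand <- cand & fam[ids] == fam[[referenceNodeId]]
    }
    rows <- lapply(which(cand), function(i) {
        d <- neutral[i] - refNeutral
        hit <- which(abs(d - deltas) <= massTol)
        if (!length(hit)) return(NULL)
        data.frame(node_id = ids[i], kind = "analogue",
                   name = names(deltas)[hit[1L]], mass_delta = d,
                   reference_node = referenceNodeId,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(node_id = character(), kind = character(),
                          name = character(), mass_delta = numeric(),
                          reference_node = character(),
                          stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

# enumerate maximal residue-spaced paths in the peak DAG for one charge;
# virtual terminal anchors (protonated N-terminus at m/z = proton,
# C-terminus at water/z + proton) let a b1 or y1 ion contribute its own
# residue, so an unbroken b series reads out the full sequence
.ladderPaths <- function(mz, residueTable, fragmentTol, z,
                         anchors = TRUE, maxTags = 2000L) {
    nReal <- length(mz)
    anchorIdx <- integer(0)
    if (anchors) {
        anchorMz <- c(PROTON_MASS,
                      monoisotopicMass("H2O") / z + PROTON_MASS)
        anchorIdx <- nReal + seq_along(anchorMz)
        mz <- c(mz, anchorMz)
    }
    n <- length(mz)
    edges <- vector("list", n)   # per start peak: list of (to, residue)
    hasIncoming <- logical(n)
    for (i in seq_len(n)) {
        di <- mz - mz[i]
        for (r in seq_along(residueTable)) {
            js <- which(abs(di - residueTable[r] / z) <= fragmentTol)
            for (j in js) {
                edges[[i]] <- c(edges[[i]],
                                list(list(to = j, res = names(residueTable)[r])))
                hasIncoming[j] <- TRUE
            }
        }
    }
    paths <- list()
    walk <- function(i, peakIdx, resSeq) {
        if (length(paths) >= maxTags) return()
        ee <- edges[[i]]
        if (is.null(ee)) {
            if (length(resSeq))
                paths[[length(paths) + 1L]] <<-
                    list(peaks = peakIdx, residues = resSeq)
            return()
        }
        for (e in ee)
            walk(e$to, c(peakIdx, e$to), c(resSeq, e$res))
    }
    for (i in which(!hasIncoming)) walk(i, i, character(0))
    # drop virtual anchor indices from the supporting-peak lists
    lapply(paths, function(p) {
        p$peaks <- p$peaks[p$peaks <= nReal]
        p
    })
}

#' Read amino-acid sequence tags from fragment ladders
#'
#' Searches the peak list for chains of fragments whose consecutive m/z
#' differences equal amino-acid residue masses within \code{fragmentTol}
#' — the de novo sequence-tag reading used to annotate trap-associated
#' peptides. Singly-charged ladders use the residue masses directly;
#' doubly-charged ladders (enabled through \code{charges}) use half the
#' residue mass. Virtual terminal anchors (the protonated N-terminus for
#' b ions, water + proton for y ions) let the first ion of a series
#' contribute its own residue, so an unbroken b series reads out the
#' complete sequence. Maximal tags (not extendable at either end) with at
#' least \code{minTagLength} residues are returned; the isobaric pair
#' Leu/Ile is always reported as the merged symbol.
#'
#' @param spectrum a [Spectrum-class] or [ConsensusNode-class] with a
#'   high-resolution peak list.
#' @param residueTable named residue masses (default [residueMasses()]).
#' @param fragmentTol m/z tolerance in Da (default 0.02).
#' @param minTagLength minimum number of residues in a tag (default 3).
#' @param charges ladder charge states to scan (default 1; use
#'   \code{c(1, 2)} for doubly-charged peptides).
#' @return data.frame with one row per tag: \code{tag} (residues joined
#'   by \code{"-"}), \code{length}, \code{ladder_charge}, and
#'   \code{peak_indices} (supporting peak rows, comma separated). Empty
#'   for spectra with fewer than two peaks.
#' @export
peptideLadder <- function(spectrum, residueTable = residueMasses(),
                          fragmentTol = 0.02, minTagLength = 3,
                          charges = 1) {
    empty <- data.frame(tag = character(), length = integer(),
                        ladder_charge = integer(),
                        peak_indices = character(), stringsAsFactors = FALSE)
    mz <- peaks(spectrum)[, "mz"]
    if (length(mz) < 2L) return(empty)
    rows <- list()
    for (z in charges) {
        for (p in .ladderPaths(mz, residueTable, fragmentTol, z)) {
            if (length(p$residues) >= minTagLength)
                rows[[length(rows) + 1L]] <- data.frame(
                    tag = paste(p$residues, collapse = "-"),
                    length = length(p$residues),
                    ladder_charge = as.integer(z),
                    peak_indices = paste(p$peaks, collapse = ","),
                    stringsAsFactors = FALSE)
        }
    }
    if (!length(rows)) return(empty)
    out <- do.call(rbind, rows)
    out <- out[order(-out$length, out$tag, method = "radix"), ,
               drop = FALSE]
    out <- out[!duplicated(out[, c("tag", "peak_indices")]), , drop = FALSE]
    rownames(out) <- NULL
    out
}

.splitTag <- function(tag) strsplit(tag, "-", fixed = TRUE)[[1]]

.tagContains <- function(tagResidues, sub) {
    nl <- length(tagResidues); ns <- length(sub)
    if (ns > nl) return(FALSE)
    for (s in seq_len(nl - ns + 1L))
        if (all(tagResidues[s:(s + ns - 1L)] == sub)) return(TRUE)
    FALSE
}

#' Conserved sequence motif across a peptide cluster
#'
#' The longest residue string occurring as a contiguous substring of at
#' least \code{threshold} of the supplied tags (one best tag per node) —
#' used to expose the sequence core shared by a peptide subfamily.
#' Because b-ion ladders read N-to-C while y-ion ladders read the same
#' backbone C-to-N, a sequence tag is direction-ambiguous: a tag supports
#' a motif if the motif occurs in the tag or in its reversal, and of two
#' equally long, equally supported motif orientations the
#' lexicographically smaller string is reported.
#'
#' @param tags character vector of sequence tags (residues joined by
#'   \code{"-"}), typically the best tag of each node in a cluster.
#' @param threshold minimum supported fraction of tags (default 1 = all).
#' @return list with \code{motif} (the residue string, \code{""} when no
#'   shared residue exists or no tags are given), \code{length} (residue
#'   count) and \code{support} (logical per input tag).
#' @export
conservedMotif <- function(tags, threshold = 1) {
    if (!length(tags))
        return(list(motif = "", length = 0L, support = logical(0)))
    split <- lapply(tags, .splitTag)
    splitRev <- lapply(split, rev)
    # candidate substrings from every tag in both orientations
    cands <- unique(unlist(lapply(c(split, splitRev), function(tr) {
        n <- length(tr)
        unlist(lapply(seq_len(n), function(len)
            vapply(seq_len(n - len + 1L), function(s)
                paste(tr[s:(s + len - 1L)], collapse = "-"), character(1))))
    })))
    lens <- vapply(cands, function(cc) length(.splitTag(cc)), integer(1))
    cands <- cands[order(-lens, cands, method = "radix")]
    need <- threshold * length(tags)
    for (cc in cands) {
        sub <- .splitTag(cc)
        supp <- vapply(seq_along(split), function(i)
            .tagContains(split[[i]], sub) ||
            .tagContains(splitRev[[i]], sub), logical(1))
        if (sum(supp) >= need)
            return(list(motif = cc, length = length(sub), support = supp))
    }
    list(motif = "", length = 0L, support = logical(length(tags)))
}

#' Best sequence tag per node and cluster motif
#'
#' Convenience wrapper running [peptideLadder()] over a set of nodes,
#' keeping each node's longest tag, and extracting the conserved motif of
#' the cluster with [conservedMotif()]. When the member scans are
#' supplied, each node's ladders are read from every constituent spectrum
#' as well as the consensus peak list, and all tags are pooled: the
#' consensus merge (fragment-tolerance scale) can fuse neighbouring
#' singly- and doubly-charged ions, and a fragment dropped from one scan
#' is usually present in another, so member-level reading is considerably
#' more sensitive.
#'
#' @param nodes list of [ConsensusNode-class] objects (e.g. one molecular
#'   family).
#' @param memberSpectra optional list of the clustered [Spectrum-class]
#'   objects (any order); member scans are looked up by spectrum id.
#' @param ... passed on to [peptideLadder()].
#' @param threshold motif support threshold (fraction of tagged nodes).
#' @return list with \code{tags} (the best tag per node, ties broken
#'   alphabetically), \code{allTags} (every distinct tag per node) and
#'   \code{motif} (result of [conservedMotif()] over the best tags).
#' @export
clusterMotif <- function(nodes, memberSpectra = NULL, ..., threshold = 1) {
    specById <- NULL
    if (!is.null(memberSpectra)) {
        specById <- memberSpectra
        names(specById) <- vapply(memberSpectra, spectrumId, character(1))
    }
    perNode <- lapply(nodes, function(nd) {
        sources <- list(nd)
        if (!is.null(specById)) {
            mem <- intersect(memberSpectrumIds(nd), names(specById))
            sources <- c(sources, specById[mem])
        }
        lad <- do.call(rbind, lapply(sources, peptideLadder, ...))
        if (is.null(lad) || !nrow(lad)) return(NULL)
        lad <- lad[order(-lad$length, lad$tag, method = "radix"), ,
                   drop = FALSE]
        lad <- lad[!duplicated(lad$tag), , drop = FALSE]
        cbind(node_id = nodeId(nd),
              lad[, c("tag", "length", "ladder_charge")],
              stringsAsFactors = FALSE)
    })
    allTags <- do.call(rbind, perNode)
    if (is.null(allTags))
        allTags <- data.frame(node_id = character(), tag = character(),
                              length = integer(),
                              ladder_charge = integer(),
                              stringsAsFactors = FALSE)
    tags <- allTags[!duplicated(allTags$node_id), , drop = FALSE]
    rownames(tags) <- NULL
    list(tags = tags, allTags = allTags,
         motif = conservedMotif(tags$tag, threshold = threshold))
}
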