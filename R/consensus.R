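#' @include networking.R
NULL

# merge pooled peaks into consensus groups: intensity-weighted mean m/z,
# summed intensity, groups separated by more than fragmentTol from the
# running weighted mean
.mergePeaks <- function(mz, intensity, fragmentTol) {
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
    outMz <- numeric(length(mz)); outInt <- numeric(length(mz))
    n <- 0L
    gSum <- 0; gWSum <- 0
    for (k in seq_along(mz)) {
        if (n > 0L && (mz[k] - gWSum / gSum) <= fragmentTol) {
            gSum <- gSum + intensity[k]
            gWSum <- gWSum + mz[k] * intensity[k]
            outMz[n] <- gWSum / gSum
            outInt[n] <- gSum
        } else {
            n <- n + 1L
            gSum <- intensity[k]
            gWSum <- mz[k] * intensity[k]
            outMz[n] <- mz[k]
            outInt[n] <- gSum
        }
    }
    cbind(mz = outMz[seq_len(n)], intensity = outInt[seq_len(n)])
}

#' Collapse repeated spectra into consensus metabolite nodes
#'
#' Deterministic greedy single-pass clustering: spectra are sorted by
#' descending total intensity (ties by precursor m/z then spectrum id) and
#' each spectrum joins the first existing node whose seed spectrum lies
#' within \code{precursorTol} Da of its precursor, shares its charge state
#' and scores at least \code{minCosine} modified cosine against the seed;
#' otherwise it seeds a new node. The consensus peak list merges member
#' peaks within \code{fragmentTol} using intensity-weighted mean m/z and
#' summed intensity, and the representative precursor is the
#' intensity-weighted mean of the members' precursors. Every input spectrum
#' lands in exactly one node, the result is invariant under permutation of
#' the input, and a singleton node reproduces its member spectrum exactly.
#'
#' @param spectra list of (preprocessed) [Spectrum-class] objects.
#' @param precursorTol precursor m/z tolerance in Da (default 0.02).
#' @param minCosine within-cluster modified-cosine threshold (default 0.7,
#'   intentionally distinct from the network edge threshold).
#' @param fragmentTol fragment tolerance for cosine scoring and peak
#'   merging (Da, default 0.5).
#' @param transform intensity transform for cosine weighting.
#' @return list of [ConsensusNode-class] objects, ordered by seed creation
#'   (descending seed intensity), ids \code{N0001, N0002, ...}.
#' @export
clusterSpectra <- function(spectra, precursorTol = 0.02, minCosine = 0.7,
                           fragmentTol = 0.5, transform = "sqrt") {
    if (!length(spectra)) return(list())
    tot <- vapply(spectra, function(s) sum(peaks(s)[, "intensity"]),
                  numeric(1))
    prec <- vapply(spectra, precursorMz, numeric(1))
    ids <- vapply(spectra, spectrumId, character(1))
    chg <- vapply(spectra, charge, integer(1))
    ord <- order(-tot, prec, ids)
    seedPrec <- numeric(length(spectra))
    seedChg <- integer(length(spectra))
    seedW <- vector("list", length(spectra))
    members <- vector("list", length(spectra))
    nNodes <- 0L
    for (s in ord) {
        w <- tryCatch(normalizeForCosine(spectra[[s]], transform = transform),
                      error = function(e) NULL)
        placed <- FALSE
        if (nNodes > 0L && !is.null(w)) {
            cand <- which(abs(seedPrec[seq_len(nNodes)] - prec[s]) <= precursorTol &
                          seedChg[seq_len(nNodes)] == chg[s])
            for (cn in cand) {
                sc <- modifiedCosine(w, seedW[[cn]], fragmentTol = fragmentTol)
                if (sc$cosine >= minCosine) {
                    members[[cn]] <- c(members[[cn]], s)
                    placed <- TRUE
                    break
                }
            }
        }
        if (!placed) {
            nNodes <- nNodes + 1L
            seedPrec[nNodes] <- prec[s]
            seedChg[nNodes] <- chg[s]
            seedW[[nNodes]] <- w
            members[[nNodes]] <- s
        }
    }
    lapply(seq_len(nNodes), function(k) {
        mem <- members[[k]]
        memSpec <- spectra[mem]
        if (length(mem) == 1L) {
            sp <- memSpec[[1L]]
            pk <- peaks(sp)
            repPrec <- precursorMz(sp)
        } else {
            allPk <- do.call(rbind, lapply(memSpec, peaks))
            pk <- .mergePeaks(allPk[, "mz"], allPk[, "intensity"], fragmentTol)
            wTot <- pmax(tot[mem], .Machine$double.eps)
            repPrec <- sum(prec[mem] * wTot) / sum(wTot)
        }
        new("ConsensusNode",
            nodeId = sprintf("N%04d", k),
            precursorMz = repPrec,
            charge = seedChg[k],
            peaks = pk,
            memberSpectrumIds = ids[mem],
            sampleIds = sort(unique(stats::na.omit(
                vapply(memSpec, sampleId, character(1))))))
    })
}

#' Per-node detection counts across strains and stages
#'
#' For each consensus node, counts the distinct (species, strain, stage)
#' samples contributing at least one member spectrum, with the maximum
#' member total ion intensity retained as an abundance proxy for use
#' when no quantified feature table is available.
#'
#' @param nodes list of [ConsensusNode-class].
#' @param spectra the spectra that were clustered (source of sample links).
#' @param metadata validated sample metadata; every member sample id must
#'   be present (unjoinable ids are an error).
#' @return data.frame with one row per (node, species, strain, stage)
#'   combination observed: columns \code{node_id}, \code{species},
#'   \code{strain_id}, \code{stage}, \code{n_samples}, \code{max_intensity}.
#' @export
nodeDetectionTable <- function(nodes, spectra, metadata) {
    specSample <- vapply(spectra, sampleId, character(1))
    names(specSample) <- vapply(spectra, spectrumId, character(1))
    specTot <- vapply(spectra, function(s) sum(peaks(s)[, "intensity"]),
                      numeric(1))
    names(specTot) <- names(specSample)
    df <- do.call(rbind, lapply(nodes, function(nd)
        data.frame(node_id = nodeId(nd),
                   spectrum_id = memberSpectrumIds(nd),
                   stringsAsFactors = FALSE)))
    df$sample_id <- unname(specSample[df$spectrum_id])
    unknown <- setdiff(stats::na.omit(unique(df$sample_id)),
                       metadata$sample_id)
    if (length(unknown))
        stop("nodes reference unknown sample id(s): ",
             paste(unknown, collapse = ", "))
    i <- match(df$sample_id, metadata$sample_id)
    df$species <- metadata$species[i]
    df$strain_id <- metadata$strain_id[i]
    df$stage <- metadata$stage[i]
    df$intensity <- unname(specTot[df$spectrum_id])
    key <- interaction(df$node_id, df$species, df$strain_id, df$stage,
                       drop = TRUE, lex.order = TRUE)
    pieces <- split(df, key)
    out <- do.call(rbind, lapply(pieces, function(p)
        data.frame(node_id = p$node_id[1L], species = p$species[1L],
                   strain_id = p$strain_id[1L], stage = p$stage[1L],
                   n_samples = length(unique(p$sample_id)),
                   max_intensity = max(p$intensity),
                   stringsAsFactors = FALSE)))
    rownames(out) <- NULL
    out[order(out$node_id, out$species, out$strain_id, out$stage), ,
        drop = FALSE]
}

#' Node membership table
#'
#' Long table linking every clustered spectrum to its consensus node and
#' source sample, suitable for TSV export.
#'
#' @inheritParams nodeDetectionTable
#' @return data.frame with columns \code{node_id}, \code{spectrum_id},
#'   \code{sample_id}.
#' @export
nodeMembership <- function(nodes, spectra) {
    specSample <- vapply(spectra, sampleId, character(1))
    names(specSample) <- vapply(spectra, spectrumId, character(1))
    do.call(rbind, lapply(nodes, function(nd)
        data.frame(node_id = nodeId(nd),
                   spectrum_id = memberSpectrumIds(nd),
                   sample_id = unname(specSample[memberSpectrumIds(nd)]),
                   stringsAsFactors = FALSE)))
}
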