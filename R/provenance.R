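#' @include consensus.R
NULL

.PROVENANCE_CATEGORIES <- c("saprophytic_only", "predatory_only",
                            "both_stages", "blank")

#' Classify network nodes by life-stage provenance
#'
#' Reproduces the node colouring of the comparative analysis: a node is
#' \code{blank} (grey) if any member spectrum comes from a blank control
#' (solvent, medium, worm or internal standard) — blank membership
#' overrides everything else; otherwise it is \code{both_stages} (blue),
#' \code{saprophytic_only} (green) or \code{predatory_only} (red) according
#' to the life stages of the fungal samples in which it was detected.
#' "Detected" means at least one member MS/MS spectrum from that sample;
#' no intensity floor is applied.
#'
#' Alongside the category, the detection-frequency differential
#' \code{freq_diff} (fraction of predatory-stage samples containing the
#' node minus the same fraction for the saprophytic stage, in [-1, 1]) and
#' the per-species strain detection fractions (\code{frac_<species>}:
#' share of that species' strains with any detection) are emitted for the
#' downstream differential and prevalence filters.
#'
#' @param network a [MolecularNetwork-class] (or plain list of
#'   [ConsensusNode-class] objects).
#' @param metadata validated sample metadata covering every member sample.
#' @return data.frame with one row per node: \code{node_id},
#'   \code{category}, \code{n_saprophytic}, \code{n_predatory},
#'   \code{n_blank} (distinct-sample counts), \code{freq_diff}, and one
#'   \code{frac_<species>} column per fungal species in the metadata.
#' @export
assignProvenance <- function(network, metadata) {
    nodes <- if (is(network, "MolecularNetwork")) networkNodes(network)
             else network
    metadata <- validateSampleMetadata(metadata)
    fungal <- metadata[!metadata$is_blank, , drop = FALSE]
    speciesLevels <- sort(unique(fungal$species))
    nStrains <- vapply(speciesLevels, function(sp)
        length(unique(fungal$strain_id[fungal$species == sp])), integer(1))
    nPredSamples <- sum(fungal$stage == "predatory")
    nSapSamples <- sum(fungal$stage == "saprophytic")
    rows <- lapply(nodes, function(nd) {
        sids <- nd@sampleIds
        if (!length(memberSpectrumIds(nd)))
            stop("node ", nodeId(nd), " has no member spectra")
        unknown <- setdiff(sids, metadata$sample_id)
        if (length(unknown))
            stop("node ", nodeId(nd), " references unknown sample id(s): ",
                 paste(unknown, collapse = ", "))
        m <- metadata[match(sids, metadata$sample_id), , drop = FALSE]
        nBlank <- sum(m$is_blank)
        nSap <- sum(!m$is_blank & m$stage == "saprophytic")
        nPred <- sum(!m$is_blank & m$stage == "predatory")
        category <- if (nBlank > 0L) "blank"
            else if (nSap > 0L && nPred > 0L) "both_stages"
            else if (nPred > 0L) "predatory_only"
            else if (nSap > 0L) "saprophytic_only"
            else stop("node ", nodeId(nd),
                      " has members in no recognisable sample group")
        fracPred <- if (nPredSamples) nPred / nPredSamples else 0
        fracSap <- if (nSapSamples) nSap / nSapSamples else 0
        fr <- vapply(speciesLevels, function(sp) {
            det <- unique(m$strain_id[!m$is_blank & m$species == sp])
            if (nStrains[[sp]]) length(det) / nStrains[[sp]] else 0
        }, numeric(1))
        out <- data.frame(node_id = nodeId(nd), category = category,
                          n_saprophytic = nSap, n_predatory = nPred,
                          n_blank = nBlank,
                          freq_diff = fracPred - fracSap,
                          stringsAsFactors = FALSE)
        for (sp in speciesLevels) out[[paste0("frac_", sp)]] <- fr[[sp]]
        out
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Venn summary of node categories
#'
#' Counts and percentages of the three fungal node categories
#' (\code{both_stages}, \code{saprophytic_only}, \code{predatory_only});
#' blank nodes are excluded, as in the published Venn split. Percentages
#' sum to 100 up to rounding.
#'
#' @param provenance result of [assignProvenance()].
#' @return data.frame with columns \code{category}, \code{n},
#'   \code{percent}; zero rows (with a warning) if every node is blank.
#' @export
vennSummary <- function(provenance) {
    keep <- provenance$category != "blank"
    if (!any(keep)) {
        warning("all nodes originate from blank controls; empty Venn summary")
        return(data.frame(category = character(), n = integer(),
                          percent = numeric(), stringsAsFactors = FALSE))
    }
    cats <- c("both_stages", "saprophytic_only", "predatory_only")
    n <- vapply(cats, function(cc) sum(provenance$category[keep] == cc),
                integer(1))
    data.frame(category = cats, n = unname(n),
               percent = unname(100 * n / sum(n)),
               stringsAsFactors = FALSE)
}

#' Parent-mass histogram per provenance category
#'
#' Distribution of node precursor (parent) m/z per fungal category,
#' half-open bins \code{[lo, hi)} of width \code{binWidth}; blank nodes
#' are excluded so bin counts total the non-blank node count.
#'
#' @param provenance result of [assignProvenance()].
#' @param network the network (or node list) the provenance was computed
#'   from.
#' @param binWidth bin width in Da (default 50).
#' @return data.frame with columns \code{category}, \code{bin_start},
#'   \code{bin_end}, \code{count}.
#' @export
parentMassDistribution <- function(provenance, network, binWidth = 50) {
    nodes <- if (is(network, "MolecularNetwork")) networkNodes(network)
             else network
    ids <- vapply(nodes, nodeId, character(1))
    mz <- vapply(nodes, precursorMz, numeric(1))
    keep <- provenance$category != "blank"
    prov <- provenance[keep, , drop = FALSE]
    if (!nrow(prov))
        return(data.frame(category = character(), bin_start = numeric(),
                          bin_end = numeric(), count = integer(),
                          stringsAsFactors = FALSE))
    nodeMz <- mz[match(prov$node_id, ids)]
    binStart <- floor(nodeMz / binWidth) * binWidth
    key <- interaction(prov$category, binStart, drop = TRUE)
    pieces <- split(seq_len(nrow(prov)), key)
    out <- do.call(rbind, lapply(pieces, function(ix)
        data.frame(category = prov$category[ix[1L]],
                   bin_start = binStart[ix[1L]],
                   bin_end = binStart[ix[1L]] + binWidth,
                   count = length(ix), stringsAsFactors = FALSE)))
    rownames(out) <- NULL
    out[order(out$category, out$bin_start), , drop = FALSE]
}

#' Detection-frequency differential of shared nodes
#'
#' For nodes detected in both life stages, the difference between the
#' fraction of predatory-stage samples and the fraction of
#' saprophytic-stage samples containing the node. Positive values mean the
#' metabolite is detected more frequently once traps have formed.
#'
#' @param provenance result of [assignProvenance()].
#' @return data.frame with columns \code{node_id}, \code{freq_diff},
#'   restricted to \code{both_stages} nodes, with attribute
#'   \code{n_positive} (number with freq_diff > 0).
#' @export
detectionFrequencyDifferential <- function(provenance) {
    sub <- provenance[provenance$category == "both_stages",
                      c("node_id", "freq_diff"), drop = FALSE]
    rownames(sub) <- NULL
    attr(sub, "n_positive") <- sum(sub$freq_diff > 0)
    sub
}

#' Species-prevalence filter
#'
#' Selects nodes of a given category detected in strictly more than
#' \code{minFraction} of the strains of at least one species — the rule
#' used to sort out uncharacterised predatory-stage metabolites present in
#' over half of the strains of a species. Raising \code{minFraction} can
#' only shrink the selection.
#'
#' @param provenance result of [assignProvenance()] (carries the
#'   \code{frac_<species>} columns).
#' @param minFraction strain-fraction threshold, strict (default 0.5).
#' @param category node category to screen (default
#'   \code{"predatory_only"}).
#' @return data.frame of passing nodes: \code{node_id}, \code{category},
#'   one logical \code{pass_<species>} column per species, and
#'   \code{species} listing the qualifying species (comma separated).
#' @export
speciesPrevalenceFilter <- function(provenance, minFraction = 0.5,
                                    category = "predatory_only") {
    fracCols <- grep("^frac_", names(provenance), value = TRUE)
    if (!length(fracCols))
        stop("provenance table carries no per-species fraction columns")
    sub <- provenance[provenance$category == category, , drop = FALSE]
    species <- sub("^frac_", "", fracCols)
    pass <- as.data.frame(lapply(fracCols, function(cc)
        sub[[cc]] > minFraction))
    names(pass) <- paste0("pass_", species)
    keep <- if (nrow(sub)) rowSums(pass) > 0 else logical(0)
    out <- data.frame(node_id = sub$node_id, category = sub$category,
                      stringsAsFactors = FALSE)
    out <- cbind(out, pass)
    out$species <- apply(pass, 1L, function(p)
        paste(species[as.logical(p)], collapse = ","))
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}
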