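#' @include AllGenerics.R
NULL

#' @rdname spectra-accessors
setMethod("precursorMz", "Spectrum", function(object) object@precursorMz)
#' @rdname spectra-accessors
setMethod("charge", "Spectrum", function(object) object@charge)
#' @rdname spectra-accessors
setMethod("peaks", "Spectrum", function(object) object@peaks)
#' @rdname spectra-accessors
setMethod("peakCount", "Spectrum", function(object) nrow(object@peaks))
#' @rdname spectra-accessors
setMethod("spectrumId", "Spectrum", function(object) object@spectrumId)
#' @rdname spectra-accessors
setMethod("retentionTime", "Spectrum", function(object) object@retentionTime)
#' @rdname spectra-accessors
setMethod("sampleId", "Spectrum", function(object) object@sampleId)

#' @rdname spectra-accessors
setMethod("precursorMz", "ConsensusNode", function(object) object@precursorMz)
#' @rdname spectra-accessors
setMethod("charge", "ConsensusNode", function(object) object@charge)
#' @rdname spectra-accessors
setMethod("peaks", "ConsensusNode", function(object) object@peaks)
#' @rdname spectra-accessors
setMethod("peakCount", "ConsensusNode", function(object) nrow(object@peaks))
#' @rdname spectra-accessors
setMethod("nodeId", "ConsensusNode", function(object) object@nodeId)
#' @rdname spectra-accessors
setMethod("sampleId", "ConsensusNode", function(object) object@sampleIds)
#' @rdname spectra-accessors
setMethod("memberSpectrumIds", "ConsensusNode",
    function(object) object@memberSpectrumIds)
#' @rdname spectra-accessors
setMethod("memberCount", "ConsensusNode",
    function(object) length(object@memberSpectrumIds))

#' @rdname network-accessors
setMethod("networkNodes", "MolecularNetwork", function(object) object@nodes)
#' @rdname network-accessors
setMethod("networkEdges", "MolecularNetwork", function(object) object@edges)
#' @rdname network-accessors
setMethod("familyIds", "MolecularNetwork", function(object) object@familyId)
#' @rdname network-accessors
setMethod("nodeIds", "MolecularNetwork",
    function(object) vapply(object@nodes, nodeId, character(1)))

setMethod("show", "Spectrum", function(object) {
    cat("Spectrum", object@spectrumId, "\n",
        " precursor m/z: ", format(object@precursorMz, digits = 8),
        "  charge: ", object@charge, "+\n",
        " peaks: ", nrow(object@peaks),
        "  sample: ", object@sampleId, "\n", sep = "")
    invisible(NULL)
})

setMethod("show", "ConsensusNode", function(object) {
    cat("ConsensusNode", object@nodeId, "\n",
        " precursor m/z: ", format(object@precursorMz, digits = 8),
        "  charge: ", object@charge, "+\n",
        " consensus peaks: ", nrow(object@peaks),
        "  members: ", length(object@memberSpectrumIds),
        "  samples: ", length(object@sampleIds), "\n", sep = "")
    invisible(NULL)
})

setMethod("show", "MolecularNetwork", function(object) {
    nfam <- length(unique(object@familyId))
    cat("MolecularNetwork\n",
        " nodes: ", length(object@nodes),
        "  edges: ", nrow(object@edges),
        "  molecular families: ", nfam, "\n", sep = "")
    if (length(object@familyId)) {
        sizes <- table(object@familyId)
        cat(" largest family: ", max(sizes), " node(s)\n", sep = "")
    }
    invisible(NULL)
})
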