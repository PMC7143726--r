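#' @import methods
NULL

#' Spectrum: a single MS/MS scan
#'
#' An MS/MS spectrum acquired in positive ionization mode: the precursor
#' mass-to-charge ratio, its charge state, the retention time and the peak
#' list (fragment m/z and intensity), plus the identifier of the sample the
#' scan came from. Peaks are stored as a two-column numeric matrix
#' (\code{mz}, \code{intensity}) sorted by ascending m/z; duplicate m/z
#' values are merged at construction by summing intensities.
#'
#' @slot spectrumId character(1), opaque unique identifier.
#' @slot precursorMz numeric(1), precursor m/z in Thomson, strictly positive.
#' @slot charge integer(1), precursor charge state, at least 1 (the sign is
#'   ignored; all data are positive mode).
#' @slot retentionTime numeric(1), retention time in seconds (may be NA).
#' @slot peaks numeric matrix, columns \code{mz} and \code{intensity}.
#' @slot sampleId character(1), reference into the sample metadata table
#'   (may be NA for library spectra).
#'
#' @seealso [Spectrum()] for the constructor, [readMgf()] to import scans.
#' @name Spectrum-class
#' @aliases Spectrum-class
#' @exportClass Spectrum
setClass("Spectrum",
    representation(
        spectrumId    = "character",
        precursorMz   = "numeric",
        charge        = "integer",
        retentionTime = "numeric",
        peaks         = "matrix",
        sampleId      = "character"
    )
)

setValidity("Spectrum", function(object) {
    msg <- character()
    if (length(object@spectrumId) != 1L || is.na(object@spectrumId))
        msg <- c(msg, "'spectrumId' must be a single non-NA string")
    if (length(object@precursorMz) != 1L || is.na(object@precursorMz) ||
        object@precursorMz <= 0)
        msg <- c(msg, "'precursorMz' must be a single positive number")
    if (length(object@charge) != 1L || is.na(object@charge) ||
        object@charge < 1L)
        msg <- c(msg, "'charge' must be a single integer >= 1")
    pk <- object@peaks
    if (!is.numeric(pk) || ncol(pk) != 2L ||
        !identical(colnames(pk), c("mz", "intensity")))
        msg <- c(msg, "'peaks' must be a numeric matrix with columns 'mz' and 'intensity'")
    else if (nrow(pk)) {
        if (any(pk[, "mz"] <= 0))
            msg <- c(msg, "peak m/z values must be > 0")
        if (any(pk[, "intensity"] < 0))
            msg <- c(msg, "peak intensities must be >= 0")
        if (nrow(pk) > 1L && any(diff(pk[, "mz"]) <= 0))
            msg <- c(msg, "peaks must be strictly ascending in m/z")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' Peaks are sorted by ascending m/z; exact duplicate m/z values are merged
#' by summing their intensities so the stored peak list is strictly
#' ascending.
#'
#' @param spectrumId unique identifier for the scan.
#' @param precursorMz precursor m/z (Th), > 0.
#' @param mz,intensity numeric vectors of equal length with the fragment
#'   peak list.
#' @param charge precursor charge state (>= 1); a negative value is taken as
#'   its absolute value since acquisition is positive mode.
#' @param retentionTime retention time in seconds.
#' @param sampleId identifier of the originating sample.
#' @return A [Spectrum-class] object.
#' @examples
#' sp <- Spectrum("s1", precursorMz = 500, mz = c(100, 200), intensity = c(1, 2))
#' peakCount(sp)
#' @export
Spectrum <- function(spectrumId, precursorMz, mz, intensity, charge = 1L,
                     retentionTime = NA_real_, sampleId = NA_character_) {
    stopifnot(length(mz) == length(intensity))
    charge <- as.integer(abs(charge))
    o <- order(mz)
    mz <- as.numeric(mz[o]); intensity <- as.numeric(intensity[o])
    if (anyDuplicated(mz)) {
        intensity <- as.numeric(tapply(intensity, factor(mz, levels = unique(mz)), sum))
        mz <- unique(mz)
    }
    pk <- cbind(mz = mz, intensity = intensity)
    new("Spectrum", spectrumId = as.character(spectrumId),
        precursorMz = as.numeric(precursorMz), charge = charge,
        retentionTime = as.numeric(retentionTime), peaks = pk,
        sampleId = as.character(sampleId))
}

#' ConsensusNode: a merged spectrum representing a putative metabolite
#'
#' Repeated MS/MS scans of the same analyte across samples are collapsed
#' into one consensus node. The representative precursor m/z is the
#' intensity-weighted mean of the members' precursors, consensus peaks merge
#' member fragments within the fragment tolerance, and the node keeps full
#' provenance: which scans and which samples contributed.
#'
#' @slot nodeId character(1), unique node identifier.
#' @slot precursorMz numeric(1), representative precursor m/z (Th).
#' @slot charge integer(1), common charge state of all members.
#' @slot peaks numeric matrix (\code{mz}, \code{intensity}), consensus peak
#'   list, ascending m/z.
#' @slot memberSpectrumIds character, ids of the constituent scans.
#' @slot sampleIds character, distinct sample ids the members came from.
#'
#' @seealso [clusterSpectra()] which creates consensus nodes.
#' @name ConsensusNode-class
#' @exportClass ConsensusNode
setClass("ConsensusNode",
    representation(
        nodeId            = "character",
        precursorMz       = "numeric",
        charge            = "integer",
        peaks             = "matrix",
        memberSpectrumIds = "character",
        sampleIds         = "character"
    )
)

setValidity("ConsensusNode", function(object) {
    msg <- character()
    if (length(object@memberSpectrumIds) < 1L)
        msg <- c(msg, "a consensus node must have at least one member spectrum")
    if (length(object@precursorMz) != 1L || object@precursorMz <= 0)
        msg <- c(msg, "'precursorMz' must be a single positive number")
    if (length(object@charge) != 1L || object@charge < 1L)
        msg <- c(msg, "'charge' must be >= 1")
    pk <- object@peaks
    if (!identical(colnames(pk), c("mz", "intensity")))
        msg <- c(msg, "'peaks' must have columns 'mz' and 'intensity'")
    else if (nrow(pk) > 1L && any(diff(pk[, "mz"]) <= 0))
        msg <- c(msg, "consensus peaks must be strictly ascending in m/z")
    if (length(msg)) msg else TRUE
})

#' MolecularNetwork: the graph of consensus metabolite nodes
#'
#' Nodes are consensus MS/MS spectra; edges connect nodes whose modified
#' cosine similarity passed the score and matched-peak thresholds plus the
#' mutual top-K rule. Connected components are molecular families,
#' interpreted as structural classes, and are capped at a maximum size by
#' removing the weakest edges.
#'
#' @slot nodes list of [ConsensusNode-class] objects.
#' @slot edges data.frame with columns \code{nodeA}, \code{nodeB} (ids,
#'   nodeA < nodeB), \code{cosine}, \code{matchedPeaks}.
#' @slot familyId named integer vector mapping node id to molecular-family
#'   (connected-component) id.
#'
#' @seealso [buildNetwork()], [writeNetworkGraphML()].
#' @name MolecularNetwork-class
#' @exportClass MolecularNetwork
setClass("MolecularNetwork",
    representation(
        nodes    = "list",
        edges    = "data.frame",
        familyId = "integer"
    )
)

setValidity("MolecularNetwork", function(object) {
    msg <- character()
    ids <- vapply(object@nodes, function(n) n@nodeId, character(1))
    if (anyDuplicated(ids))
        msg <- c(msg, "duplicate node ids")
    ed <- object@edges
    need <- c("nodeA", "nodeB", "cosine", "matchedPeaks")
    if (!all(need %in% names(ed)))
        msg <- c(msg, "edges must have columns nodeA, nodeB, cosine, matchedPeaks")
    else if (nrow(ed)) {
        if (!all(ed$nodeA %in% ids) || !all(ed$nodeB %in% ids))
            msg <- c(msg, "edge endpoints must be existing node ids")
        if (any(ed$nodeA == ed$nodeB))
            msg <- c(msg, "self-edges are not allowed")
        if (any(ed$cosine < 0 | ed$cosine > 1 + 1e-9))
            msg <- c(msg, "edge cosine must lie in [0, 1]")
        if (any(ed$matchedPeaks < 0))
            msg <- c(msg, "matchedPeaks must be >= 0")
    }
    if (length(ids) && !identical(sort(names(object@familyId)), sort(ids)))
        msg <- c(msg, "familyId must be named by exactly the node ids")
    if (length(msg)) msg else TRUE
})
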