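#' @include AllClasses.R
NULL

#' Accessors for spectral objects
#'
#' Small generic accessors shared by [Spectrum-class] and
#' [ConsensusNode-class]: the precursor m/z, charge state, peak matrix and
#' peak count, and the identifiers tying an object to scans and samples.
#'
#' @param object a \code{Spectrum}, \code{ConsensusNode} or
#'   \code{MolecularNetwork}.
#' @return \code{precursorMz}, \code{retentionTime}: numeric(1).
#'   \code{charge}, \code{peakCount}: integer(1). \code{peaks}: two-column
#'   numeric matrix. \code{spectrumId}, \code{nodeId}, \code{sampleId}:
#'   character.
#' @examples
#' sp <- Spectrum("s1", 500, mz = c(100, 200), intensity = c(1, 2))
#' precursorMz(sp); charge(sp); peaks(sp)
#' @name spectra-accessors
NULL

#' @rdname spectra-accessors
#' @export
setGeneric("precursorMz", function(object) standardGeneric("precursorMz"))
#' @rdname spectra-accessors
#' @export
setGeneric("charge", function(object) standardGeneric("charge"))
#' @rdname spectra-accessors
#' @export
setGeneric("peaks", function(object) standardGeneric("peaks"))
#' @rdname spectra-accessors
#' @export
setGeneric("peakCount", function(object) standardGeneric("peakCount"))
#' @rdname spectra-accessors
#' @export
setGeneric("spectrumId", function(object) standardGeneric("spectrumId"))
#' @rdname spectra-accessors
#' @export
setGeneric("retentionTime", function(object) standardGeneric("retentionTime"))
#' @rdname spectra-accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname spectra-accessors
#' @export
setGeneric("nodeId", function(object) standardGeneric("nodeId"))

#' @rdname spectra-accessors
#' @export
setGeneric("memberSpectrumIds",
    function(object) standardGeneric("memberSpectrumIds"))
#' @rdname spectra-accessors
#' @export
setGeneric("memberCount", function(object) standardGeneric("memberCount"))

#' Accessors for molecular networks
#'
#' @param object a [MolecularNetwork-class].
#' @return \code{networkNodes}: list of consensus nodes. \code{networkEdges}:
#'   data.frame of scored edges. \code{familyIds}: named integer vector of
#'   molecular-family (connected component) ids. \code{nodeIds}: character
#'   vector of node identifiers.
#' @name network-accessors
NULL

#' @rdname network-accessors
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))
#' @rdname network-accessors
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))
#' @rdname network-accessors
#' @export
setGeneric("familyIds", function(object) standardGeneric("familyIds"))
#' @rdname network-accessors
#' @export
setGeneric("nodeIds", function(object) standardGeneric("nodeIds"))
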