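#' @include AllClasses.R
NULL

#' Remove fragment peaks near the precursor
#'
#' Drops every fragment ion within +/- \code{window} Da of the precursor
#' m/z (boundary inclusive), the standard cleaning step before spectral
#' similarity scoring: residual precursor signal and its isotopes otherwise
#' dominate the cosine. The operation is idempotent and never increases the
#' peak count; the input object is not modified.
#'
#' @param spectrum a [Spectrum-class] or [ConsensusNode-class].
#' @param window half-width of the removal window in Da (default 17).
#' @return An object of the same class with the windowed peaks removed.
#' @examples
#' sp <- Spectrum("s", 500, mz = c(482.9, 483.5, 490), intensity = c(1, 1, 1))
#' peaks(removePrecursorWindow(sp))  # only 482.9 survives
#' @export
removePrecursorWindow <- function(spectrum, window = 17) {
    if (!is.numeric(window) || length(window) != 1L || window < 0)
        stop("'window' must be a single non-negative number")
    pk <- peaks(spectrum)
    keep <- abs(pk[, "mz"] - precursorMz(spectrum)) > window
    out <- spectrum
    out@peaks <- pk[keep, , drop = FALSE]
    out
}

#' Square-root intensity weighting for cosine scoring
#'
#' Converts a peak list into the weight vector used by the modified cosine:
#' intensities are square-root transformed (damping the dominance of base
#' peaks) and scaled to unit Euclidean norm, so a spectrum scored against
#' itself gives exactly 1. The transform can be switched off, in which case
#' raw intensities are norm-scaled.
#'
#' @param spectrum a [Spectrum-class] or [ConsensusNode-class] with at
#'   least one peak (an empty spectrum is an unscorable spectrum and an
#'   error).
#' @param transform \code{"sqrt"} (default) or \code{"none"}.
#' @return A numeric matrix with columns \code{mz} and \code{weight}
#'   (sum of squared weights = 1), with the precursor m/z attached as
#'   attribute \code{precursorMz}.
#' @export
normalizeForCosine <- function(spectrum, transform = c("sqrt", "none")) {
    transform <- match.arg(transform)
    pk <- peaks(spectrum)
    if (nrow(pk) == 0L)
        stop("unscorable spectrum: no peaks remain after filtering")
    w <- if (transform == "sqrt") sqrt(pk[, "intensity"]) else pk[, "intensity"]
    nrm <- sqrt(sum(w^2))
    if (nrm == 0)
        stop("unscorable spectrum: all peak intensities are zero")
    out <- cbind(mz = pk[, "mz"], weight = w / nrm)
    attr(out, "precursorMz") <- precursorMz(spectrum)
    out
}
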