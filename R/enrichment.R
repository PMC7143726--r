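#' @include spectra-io.R
NULL

#' Read a quantified feature table
#'
#' Delimited table from upstream feature detection/alignment: columns
#' \code{feature_id}, \code{mz}, \code{rt}, then one peak-area column per
#' sample. The feature-detection thresholds themselves (mass tolerance,
#' minimum intensity, retention-time alignment) belong to the upstream
#' tool; here the table is validated on ingest: areas must be numeric and
#' non-negative, m/z positive, feature ids unique.
#'
#' @param path path to a TSV (or CSV if \code{sep = ","}) file.
#' @param sep field separator (default tab).
#' @return data.frame with \code{feature_id}, \code{mz}, \code{rt} and one
#'   numeric column per sample.
#' @export
readFeatureTable <- function(path, sep = "\t") {
    if (!file.exists(path))
        stop("feature table not found: ", path)
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE)
    validateFeatureTable(tab)
}

#' @rdname readFeatureTable
#' @param features a feature data.frame to validate in place.
#' @export
validateFeatureTable <- function(features) {
    need <- c("feature_id", "mz", "rt")
    missing <- setdiff(need, names(features))
    if (length(missing))
        stop("feature table missing column(s): ",
             paste(missing, collapse = ", "))
    if (anyDuplicated(features$feature_id))
        stop("duplicated feature_id in feature table")
    if (any(features$mz <= 0))
        stop("feature m/z must be > 0")
    areaCols <- setdiff(names(features), need)
    if (!length(areaCols))
        stop("feature table has no sample area columns")
    areas <- as.matrix(features[, areaCols, drop = FALSE])
    if (!is.numeric(areas) || anyNA(areas) || any(areas < 0))
        stop("peak areas must be numeric and >= 0")
    features
}

.featureAreas <- function(features) {
    areaCols <- setdiff(names(features), c("feature_id", "mz", "rt"))
    m <- as.matrix(features[, areaCols, drop = FALSE])
    rownames(m) <- features$feature_id
    m
}

#' Four-step predatory-stage enrichment filter
#'
#' Screens quantified features for significant enrichment in the predatory
#' stage, in order:
#' \describe{
#'   \item{i}{blank ceiling — mean peak area across blank samples below
#'     \code{blankMax};}
#'   \item{ii}{mean predatory-stage area more than \code{fold} times the
#'     blank mean (a zero blank mean passes when the predatory mean is
#'     positive);}
#'   \item{iii}{mean predatory-stage area more than \code{fold} times the
#'     saprophytic-stage mean;}
#'   \item{iv}{significance — a two-sided Welch t-test (or Mann-Whitney)
#'     on log10(area + 1), predatory vs saprophytic, with
#'     Benjamini-Hochberg (or Bonferroni) adjustment computed across the
#'     features that reached step iv; adjusted p below \code{alpha}.}
#' }
#' A feature is \code{selected} iff it passes all four steps. If either
#' stage has fewer than two samples the test is untestable: the feature is
#' flagged and not selected. Raising \code{fold} never enlarges the
#' selected set; raising \code{blankMax} never shrinks the step-i
#' survivors.
#'
#' @param features validated feature table (see [readFeatureTable()]).
#' @param metadata validated sample metadata; blank samples are required.
#' @param blankMax step-i blank mean ceiling (default 1e5).
#' @param fold step-ii/iii fold threshold (default 10).
#' @param alpha step-iv adjusted-p threshold (default 0.05).
#' @param test \code{"welch"} (default) or \code{"mannwhitney"}.
#' @param adjust \code{"bh"} (default) or \code{"bonferroni"}.
#' @return data.frame with one row per feature: group means, fold changes
#'   (\code{Inf} when the denominator mean is zero and the numerator is
#'   positive), \code{p_value}, \code{adjusted_p}, per-step logicals
#'   \code{passed_i}..\code{passed_iv}, \code{untestable},
#'   \code{det_predatory}/\code{det_saprophytic} (detection fractions,
#'   area > 0), and \code{selected}.
#' @export
enrichmentFilter <- function(features, metadata, blankMax = 1e5, fold = 10,
                             alpha = 0.05,
                             test = c("welch", "mannwhitney"),
                             adjust = c("bh", "bonferroni")) {
    test <- match.arg(test)
    adjust <- match.arg(adjust)
    features <- validateFeatureTable(features)
    metadata <- validateSampleMetadata(metadata)
    areas <- .featureAreas(features)
    missing <- setdiff(colnames(areas), metadata$sample_id)
    if (length(missing))
        stop("feature table references unknown sample id(s): ",
             paste(missing, collapse = ", "))
    m <- metadata[match(colnames(areas), metadata$sample_id), , drop = FALSE]
    blankIdx <- which(m$is_blank)
    predIdx <- which(!m$is_blank & m$stage == "predatory")
    sapIdx <- which(!m$is_blank & m$stage == "saprophytic")
    if (!length(blankIdx))
        stop("no blank samples present; the blank-ceiling step cannot run")
    untestable <- length(predIdx) < 2L || length(sapIdx) < 2L
    meanBlank <- rowMeans(areas[, blankIdx, drop = FALSE])
    meanPred <- rowMeans(areas[, predIdx, drop = FALSE])
    meanSap <- rowMeans(areas[, sapIdx, drop = FALSE])
    foldOf <- function(num, den) ifelse(den > 0, num / den,
                                        ifelse(num > 0, Inf, NA_real_))
    foldPredBlank <- foldOf(meanPred, meanBlank)
    foldPredSap <- foldOf(meanPred, meanSap)
    passI <- meanBlank < blankMax
    passII <- passI & !is.na(foldPredBlank) & foldPredBlank > fold
    passIII <- passII & !is.na(foldPredSap) & foldPredSap > fold
    p <- rep(NA_real_, nrow(areas))
    if (!untestable && any(passIII)) {
        lp <- log10(areas[, predIdx, drop = FALSE] + 1)
        ls <- log10(areas[, sapIdx, drop = FALSE] + 1)
        for (r in which(passIII)) {
            p[r] <- switch(test,
                welch = tryCatch(
                    stats::t.test(lp[r, ], ls[r, ])$p.value,
                    error = function(e) 1),   # constant data: no evidence
                mannwhitney = suppressWarnings(
                    stats::wilcox.test(lp[r, ], ls[r, ])$p.value))
        }
    }
    adjP <- rep(NA_real_, nrow(areas))
    tested <- which(!is.na(p))
    if (length(tested))
        adjP[tested] <- stats::p.adjust(p[tested],
            method = if (adjust == "bh") "BH" else "bonferroni")
    passIV <- passIII & !untestable & !is.na(adjP) & adjP < alpha
    detFrac <- function(idx) rowMeans(areas[, idx, drop = FALSE] > 0)
    data.frame(
        feature_id = features$feature_id,
        mz = features$mz, rt = features$rt,
        mean_blank = meanBlank, mean_pred = meanPred, mean_sap = meanSap,
        fold_pred_vs_blank = foldPredBlank,
        fold_pred_vs_sap = foldPredSap,
        p_value = p, adjusted_p = adjP,
        passed_i = passI, passed_ii = passII, passed_iii = passIII,
        passed_iv = passIV,
        untestable = untestable,
        det_predatory = detFrac(predIdx),
        det_saprophytic = detFrac(sapIdx),
        selected = passIV,
        stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank enriched features for structural identification
#'
#' From the enrichment survivors, keeps features that are also detected
#' more frequently in the predatory than in the saprophytic stage, orders
#' them by mean predatory-stage area (descending; ties broken by feature
#' id for determinism), and truncates to the top \code{topN}.
#'
#' @param results output of [enrichmentFilter()].
#' @param topN maximum number of features to return (default 100).
#' @param onlySelected restrict to features passing all four steps
#'   (default TRUE).
#' @return The ranked subset of \code{results}, with a \code{rank} column.
#' @export
rankForIdentification <- function(results, topN = 100, onlySelected = TRUE) {
    sub <- results
    if (onlySelected) sub <- sub[sub$selected, , drop = FALSE]
    sub <- sub[sub$det_predatory > sub$det_saprophytic, , drop = FALSE]
    sub <- sub[order(-sub$mean_pred, sub$feature_id), , drop = FALSE]
    sub <- utils::head(sub, topN)
    if (nrow(sub)) sub$rank <- seq_len(nrow(sub))
    else sub$rank <- integer(0)
    rownames(sub) <- NULL
    sub
}

#' Link quantified features to network nodes by precursor mass
#'
#' Matches features to consensus nodes whose representative precursor m/z
#' lies within \code{ppm} parts-per-million (and, optionally, whose
#' retention time is within \code{rtTol} seconds).
#'
#' @param features feature table.
#' @param network a [MolecularNetwork-class] or node list.
#' @param ppm mass tolerance in ppm (default 5).
#' @param rtTol optional retention-time window in seconds (ignored when NA
#'   or when nodes carry no retention time).
#' @return data.frame with columns \code{feature_id}, \code{node_id},
#'   \code{ppm_error}.
#' @export
linkFeaturesToNodes <- function(features, network, ppm = 5, rtTol = NA) {
    nodes <- if (is(network, "MolecularNetwork")) networkNodes(network)
             else network
    nid <- vapply(nodes, nodeId, character(1))
    nmz <- vapply(nodes, precursorMz, numeric(1))
    out <- lapply(seq_len(nrow(features)), function(r) {
        tol <- features$mz[r] * ppm * 1e-6
        hit <- which(abs(nmz - features$mz[r]) <= tol)
        if (!length(hit)) return(NULL)
        data.frame(feature_id = features$feature_id[r],
                   node_id = nid[hit],
                   ppm_error = (nmz[hit] - features$mz[r]) /
                       features$mz[r] * 1e6,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out))
        out <- data.frame(feature_id = character(), node_id = character(),
                          ppm_error = numeric(), stringsAsFactors = FALSE)
    out
}
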