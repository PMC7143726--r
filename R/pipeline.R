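#' @include synthetic-data.R provenance.R
NULL

#' Default analysis parameters
#'
#' The parameter set used throughout the pipeline, with the standard
#' values of the molecular-networking workflow and the enrichment screen:
#' precursor-window removal 17 Da, clustering precursor tolerance 0.02
#' Da, fragment tolerance 0.5 Da, network edge cosine 0.65 with at least
#' 4 matched peaks, mutual top-K 10, molecular-family cap 500, blank
#' ceiling 1e5, fold threshold 10 and adjusted-p threshold 0.05.
#'
#' @return named list of parameters.
#' @export
defaultParams <- function() {
    list(
        precursor_window_da      = 17,
        cluster_precursor_tol_da = 0.02,
        cluster_min_cosine       = 0.7,
        fragment_tol_da          = 0.5,
        min_cosine               = 0.65,
        min_matched_peaks        = 4,
        top_k                    = 10,
        max_family_size          = 500,
        blank_max                = 1e5,
        fold                     = 10,
        alpha                    = 0.05,
        bin_width_da             = 50,
        min_fraction             = 0.5,
        ladder_fragment_tol_da   = 0.02,
        min_tag_length           = 3,
        intensity_transform      = "sqrt"
    )
}

.validateParams <- function(p) {
    if (p$min_cosine < 0 || p$min_cosine > 1)
        stop("'min_cosine' must lie in [0, 1]")
    if (p$cluster_min_cosine < 0 || p$cluster_min_cosine > 1)
        stop("'cluster_min_cosine' must lie in [0, 1]")
    if (p$precursor_window_da < 0)
        stop("'precursor_window_da' must be >= 0")
    if (p$fragment_tol_da <= 0 || p$cluster_precursor_tol_da <= 0)
        stop("tolerances must be > 0")
    if (p$min_matched_peaks < 0 || p$top_k < 1 || p$max_family_size < 1)
        stop("'min_matched_peaks', 'top_k' and 'max_family_size' must be positive")
    if (p$alpha <= 0 || p$alpha >= 1)
        stop("'alpha' must lie in (0, 1)")
    if (p$fold < 0 || p$blank_max < 0)
        stop("'fold' and 'blank_max' must be >= 0")
    invisible(p)
}

#' Run the full analysis pipeline
#'
#' Orchestrates preprocessing, consensus clustering, network
#' construction, provenance classification, the enrichment screen (when a
#' feature table is supplied) and annotation (library matching on every
#' node when a library is supplied; ladder tags on predatory-only
#' nodes), writing all result tables, a GraphML export and a JSON run
#' summary into \code{outDir}. Inputs are validated before any stage
#' runs; re-running into an existing non-empty directory is refused so
#' runs stay immutable.
#'
#' @param config either the path to a YAML file or a list, with elements
#'   \code{spectra} (MGF path or list of [Spectrum-class]),
#'   \code{metadata} (TSV path or data.frame), optional \code{features}
#'   (TSV path or data.frame), optional \code{library} (MGF path or
#'   spectrum list), and optional \code{params} overriding entries of
#'   [defaultParams()].
#' @param outDir output directory (must not already contain files); NULL
#'   to skip writing.
#' @param quiet suppress per-stage log messages.
#' @return (invisibly) a list with \code{network}, \code{provenance},
#'   \code{venn}, \code{massDistribution}, \code{freqDiff},
#'   \code{prevalence}, \code{enrichment} (or NULL), \code{annotations}
#'   (or NULL), \code{ladderTags}, \code{summary} and \code{params}.
#' @export
runPipeline <- function(config, outDir = NULL, quiet = FALSE) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    p <- utils::modifyList(defaultParams(), config$params %||% list())
    .validateParams(p)
    log <- function(...) if (!quiet) message("[TrapNet] ", ...)
    if (is.null(config$spectra) || is.null(config$metadata))
        stop("config must provide 'spectra' and 'metadata'")
    if (!is.null(outDir)) {
        if (dir.exists(outDir) && length(list.files(outDir)))
            stop("output directory exists and is not empty: ", outDir)
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    }
    t0 <- proc.time()[["elapsed"]]
    stageTimes <- c()
    tick <- function(stage) {
        t1 <- proc.time()[["elapsed"]]
        stageTimes[[stage]] <<- round(t1 - t0, 2)
        log(stage, " done (", stageTimes[[stage]], " s elapsed)")
    }

    spectra <- if (is.character(config$spectra)) readMgf(config$spectra)
               else config$spectra
    metadata <- if (is.character(config$metadata))
        readSampleMetadata(config$metadata)
    else validateSampleMetadata(config$metadata)
    joinSpectraMetadata(spectra, metadata)   # orphan check up front
    features <- if (is.null(config$features)) NULL
        else if (is.character(config$features))
            readFeatureTable(config$features)
        else validateFeatureTable(config$features)
    lib <- if (is.null(config$library)) NULL
        else if (is.character(config$library)) readMgf(config$library)
        else config$library
    tick("load")

    rawSpectra <- spectra   # ladder reading uses the unfiltered scans
    spectra <- lapply(spectra, removePrecursorWindow,
                      window = p$precursor_window_da)
    spectra <- Filter(function(s) peakCount(s) > 0, spectra)
    tick("preprocess")

    nodes <- clusterSpectra(spectra,
                            precursorTol = p$cluster_precursor_tol_da,
                            minCosine = p$cluster_min_cosine,
                            fragmentTol = p$fragment_tol_da,
                            transform = p$intensity_transform)
    tick("consensus")

    network <- buildNetwork(nodes, minCosine = p$min_cosine,
                            minMatchedPeaks = p$min_matched_peaks,
                            topK = p$top_k,
                            maxFamilySize = p$max_family_size,
                            fragmentTol = p$fragment_tol_da,
                            transform = p$intensity_transform)
    tick("networking")

    provenance <- assignProvenance(network, metadata)
    venn <- vennSummary(provenance)
    massDist <- parentMassDistribution(provenance, network,
                                       binWidth = p$bin_width_da)
    freqDiff <- detectionFrequencyDifferential(provenance)
    prevalence <- speciesPrevalenceFilter(provenance,
                                          minFraction = p$min_fraction)
    tick("provenance")

    enrichment <- NULL
    if (!is.null(features)) {
        enrichment <- enrichmentFilter(features, metadata,
                                       blankMax = p$blank_max,
                                       fold = p$fold, alpha = p$alpha)
        tick("enrichment")
    }

    annotations <- NULL
    if (!is.null(lib) && length(lib)) {
        hits <- lapply(networkNodes(network), libraryMatch,
                       librarySpectra = lib, minScore = p$min_cosine,
                       minMatched = p$min_matched_peaks,
                       fragmentTol = p$fragment_tol_da,
                       window = p$precursor_window_da,
                       transform = p$intensity_transform)
        annotations <- do.call(rbind, hits)
        tick("annotation")
    }
    predNodes <- networkNodes(network)[
        nodeIds(network) %in%
            provenance$node_id[provenance$category == "predatory_only"]]
    ladder <- clusterMotif(predNodes, memberSpectra = rawSpectra,
                           fragmentTol = p$ladder_fragment_tol_da,
                           minTagLength = p$min_tag_length,
                           charges = c(1, 2))
    tick("ladder")

    summary <- list(
        n_spectra = length(spectra),
        n_nodes = length(networkNodes(network)),
        n_edges = nrow(networkEdges(network)),
        n_families = length(unique(familyIds(network))),
        category_counts = as.list(table(provenance$category)),
        n_freq_diff_positive = attr(freqDiff, "n_positive"),
        n_prevalence_hits = nrow(prevalence),
        n_enriched_selected = if (is.null(enrichment)) NA_integer_
                              else sum(enrichment$selected),
        motif = ladder$motif$motif,
        params = p,
        stage_seconds = as.list(stageTimes))

    if (!is.null(outDir)) {
        writeNetworkGraphML(network,
                            file.path(outDir, "network.graphml"),
                            provenance = provenance)
        writeNodeTable(network, file.path(outDir, "nodes.tsv"),
                       provenance = provenance)
        utils::write.table(networkEdges(network),
                           file.path(outDir, "edges.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        utils::write.table(provenance,
                           file.path(outDir, "provenance.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        if (!is.null(enrichment))
            utils::write.table(enrichment,
                               file.path(outDir, "enrichment.tsv"),
                               sep = "\t", quote = FALSE,
                               row.names = FALSE)
        if (!is.null(annotations))
            utils::write.table(annotations,
                               file.path(outDir, "annotations.tsv"),
                               sep = "\t", quote = FALSE,
                               row.names = FALSE)
        jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    invisible(list(network = network, provenance = provenance,
                   venn = venn, massDistribution = massDist,
                   freqDiff = freqDiff, prevalence = prevalence,
                   enrichment = enrichment, annotations = annotations,
                   ladderTags = ladder, summary = summary, params = p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
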