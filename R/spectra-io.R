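#' @include AllClasses.R
NULL

.SPECIES_LEVELS <- c("A_oligospora", "A_thaumasia", "A_musiformis", "none")
.STAGE_LEVELS   <- c("saprophytic", "predatory", "not_applicable")
.BLANK_KINDS    <- c("solvent", "medium", "worm", "internal_standard", "none")
.PHASE_LEVELS   <- c("organic", "aqueous")

#' Read tandem mass spectra from an MGF file
#'
#' Parses the Mascot Generic Format dialect used throughout the package:
#' \code{BEGIN IONS}/\code{END IONS} blocks with \code{PEPMASS},
#' \code{CHARGE}, \code{RTINSECONDS}, \code{TITLE} headers, optional
#' \code{NAME} (compound name, used for library entries) and
#' \code{SAMPLEID} keys, and one \code{m/z intensity} pair per line. Peaks
#' are re-sorted to ascending m/z on read. A block without \code{CHARGE}
#' defaults to charge 1 (a message is emitted); a block without
#' \code{PEPMASS} is an error naming the offending block and line.
#'
#' @param path path to the MGF file.
#' @return A list of [Spectrum-class] objects (empty, with a warning, for an
#'   empty file). Library entries carrying a \code{NAME} header use that
#'   name as the \code{spectrumId}.
#' @seealso [writeMgf()]
#' @export
readMgf <- function(path) {
    if (!file.exists(path))
        stop("MGF file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    starts <- which(lines == "BEGIN IONS")
    ends   <- which(lines == "END IONS")
    if (length(starts) != length(ends) ||
        (length(starts) && any(ends < starts)))
        stop("malformed MGF: unbalanced BEGIN IONS/END IONS near line ",
             if (length(ends) < length(starts))
                 starts[length(ends) + 1L] else ends[length(starts) + 1L])
    if (!length(starts)) {
        warning("no spectra found in ", path)
        return(list())
    }
    nMissingCharge <- 0L
    spectra <- vector("list", length(starts))
    for (b in seq_along(starts)) {
        block <- lines[(starts[b] + 1L):(ends[b] - 1L)]
        lineNo <- (starts[b] + 1L):(ends[b] - 1L)
        isKey <- grepl("=", block, fixed = TRUE)
        keys <- block[isKey]
        keyName <- toupper(sub("=.*$", "", keys))
        keyVal  <- sub("^[^=]*=", "", keys)
        getKey <- function(k) if (k %in% keyName) keyVal[match(k, keyName)] else NA_character_
        pep <- getKey("PEPMASS")
        if (is.na(pep))
            stop("MGF block ", b, " (starting line ", starts[b],
                 "): missing PEPMASS")
        pep <- suppressWarnings(as.numeric(strsplit(pep, "[ \t]+")[[1]][1]))
        if (is.na(pep))
            stop("MGF block ", b, ": unparseable PEPMASS")
        ch <- getKey("CHARGE")
        if (is.na(ch)) {
            nMissingCharge <- nMissingCharge + 1L
            ch <- 1L
        } else {
            ch <- suppressWarnings(as.integer(gsub("[^0-9]", "", ch)))
            if (is.na(ch) || ch < 1L) ch <- 1L
        }
        rt <- suppressWarnings(as.numeric(getKey("RTINSECONDS")))
        title <- getKey("TITLE"); nm <- getKey("NAME")
        sid <- getKey("SAMPLEID")
        id <- if (!is.na(nm)) nm else if (!is.na(title)) title else
            paste0("spectrum_", b)
        pkLines <- block[!isKey & nzchar(block)]
        pkNo <- lineNo[!isKey & nzchar(block)]
        if (length(pkLines)) {
            parts <- strsplit(pkLines, "[ \t]+")
            bad <- vapply(parts, function(p)
                length(p) < 2L || anyNA(suppressWarnings(as.numeric(p[1:2]))),
                logical(1))
            if (any(bad))
                stop("MGF block ", b, ": malformed peak line at line ",
                     pkNo[which(bad)[1]])
            mz <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
            it <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
        } else {
            mz <- numeric(); it <- numeric()
        }
        spectra[[b]] <- Spectrum(id, precursorMz = pep, mz = mz,
            intensity = it, charge = ch, retentionTime = rt,
            sampleId = if (is.na(sid)) NA_character_ else sid)
    }
    if (nMissingCharge > 0L)
        message(nMissingCharge, " spectrum block(s) without CHARGE; ",
                "defaulted to 1+")
    spectra
}

#' Write spectra to an MGF file
#'
#' Inverse of [readMgf()]: round-tripping preserves the precursor m/z to
#' 1e-4 Th, the peak count exactly and intensities to a relative 1e-6.
#'
#' @param spectra list of [Spectrum-class] objects.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeMgf <- function(spectra, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (sp in spectra) {
        pk <- peaks(sp)
        lines <- c(
            "BEGIN IONS",
            paste0("TITLE=", spectrumId(sp)),
            paste0("PEPMASS=", sprintf("%.6f", precursorMz(sp))),
            paste0("CHARGE=", charge(sp), "+"),
            if (!is.na(retentionTime(sp)))
                paste0("RTINSECONDS=", sprintf("%.3f", retentionTime(sp))),
            if (!is.na(sampleId(sp)))
                paste0("SAMPLEID=", sampleId(sp)),
            if (nrow(pk))
                sprintf("%.6f %.8g", pk[, "mz"], pk[, "intensity"]),
            "END IONS", "")
        writeLines(lines, con)
    }
    invisible(path)
}

#' Validate a sample-metadata table
#'
#' Checks column presence, allowed category tokens, uniqueness of sample
#' ids, and the structural invariants tying blanks to stages and species:
#' a blank sample must have stage \code{not_applicable}, and species
#' \code{none} is used exactly for blank/control samples.
#'
#' @param meta data.frame with columns \code{sample_id}, \code{species},
#'   \code{strain_id}, \code{stage}, \code{is_blank}, \code{blank_kind},
#'   \code{extract_phase}.
#' @return The validated data.frame (with \code{is_blank} coerced to
#'   logical), invisibly usable downstream.
#' @export
validateSampleMetadata <- function(meta) {
    need <- c("sample_id", "species", "strain_id", "stage", "is_blank",
              "blank_kind", "extract_phase")
    missing <- setdiff(need, names(meta))
    if (length(missing))
        stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
    meta$is_blank <- as.logical(meta$is_blank)
    if (anyNA(meta$is_blank))
        stop("'is_blank' must be logical (TRUE/FALSE)")
    if (anyDuplicated(meta$sample_id))
        stop("duplicated sample_id: ",
             paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
                   collapse = ", "))
    checkTokens <- function(col, allowed) {
        bad <- setdiff(unique(meta[[col]]), allowed)
        if (length(bad))
            stop("unknown ", col, " value(s): ", paste(bad, collapse = ", "),
                 "; allowed: ", paste(allowed, collapse = ", "))
    }
    checkTokens("species", .SPECIES_LEVELS)
    checkTokens("stage", .STAGE_LEVELS)
    checkTokens("blank_kind", .BLANK_KINDS)
    checkTokens("extract_phase", .PHASE_LEVELS)
    bad <- meta$is_blank & meta$stage != "not_applicable"
    if (any(bad))
        stop("blank samples must have stage 'not_applicable': ",
             paste(meta$sample_id[bad], collapse = ", "))
    bad <- (meta$species == "none") != meta$is_blank
    if (any(bad))
        stop("species 'none' must be used exactly for blank/control samples: ",
             paste(meta$sample_id[bad], collapse = ", "))
    meta
}

#' Read the sample-metadata table
#'
#' Tab-delimited table with one row per LC-MS sample: sample id, fungal
#' species, strain id, life stage (\code{saprophytic}/\code{predatory}/
#' \code{not_applicable}), blank flag and kind, and extract phase
#' (\code{organic}/\code{aqueous}). See [validateSampleMetadata()] for the
#' invariants enforced.
#'
#' @param path path to the TSV file.
#' @return A validated data.frame.
#' @export
readSampleMetadata <- function(path) {
    if (!file.exists(path))
        stop("metadata file not found: ", path)
    meta <- utils::read.delim(path, stringsAsFactors = FALSE)
    validateSampleMetadata(meta)
}

#' Join spectra to sample metadata
#'
#' Every spectrum must reference an existing sample; orphan spectra are an
#' error naming the unknown sample ids, never silently dropped.
#'
#' @param spectra list of [Spectrum-class].
#' @param metadata validated metadata data.frame.
#' @return data.frame with one row per spectrum: \code{spectrum_id} plus
#'   the metadata columns of the matching sample.
#' @export
joinSpectraMetadata <- function(spectra, metadata) {
    sids <- vapply(spectra, sampleId, character(1))
    unknown <- setdiff(stats::na.omit(unique(sids)), metadata$sample_id)
    if (length(unknown))
        stop("spectra reference unknown sample id(s): ",
             paste(unknown, collapse = ", "))
    idx <- match(sids, metadata$sample_id)
    cbind(data.frame(spectrum_id = vapply(spectra, spectrumId, character(1)),
                     stringsAsFactors = FALSE),
          metadata[idx, , drop = FALSE], row.names = NULL)
}

.networkNodeTable <- function(network, provenance = NULL, detection = NULL) {
    nodes <- networkNodes(network)
    tab <- data.frame(
        node_id       = vapply(nodes, nodeId, character(1)),
        precursor_mz  = vapply(nodes, precursorMz, numeric(1)),
        charge        = vapply(nodes, charge, integer(1)),
        member_count  = vapply(nodes, memberCount, integer(1)),
        n_samples     = vapply(nodes, function(n) length(n@sampleIds),
                               integer(1)),
        family_id     = unname(familyIds(network)[
                            vapply(nodes, nodeId, character(1))]),
        stringsAsFactors = FALSE)
    if (!is.null(provenance)) {
        i <- match(tab$node_id, provenance$node_id)
        tab$category <- provenance$category[i]
        tab$freq_diff <- provenance$freq_diff[i]
        tab$n_predatory <- provenance$n_predatory[i]
        tab$n_saprophytic <- provenance$n_saprophytic[i]
    }
    tab
}

#' Export a molecular network
#'
#' \code{writeNetworkGraphML} writes GraphML loadable by standard graph
#' viewers (e.g. Cytoscape), with node attributes (precursor m/z, charge,
#' member/sample counts, molecular-family id, and — when a provenance table
#' is supplied — the stage category and per-stage detection counts) and
#' edge attributes (cosine score, matched peak count).
#' \code{writeNodeTable} writes the same node attributes as a TSV.
#'
#' @param network a [MolecularNetwork-class].
#' @param path output file path.
#' @param provenance optional result of [assignProvenance()] to merge in.
#' @return Invisibly, the path.
#' @export
writeNetworkGraphML <- function(network, path, provenance = NULL) {
    tab <- .networkNodeTable(network, provenance)
    ed <- networkEdges(network)
    g <- igraph::graph_from_data_frame(
        d = if (nrow(ed)) ed[, c("nodeA", "nodeB", "cosine", "matchedPeaks")]
            else data.frame(nodeA = character(), nodeB = character(),
                            cosine = numeric(), matchedPeaks = integer()),
        directed = FALSE, vertices = tab)
    tryCatch(
        igraph::write_graph(g, path, format = "graphml"),
        error = function(e) stop("cannot write GraphML to '", path, "': ",
                                 conditionMessage(e)))
    invisible(path)
}

#' @rdname writeNetworkGraphML
#' @export
writeNodeTable <- function(network, path, provenance = NULL) {
    tab <- .networkNodeTable(network, provenance)
    tryCatch(
        utils::write.table(tab, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, fileEncoding = "UTF-8"),
        error = function(e) stop("cannot write node table to '", path, "': ",
                                 conditionMessage(e)))
    invisible(path)
}
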