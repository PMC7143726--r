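#' @include annotation-match.R enrichment.R
NULL

#' Theoretical peptide fragment spectrum
#'
#' Builds the b/y fragment-ion series of a residue sequence:
#' \eqn{b_k} = sum of the first k residue masses + proton,
#' \eqn{y_k} = sum of the last k residue masses + water + proton, each
#' for k = 1..n (so the full-length y ion equals the linear peptide
#' \eqn{[M+H]^+}). When \code{charge = 2}, doubly-charged variants
#' \eqn{(m + 2m_p)/2} of every fragment are added. The precursor is the
#' protonated linear peptide at the requested charge.
#'
#' @param sequence character vector of residue symbols (see
#'   [residueMasses()]).
#' @param charge precursor charge state (1 or 2).
#' @param ionTypes subset of \code{c("b", "y")}.
#' @param spectrumId,sampleId identifiers for the returned object.
#' @return A [Spectrum-class] with unit intensities (100 per fragment).
#' @examples
#' sp <- theoreticalPeptideSpectrum(c("Ala", "Arg", "Ala"))
#' peaks(sp)
#' @export
theoreticalPeptideSpectrum <- function(sequence, charge = 1,
                                       ionTypes = c("b", "y"),
                                       spectrumId = paste(sequence,
                                                          collapse = ""),
                                       sampleId = NA_character_) {
    rm <- residueMasses()
    bad <- setdiff(sequence, names(rm))
    if (length(bad))
        stop("unknown residue symbol(s): ", paste(bad, collapse = ", "))
    res <- rm[sequence]
    n <- length(res)
    water <- monoisotopicMass("H2O")
    frag <- numeric(0)
    if ("b" %in% ionTypes)
        frag <- c(frag, cumsum(res) + PROTON_MASS)
    if ("y" %in% ionTypes)
        frag <- c(frag, cumsum(rev(res)) + water + PROTON_MASS)
    if (charge >= 2)
        frag <- c(frag, (frag - PROTON_MASS + 2 * PROTON_MASS) / 2)
    frag <- sort(unique(frag))
    Spectrum(spectrumId,
             precursorMz = mzFromNeutral(linearPeptideMass(sequence), charge),
             mz = frag, intensity = rep(100, length(frag)),
             charge = charge, sampleId = sampleId)
}

#' Planted compound-family specifications
#'
#' The default plant mirrors the study's qualitative findings: a broad
#' background of housekeeping metabolites in both stages, a set of
#' predatory-stage-only compounds, a few saprophytic-only compounds, a
#' ferrichrome-type siderophore set (reference compound plus -O, +C2H2O
#' and -C2H2O analogues, restricted to two of the three species and
#' quantitatively enriched in the predatory stage), a trap-associated
#' peptide series confined to one species' predatory stage and sharing
#' the 6-residue core Ala-Arg-Ala-Leu/Ile-Ser-Leu/Ile, and blank-control
#' compounds (medium, worm, and the glycocholic acid internal standard
#' spiked into every sample).
#'
#' @return list of family specification lists (fields: \code{name},
#'   \code{kind}, \code{species}, \code{stage_pattern},
#'   \code{fold_effect}, \code{prevalence}, \code{compounds}).
#' @export
defaultFamilySpecs <- function() {
    core <- c("Ala", "Arg", "Ala", "Leu/Ile", "Ser", "Leu/Ile")
    pep <- function(i, flank) list(name = sprintf("AmTP_like_%d", i),
                                   type = "peptide",
                                   sequence = c(flank, core), charge = 2L)
    list(
        list(name = "background", kind = "background", species = "all",
             stage_pattern = "both_flat", fold_effect = 1, prevalence = 0.9,
             compounds = lapply(seq_len(18), function(i)
                 list(name = sprintf("bg_%02d", i), type = "random",
                      charge = 1L))),
        list(name = "lipids", kind = "lipid_cluster", species = "all",
             stage_pattern = "both_enriched", fold_effect = 20,
             prevalence = 0.9,
             compounds = list(
                 list(name = "nonadecanamide", type = "formula",
                      formula = "C19H39NO", charge = 1L),
                 list(name = "lipid_2", type = "mass", mass = 269.2713,
                      charge = 1L),
                 list(name = "lipid_3", type = "mass", mass = 311.3183,
                      charge = 1L))),
        list(name = "predatory_family", kind = "background",
             species = "all", stage_pattern = "predatory_only",
             fold_effect = 1, prevalence = 0.8,
             compounds = lapply(seq_len(6), function(i)
                 list(name = sprintf("pred_%02d", i), type = "random",
                      charge = 1L))),
        list(name = "saprophytic_family", kind = "background",
             species = "all", stage_pattern = "saprophytic_only",
             fold_effect = 1, prevalence = 0.8,
             compounds = lapply(seq_len(4), function(i)
                 list(name = sprintf("sap_%02d", i), type = "random",
                      charge = 1L))),
        list(name = "siderophores", kind = "siderophore_set",
             species = c("A_oligospora", "A_musiformis"),
             stage_pattern = "both_enriched", fold_effect = 20,
             prevalence = 0.9,
             compounds = list(
                 list(name = "desferriferrichrome", type = "formula",
                      formula = "C27H45N9O12", charge = 1L),
                 list(name = "desferriferrichrome_minus_O", type = "formula",
                      formula = "C27H45N9O11", charge = 1L),
                 list(name = "desferriferrichrome_plus_C2H2O",
                      type = "formula", formula = "C29H47N9O13",
                      charge = 2L),
                 list(name = "desferriferrichrome_minus_C2H2O",
                      type = "formula", formula = "C25H43N9O11",
                      charge = 1L))),
        list(name = "peptides", kind = "peptide_series",
             species = "A_musiformis", stage_pattern = "predatory_only",
             fold_effect = 1, prevalence = 14 / 18,
             compounds = list(pep(1, "Gly"), pep(2, "Ser"), pep(3, "hOrn"),
                              pep(4, c("Gly", "Gly")),
                              pep(5, c("Gly", "Ser")))),
        list(name = "blank_compounds", kind = "background",
             species = "blank", stage_pattern = "both_flat",
             fold_effect = 1, prevalence = 1,
             compounds = list(
                 list(name = "medium_1", type = "random", charge = 1L,
                      blank_kind = "medium"),
                 list(name = "medium_2", type = "random", charge = 1L,
                      blank_kind = "medium"),
                 list(name = "worm_1", type = "random", charge = 1L,
                      blank_kind = "worm"),
                 list(name = "glycocholic_acid", type = "formula",
                      formula = "C26H43NO6", charge = 1L,
                      blank_kind = "internal_standard")))
    )
}

#' Synthetic study configuration
#'
#' Desk-scale defaults: 28 strains (10 A. oligospora, 9 A. thaumasia, 9
#' A. musiformis — the minority species kept at half their real census so
#' strain-fraction rules keep their granularity) sampled in both life
#' stages plus four blank controls, with ~40 planted compounds;
#' \code{scale = "full"} restores the study's 64/18/18 strain census.
#' Noise defaults: fragment m/z jitter sd 0.003 Da, lognormal intensity
#' coefficient of variation 0.25, per-peak dropout probability 0.05.
#'
#' @param seed integer seed; identical configurations reproduce
#'   byte-identical outputs.
#' @param scale \code{"desk"} (default) or \code{"full"}.
#' @param nStrains named integer vector overriding the per-species strain
#'   counts.
#' @param mzJitterSd,intensityCv,peakDropout noise levels.
#' @param sapDetect probability that a low-abundance saprophytic-stage
#'   occurrence of a stage-enriched compound triggers an MS/MS scan
#'   (data-dependent acquisition preferentially fragments abundant ions,
#'   so enriched compounds are seen less often before trap formation);
#'   default 0.6.
#' @param families list of family specs (default [defaultFamilySpecs()]).
#' @return A configuration list for [generateDataset()].
#' @export
syntheticConfig <- function(seed = 1, scale = c("desk", "full"),
                            nStrains = NULL, mzJitterSd = 0.003,
                            intensityCv = 0.25, peakDropout = 0.05,
                            sapDetect = 0.6,
                            families = defaultFamilySpecs()) {
    scale <- match.arg(scale)
    if (is.null(nStrains))
        nStrains <- if (scale == "desk")
            c(A_oligospora = 10L, A_thaumasia = 9L, A_musiformis = 9L)
        else
            c(A_oligospora = 64L, A_thaumasia = 18L, A_musiformis = 18L)
    prev <- unlist(lapply(families, `[[`, "prevalence"))
    if (any(prev <= 0))
        stop("infeasible family spec: prevalence must be > 0")
    list(seed = as.integer(seed), scale = scale, nStrains = nStrains,
         mzJitterSd = mzJitterSd, intensityCv = intensityCv,
         peakDropout = peakDropout, sapDetect = sapDetect,
         families = families)
}

# deterministic per-compound fragment scaffold; families get cohesion by
# sharing a base scaffold whose fragments are partly shifted by the
# compound's neutral-mass offset from the family base
.compoundTable <- function(families) {
    rows <- list()
    for (fam in families) {
        for (cp in fam$compounds) {
            mass <- switch(cp$type,
                formula = monoisotopicMass(cp$formula),
                mass = cp$mass,
                peptide = linearPeptideMass(cp$sequence),
                random = NA_real_)   # drawn later from the seeded stream
            rows[[length(rows) + 1L]] <- list(
                name = cp$name, family = fam$name, kind = fam$kind,
                type = cp$type, species = fam$species,
                stage_pattern = fam$stage_pattern,
                fold_effect = fam$fold_effect, prevalence = fam$prevalence,
                charge = cp$charge, neutral_mass = mass,
                sequence = if (cp$type == "peptide") cp$sequence else NULL,
                blank_kind = if (!is.null(cp$blank_kind)) cp$blank_kind
                             else "none")
        }
    }
    rows
}

.syntheticMetadata <- function(nStrains) {
    prefix <- c(A_oligospora = "AO", A_thaumasia = "AT",
                A_musiformis = "AM")
    rows <- list()
    for (sp in names(nStrains)) {
        for (k in seq_len(nStrains[[sp]])) {
            strain <- sprintf("%s%02d", prefix[[sp]], k)
            for (st in c("saprophytic", "predatory"))
                rows[[length(rows) + 1L]] <- data.frame(
                    sample_id = paste0(strain, "_",
                                       substr(st, 1, 4)),
                    species = sp, strain_id = strain, stage = st,
                    is_blank = FALSE, blank_kind = "none",
                    extract_phase = "organic", stringsAsFactors = FALSE)
        }
    }
    blanks <- data.frame(
        sample_id = c("blank_solvent", "blank_medium", "blank_worm",
                      "blank_is"),
        species = "none", strain_id = "none", stage = "not_applicable",
        is_blank = TRUE,
        blank_kind = c("solvent", "medium", "worm", "internal_standard"),
        extract_phase = "organic", stringsAsFactors = FALSE)
    validateSampleMetadata(rbind(do.call(rbind, rows), blanks))
}

#' Generate a complete synthetic study dataset
#'
#' Emulates the multi-species, multi-strain, two-life-stage LC-MS/MS
#' design with planted ground truth: for every planted compound a
#' theoretical fragment set is built (peptides from b/y ions, others from
#' seeded fragment scaffolds with family cohesion), replicated across the
#' samples dictated by its species restriction, stage pattern and
#' strain-level prevalence, with Gaussian m/z jitter, per-peak dropout
#' and lognormal intensity noise. Blank controls carry medium and worm
#' background compounds; the glycocholic acid internal standard is spiked
#' into every sample. A quantified feature table with the configured
#' stage fold effects and a toy spectral library (including a deliberate
#' structural-isomer pair sharing every fragment) are produced alongside,
#' plus a manifest recording every planted truth.
#'
#' @param config from [syntheticConfig()].
#' @param outDir optional directory; when given, writes
#'   \code{spectra.mgf}, \code{metadata.tsv}, \code{features.tsv},
#'   \code{library.mgf} and \code{manifest.json} there.
#' @return list with \code{spectra} (list of [Spectrum-class]),
#'   \code{metadata} (data.frame), \code{features} (data.frame),
#'   \code{library} (list of [Spectrum-class]), \code{manifest} (list:
#'   \code{compounds} data.frame incl. expected provenance category and
#'   detected strains, \code{motif}, \code{seed}).
#' @export
generateDataset <- function(config = syntheticConfig(), outDir = NULL) {
    set.seed(config$seed)
    metadata <- .syntheticMetadata(config$nStrains)
    fungal <- metadata[!metadata$is_blank, , drop = FALSE]
    compounds <- .compoundTable(config$families)

    # pass 1: masses and scaffolds, in fixed compound order
    famBase <- list()
    for (ci in seq_along(compounds)) {
        cp <- compounds[[ci]]
        if (cp$type == "random")
            cp$neutral_mass <- round(stats::runif(1, 180, 900), 4)
        cp$precursor_mz <- mzFromNeutral(cp$neutral_mass, cp$charge)
        if (cp$type == "peptide") {
            sp <- theoreticalPeptideSpectrum(cp$sequence, cp$charge)
            cp$scaffold <- peaks(sp)
        } else if (cp$kind %in% c("siderophore_set", "lipid_cluster")) {
            if (is.null(famBase[[cp$family]])) {
                nf <- sample(10:16, 1)
                famBase[[cp$family]] <- list(
                    mass = cp$neutral_mass,
                    mz = sort(stats::runif(nf, 60,
                                           max(120, cp$neutral_mass - 40))),
                    int = stats::rlnorm(nf, log(1000), 0.7))
            }
            base <- famBase[[cp$family]]
            off <- cp$neutral_mass - base$mass
            shift <- stats::runif(length(base$mz)) < 0.25 & off != 0
            mzv <- base$mz + ifelse(shift, off, 0)
            ok <- mzv > 50 & mzv < cp$precursor_mz * cp$charge
            cp$scaffold <- cbind(mz = mzv[ok], intensity = base$int[ok])
        } else {
            nf <- sample(8:30, 1)
            hi <- max(120, cp$neutral_mass - 40)
            mzv <- sort(stats::runif(nf, 60, hi))
            cp$scaffold <- cbind(mz = mzv,
                                 intensity = stats::rlnorm(nf, log(1000),
                                                           0.7))
        }
        cp$base_area <- stats::rlnorm(1, log(5e5), 0.4)
        compounds[[ci]] <- cp
    }

    # pass 2: strain-level detection draws
    for (ci in seq_along(compounds)) {
        cp <- compounds[[ci]]
        if (identical(cp$species, "blank")) {
            cp$strains <- character(0)
        } else {
            pool <- if (identical(cp$species, "all"))
                unique(fungal$strain_id)
            else unique(fungal$strain_id[fungal$species %in% cp$species])
            cp$strains <- pool[stats::runif(length(pool)) < cp$prevalence]
        }
        compounds[[ci]] <- cp
    }

    stagesOf <- function(pattern) switch(pattern,
        predatory_only = "predatory",
        saprophytic_only = "saprophytic",
        c("saprophytic", "predatory"))

    # pass 3: spectra with noise
    spectra <- list()
    emit <- function(cp, sampleIdStr, idx) {
        pk <- cp$scaffold
        keep <- stats::runif(nrow(pk)) >= config$peakDropout
        if (!sum(keep)) keep[sample(nrow(pk), 1)] <- TRUE
        mzv <- pk[keep, "mz"] + stats::rnorm(sum(keep), 0, config$mzJitterSd)
        itv <- pk[keep, "intensity"] *
            stats::rlnorm(sum(keep), 0, config$intensityCv)
        Spectrum(sprintf("%s.%s.%04d", cp$name, sampleIdStr, idx),
                 precursorMz = cp$precursor_mz +
                     stats::rnorm(1, 0, config$mzJitterSd),
                 mz = pmax(mzv, 1e-3), intensity = itv,
                 charge = cp$charge, retentionTime = stats::runif(1, 30, 800),
                 sampleId = sampleIdStr)
    }
    k <- 0L
    for (cp in compounds) {
        if (identical(cp$species, "blank")) {
            targets <- if (cp$blank_kind == "internal_standard")
                metadata$sample_id
            else metadata$sample_id[metadata$blank_kind == cp$blank_kind]
        } else {
            st <- stagesOf(cp$stage_pattern)
            targets <- fungal$sample_id[fungal$strain_id %in% cp$strains &
                                        fungal$stage %in% st]
            if (cp$stage_pattern == "both_enriched") {
                # DDA under-samples the low-abundance pre-trap occurrences
                isSap <- targets %in%
                    fungal$sample_id[fungal$stage == "saprophytic"]
                keep <- !isSap | stats::runif(length(targets)) < config$sapDetect
                targets <- targets[keep]
            }
        }
        for (sid in targets) {
            k <- k + 1L
            spectra[[k]] <- emit(cp, sid, k)
        }
    }

    # pass 4: quantified feature table
    nSamp <- nrow(metadata)
    areas <- matrix(0, nrow = length(compounds), ncol = nSamp,
                    dimnames = list(NULL, metadata$sample_id))
    for (ci in seq_along(compounds)) {
        cp <- compounds[[ci]]
        if (identical(cp$species, "blank")) {
            targets <- if (cp$blank_kind == "internal_standard")
                metadata$sample_id
            else metadata$sample_id[metadata$blank_kind == cp$blank_kind]
            areas[ci, targets] <- cp$base_area *
                stats::rlnorm(length(targets), 0, config$intensityCv)
        } else {
            st <- stagesOf(cp$stage_pattern)
            sel <- fungal$strain_id %in% cp$strains & fungal$stage %in% st
            sids <- fungal$sample_id[sel]
            a <- cp$base_area * stats::rlnorm(length(sids), 0,
                                              config$intensityCv)
            if (cp$stage_pattern == "both_enriched")
                a <- a * ifelse(fungal$stage[sel] == "predatory",
                                cp$fold_effect, 1)
            areas[ci, sids] <- a
        }
    }
    features <- data.frame(
        feature_id = sprintf("F%04d", seq_along(compounds)),
        mz = vapply(compounds, `[[`, numeric(1), "precursor_mz"),
        rt = round(stats::runif(length(compounds), 30, 800), 1),
        stringsAsFactors = FALSE)
    features <- cbind(features, as.data.frame(areas))

    lib <- .toyLibrary(compounds)

    expectedCategory <- vapply(compounds, function(cp) {
        if (identical(cp$species, "blank") ||
            cp$blank_kind == "internal_standard") "blank"
        else switch(cp$stage_pattern,
                    predatory_only = "predatory_only",
                    saprophytic_only = "saprophytic_only",
                    "both_stages")
    }, character(1))
    manifest <- list(
        seed = config$seed,
        motif = "Ala-Arg-Ala-Leu/Ile-Ser-Leu/Ile",
        compounds = data.frame(
            name = vapply(compounds, `[[`, character(1), "name"),
            family = vapply(compounds, `[[`, character(1), "family"),
            kind = vapply(compounds, `[[`, character(1), "kind"),
            stage_pattern = vapply(compounds, `[[`, character(1),
                                   "stage_pattern"),
            species = vapply(compounds, function(cp)
                paste(cp$species, collapse = ","), character(1)),
            charge = vapply(compounds, `[[`, integer(1), "charge"),
            neutral_mass = vapply(compounds, `[[`, numeric(1),
                                  "neutral_mass"),
            precursor_mz = vapply(compounds, `[[`, numeric(1),
                                  "precursor_mz"),
            prevalence = vapply(compounds, `[[`, numeric(1), "prevalence"),
            fold_effect = vapply(compounds, `[[`, numeric(1),
                                 "fold_effect"),
            n_detected_strains = vapply(compounds, function(cp)
                length(cp$strains), integer(1)),
            detected_strains = vapply(compounds, function(cp)
                paste(cp$strains, collapse = ","), character(1)),
            expected_category = expectedCategory,
            feature_id = sprintf("F%04d", seq_along(compounds)),
            stringsAsFactors = FALSE))

    out <- list(spectra = spectra, metadata = metadata,
                features = features, library = lib,
                manifest = manifest)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeMgf(spectra, file.path(outDir, "spectra.mgf"))
        utils::write.table(metadata, file.path(outDir, "metadata.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(features, file.path(outDir, "features.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        writeMgf(lib, file.path(outDir, "library.mgf"))
        jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA,
                             dataframe = "rows")
    }
    out
}

#' Simulate a feature-level enrichment study
#'
#' Quantification-table simulation for characterising the four-step
#' enrichment screen: \code{nEnriched} truly enriched features (lognormal
#' areas with a \code{foldEffect}-times stage effect in the predatory
#' group) among \code{nFeatures - nEnriched} null features with no stage
#' effect, across paired predatory/saprophytic samples and a set of
#' low-signal blanks. With \code{foldEffect = 1} and \code{nEnriched = 0}
#' it produces a global-null dataset for calibrating the step-iv error
#' rate.
#'
#' @param nFeatures total number of features (default 500).
#' @param nEnriched number of planted enriched features (default 20).
#' @param foldEffect multiplicative predatory-stage effect for planted
#'   features (default 50).
#' @param nPerStage samples per stage (default 30).
#' @param nBlank number of blank samples (default 6).
#' @param seed RNG seed.
#' @param baseMeanLog,baseSdLog,sampleSdLog lognormal area parameters:
#'   per-feature base level and per-sample variation (log scale).
#' @param blankMeanLog blank-sample area level (log scale).
#' @return list with \code{features} (feature table), \code{metadata}
#'   (sample table) and \code{enriched} (feature ids of the planted
#'   features).
#' @export
simulateEnrichmentStudy <- function(nFeatures = 500, nEnriched = 20,
                                    foldEffect = 50, nPerStage = 30,
                                    nBlank = 6, seed = 1,
                                    baseMeanLog = log(5e5),
                                    baseSdLog = 0.5, sampleSdLog = 0.5,
                                    blankMeanLog = log(1e4)) {
    set.seed(seed)
    strains <- sprintf("ST%02d", seq_len(nPerStage))
    metadata <- rbind(
        data.frame(sample_id = paste0(strains, "_pred"),
                   species = "A_oligospora", strain_id = strains,
                   stage = "predatory", is_blank = FALSE,
                   blank_kind = "none", extract_phase = "organic",
                   stringsAsFactors = FALSE),
        data.frame(sample_id = paste0(strains, "_sap"),
                   species = "A_oligospora", strain_id = strains,
                   stage = "saprophytic", is_blank = FALSE,
                   blank_kind = "none", extract_phase = "organic",
                   stringsAsFactors = FALSE),
        data.frame(sample_id = sprintf("blank_%02d", seq_len(nBlank)),
                   species = "none", strain_id = "none",
                   stage = "not_applicable", is_blank = TRUE,
                   blank_kind = "solvent", extract_phase = "organic",
                   stringsAsFactors = FALSE))
    base <- stats::rlnorm(nFeatures, baseMeanLog, baseSdLog)
    enriched <- if (nEnriched > 0) seq_len(nEnriched) else integer(0)
    nSamp <- nrow(metadata)
    areas <- matrix(stats::rlnorm(nFeatures * nSamp, 0, sampleSdLog),
                    nrow = nFeatures) * base
    isPred <- metadata$stage == "predatory"
    areas[enriched, isPred] <- areas[enriched, isPred] * foldEffect
    areas[, metadata$is_blank] <-
        stats::rlnorm(nFeatures * nBlank, blankMeanLog, sampleSdLog)
    colnames(areas) <- metadata$sample_id
    features <- data.frame(
        feature_id = sprintf("F%04d", seq_len(nFeatures)),
        mz = round(stats::runif(nFeatures, 100, 1200), 4),
        rt = round(stats::runif(nFeatures, 30, 800), 1),
        stringsAsFactors = FALSE)
    features <- cbind(features, as.data.frame(areas))
    list(features = features, metadata = metadata,
         enriched = sprintf("F%04d", enriched))
}

# toy reference library: idealised (noise-free) spectra with compound
# names, including citicoline at its computed protonated mass and a
# tridemorph entry sharing every fragment with nonadecanamide (the
# structural-isomer ambiguity: identical precursor, identical MS/MS)
.toyLibrary <- function(compounds) {
    named <- c("desferriferrichrome", "nonadecanamide", "glycocholic_acid")
    lib <- list()
    for (cp in compounds) {
        if (!cp$name %in% named) next
        lib[[length(lib) + 1L]] <- Spectrum(
            cp$name, precursorMz = cp$precursor_mz,
            mz = cp$scaffold[, "mz"], intensity = cp$scaffold[, "intensity"],
            charge = cp$charge)
    }
    nona <- Filter(function(s) spectrumId(s) == "nonadecanamide", lib)
    if (length(nona)) {
        td <- nona[[1L]]
        td@spectrumId <- "tridemorph"
        lib[[length(lib) + 1L]] <- td
    }
    citMass <- monoisotopicMass("C14H26N4O11P2")
    set_mz <- sort(citMass * c(0.12, 0.2, 0.33, 0.45, 0.61, 0.72, 0.85))
    lib[[length(lib) + 1L]] <- Spectrum(
        "citicoline", precursorMz = mzFromNeutral(citMass, 1),
        mz = set_mz, intensity = rep(800, length(set_mz)), charge = 1L)
    linMass <- monoisotopicMass("C18H34O")
    lin_mz <- sort(linMass * c(0.15, 0.27, 0.4, 0.52, 0.66, 0.81))
    lib[[length(lib) + 1L]] <- Spectrum(
        "linoleyl_alcohol", precursorMz = mzFromNeutral(linMass, 1),
        mz = lin_mz, intensity = rep(800, length(lin_mz)), charge = 1L)
    lib
}
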