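test_that("theoretical peptide spectra follow the b/y conventions", {
    b1 <- theoreticalPeptideSpectrum("Gly")
    # b1 of Gly: residue + proton
    expect_true(any(abs(peaks(b1)[, "mz"] - 58.0288) < 1e-3))
    # full-length y ion equals the linear peptide [M+H]+
    seqs <- c("Ala", "Arg", "Ser")
    sp <- theoreticalPeptideSpectrum(seqs)
    expect_true(any(abs(peaks(sp)[, "mz"] -
                        mzFromNeutral(linearPeptideMass(seqs), 1)) < 1e-6))
    expect_error(theoreticalPeptideSpectrum(c("Gly", "Foo")),
                 "unknown residue")
    # round trip: the generated series is read back as the full tag
    core <- strsplit(coreMotif(), "-", fixed = TRUE)[[1]]
    tags <- peptideLadder(theoreticalPeptideSpectrum(core))
    expect_true(coreMotif() %in% tags$tag)
})

test_that("the generator is byte-deterministic for a fixed config", {
    cfg <- syntheticConfig(seed = 7)
    d1 <- generateDataset(cfg)
    d2 <- generateDataset(cfg)
    expect_identical(d1$features, d2$features)
    expect_identical(d1$metadata, d2$metadata)
    expect_identical(d1$manifest, d2$manifest)
    expect_identical(lapply(d1$spectra, peaks),
                     lapply(d2$spectra, peaks))

    outA <- withr::local_tempdir(); outB <- withr::local_tempdir()
    generateDataset(cfg, outDir = outA)
    generateDataset(cfg, outDir = outB)
    for (f in list.files(outA))
        expect_identical(unname(tools::md5sum(file.path(outA, f))),
                         unname(tools::md5sum(file.path(outB, f))),
                         label = f)
    # a different seed changes the data
    d3 <- generateDataset(syntheticConfig(seed = 8))
    expect_false(identical(lapply(d1$spectra, peaks),
                           lapply(d3$spectra, peaks)))
})

test_that("species restrictions and blank composition are honoured", {
    d <- generateDataset(syntheticConfig(seed = 5))
    man <- d$manifest$compounds
    meta <- d$metadata
    bySample <- split(vapply(d$spectra, function(s)
        sub("\\..*$", "", spectrumId(s)), character(1)),
        vapply(d$spectra, sampleId, character(1)))
    pep <- man[man$kind == "peptide_series", ]
    amStrains <- meta$strain_id[meta$species == "A_musiformis"]
    for (i in seq_len(nrow(pep))) {
        hostSamples <- names(bySample)[vapply(bySample, function(x)
            pep$name[i] %in% x, logical(1))]
        hostMeta <- meta[match(hostSamples, meta$sample_id), ]
        expect_true(all(hostMeta$species == "A_musiformis"))
        expect_true(all(hostMeta$stage == "predatory"))
    }
    # manifest lists zero detections outside the restricted species
    expect_true(all(vapply(strsplit(pep$detected_strains, ","),
                           function(x) all(x %in% amStrains), logical(1))))
    # blank compounds only in their blank samples (IS is spiked everywhere)
    med <- names(bySample)[vapply(bySample, function(x)
        "medium_1" %in% x, logical(1))]
    expect_true(all(meta$blank_kind[match(med, meta$sample_id)] == "medium"))
    isHosts <- names(bySample)[vapply(bySample, function(x)
        "glycocholic_acid" %in% x, logical(1))]
    expect_gt(length(isHosts), nrow(meta) - 2)   # spiked essentially everywhere
})

test_that("with noise off, detections equal prevalence draws exactly", {
    cfg <- syntheticConfig(seed = 2, mzJitterSd = 0, intensityCv = 0,
                           peakDropout = 0, sapDetect = 1)
    d <- generateDataset(cfg)
    man <- d$manifest$compounds
    counts <- table(vapply(d$spectra, function(s)
        sub("\\..*$", "", spectrumId(s)), character(1)))
    fungal <- man[man$species != "blank" &
                  man$expected_category != "blank", ]
    for (i in seq_len(nrow(fungal))) {
        nStage <- if (fungal$stage_pattern[i] %in%
                      c("predatory_only", "saprophytic_only")) 1L else 2L
        expect_equal(unname(counts[fungal$name[i]]),
                     fungal$n_detected_strains[i] * nStage,
                     label = fungal$name[i])
    }
    # zero jitter: every emitted fragment sits exactly on its scaffold m/z
    pepSpec <- Filter(function(s)
        grepl("^AmTP_like_1\\.", spectrumId(s)), d$spectra)
    ref <- theoreticalPeptideSpectrum(
        c("Gly", strsplit(coreMotif(), "-", fixed = TRUE)[[1]]),
        charge = 2)
    expect_true(all(peaks(pepSpec[[1]])[, "mz"] %in% peaks(ref)[, "mz"]))
})

test_that("the enrichment-study simulator plants what it reports", {
    sim <- simulateEnrichmentStudy(nFeatures = 50, nEnriched = 5,
                                   nPerStage = 10, seed = 4)
    expect_length(sim$enriched, 5L)
    areas <- as.matrix(sim$features[, sim$metadata$sample_id])
    predCols <- sim$metadata$sample_id[sim$metadata$stage == "predatory"]
    sapCols <- sim$metadata$sample_id[sim$metadata$stage == "saprophytic"]
    plantedIdx <- match(sim$enriched, sim$features$feature_id)
    ratio <- rowMeans(areas[plantedIdx, predCols]) /
        rowMeans(areas[plantedIdx, sapCols])
    expect_true(all(ratio > 10))
    nullIdx <- setdiff(seq_len(50), plantedIdx)
    nullRatio <- rowMeans(areas[nullIdx, predCols]) /
        rowMeans(areas[nullIdx, sapCols])
    expect_true(median(nullRatio) < 2)
    # infeasible configs are refused
    expect_error(syntheticConfig(families = list(list(prevalence = 0))),
                 "prevalence")
})
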