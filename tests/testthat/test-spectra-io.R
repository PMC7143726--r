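test_that("Spectrum constructor sorts, merges and validates peaks", {
    sp <- Spectrum("s1", 500, mz = c(300, 100, 200),
                   intensity = c(3, 1, 2))
    expect_equal(peaks(sp)[, "mz"], c(100, 200, 300))
    expect_equal(peaks(sp)[, "intensity"], c(1, 2, 3))
    # exact duplicate m/z merged by summing
    dup <- Spectrum("s2", 500, mz = c(100, 100, 200),
                    intensity = c(1, 2, 5))
    expect_equal(peakCount(dup), 2L)
    expect_equal(unname(peaks(dup)[1, "intensity"]), 3)
    expect_error(Spectrum("bad", -5, mz = 100, intensity = 1),
                 "precursorMz")
    expect_error(Spectrum("bad", 500, mz = 100, intensity = -1),
                 "intensities")
})

test_that("MGF round-trip preserves precursor, peak count and intensities", {
    spectra <- list(
        toySpectrum("a", 500.12345, c(100.5, 200.25, 300.125),
                    c(10, 2e6, 0.5), z = 2L, sample = "s1"),
        toySpectrum("b", 912.4, c(88.8, 444.4), c(1, 1)))
    spectra[[1]]@retentionTime <- 123.456
    path <- withr::local_tempfile(fileext = ".mgf")
    writeMgf(spectra, path)
    back <- readMgf(path)
    expect_length(back, 2L)
    for (i in 1:2) {
        expect_lt(abs(precursorMz(back[[i]]) - precursorMz(spectra[[i]])),
                  1e-4)
        expect_equal(peakCount(back[[i]]), peakCount(spectra[[i]]))
        expect_equal(peaks(back[[i]])[, "intensity"],
                     peaks(spectra[[i]])[, "intensity"], tolerance = 1e-6)
        expect_equal(charge(back[[i]]), charge(spectra[[i]]))
        expect_equal(sampleId(back[[i]]), sampleId(spectra[[i]]))
    }
})

test_that("readMgf handles block count, defaults and malformed input", {
    path <- withr::local_tempfile(fileext = ".mgf")
    writeLines(c("BEGIN IONS", "TITLE=one", "PEPMASS=500.1",
                 "CHARGE=1+", "100.1 5", "99.0 2", "END IONS",
                 "BEGIN IONS", "TITLE=two", "PEPMASS=300.2",
                 "150.0 1", "END IONS"), path)
    expect_message(sp <- readMgf(path), "without CHARGE")
    expect_length(sp, 2L)
    # unsorted peaks resorted ascending
    expect_equal(peaks(sp[[1]])[, "mz"], c(99.0, 100.1))
    expect_equal(charge(sp[[2]]), 1L)

    noPep <- withr::local_tempfile(fileext = ".mgf")
    writeLines(c("BEGIN IONS", "TITLE=x", "100 1", "END IONS"), noPep)
    expect_error(readMgf(noPep), "PEPMASS")

    badPeak <- withr::local_tempfile(fileext = ".mgf")
    writeLines(c("BEGIN IONS", "PEPMASS=100", "CHARGE=1+",
                 "abc def", "END IONS"), badPeak)
    expect_error(readMgf(badPeak), "line 4")

    empty <- withr::local_tempfile(fileext = ".mgf")
    writeLines(character(0), empty)
    expect_warning(out <- readMgf(empty), "no spectra")
    expect_length(out, 0L)
})

test_that("sample metadata validation enforces tokens and invariants", {
    meta <- smallMetadata()
    expect_silent(validateSampleMetadata(meta))
    expect_equal(nrow(validateSampleMetadata(meta)), 5L)

    bad <- meta; bad$stage[5] <- "predatory"   # blank with a life stage
    expect_error(validateSampleMetadata(bad), "not_applicable")

    dup <- rbind(meta, meta[1, ])
    expect_error(validateSampleMetadata(dup), "duplicated sample_id")

    unk <- meta; unk$stage[1] <- "dormant"
    expect_error(validateSampleMetadata(unk), "allowed")

    noneBad <- meta; noneBad$species[1] <- "none"
    expect_error(validateSampleMetadata(noneBad), "none")

    path <- withr::local_tempfile(fileext = ".tsv")
    write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_equal(readSampleMetadata(path)$sample_id, meta$sample_id)
})

test_that("spectra joined to metadata report orphans instead of dropping", {
    meta <- smallMetadata()
    sp <- list(toySpectrum("x", 400, c(100, 200), sample = "s_sap1"),
               toySpectrum("y", 400, c(100, 200), sample = "ghost"))
    expect_error(joinSpectraMetadata(sp, meta), "ghost")
    joined <- joinSpectraMetadata(sp[1], meta)
    expect_equal(joined$stage, "saprophytic")
})

test_that("GraphML and node-table export round-trip a small network", {
    nodes <- list(toyNode("N1", 300, c(100, 150, 200)),
                  toyNode("N2", 300.001, c(100, 150, 200)),
                  toyNode("N3", 700, c(650.5, 660.5)))
    net <- buildNetwork(nodes, minMatchedPeaks = 2)
    path <- withr::local_tempfile(fileext = ".graphml")
    writeNetworkGraphML(net, path)
    g <- igraph::read_graph(path, format = "graphml")
    expect_equal(igraph::vcount(g), 3)
    expect_equal(igraph::ecount(g), nrow(networkEdges(net)))
    expect_setequal(igraph::V(g)$name, c("N1", "N2", "N3"))

    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeNodeTable(net, tsv)
    tab <- read.delim(tsv)
    expect_equal(nrow(tab), 3L)
    expect_true(all(c("node_id", "precursor_mz", "family_id") %in%
                    names(tab)))

    # empty (edge-free) network still yields valid GraphML
    lone <- buildNetwork(nodes[3], minMatchedPeaks = 2)
    p2 <- withr::local_tempfile(fileext = ".graphml")
    writeNetworkGraphML(lone, p2)
    expect_equal(igraph::vcount(igraph::read_graph(p2,
                                                   format = "graphml")), 1)
})
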