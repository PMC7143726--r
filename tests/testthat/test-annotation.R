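test_that("formula parsing and monoisotopic masses are exact", {
    expect_equal(monoisotopicMass("H2O"), 18.0106, tolerance = 1e-4)
    expect_equal(monoisotopicMass(""), 0)
    expect_equal(monoisotopicMass("C6H12O6"), 180.0634, tolerance = 1e-4)
    expect_error(monoisotopicMass("C2Xx3"), "unknown element")
    expect_equal(unname(parseFormula("CH4")["H"]), 4)
    # additivity over disjoint formulas
    expect_equal(monoisotopicMass(addFormulas("C5H5N5", "C2H2O")),
                 monoisotopicMass("C5H5N5") + monoisotopicMass("C2H2O"))
    expect_error(subtractFormulas("CH4", "O"), "negative")
    expect_equal(monoisotopicMass(subtractFormulas("C2H6O", "H2O")),
                 monoisotopicMass("C2H4"))
})

test_that("protonated m/z and neutral mass are mutual inverses", {
    expect_equal(mzFromNeutral(0, 1), 1.0072765, tolerance = 1e-7)
    expect_error(mzFromNeutral(100, 0), "charge")
    expect_error(neutralFromMz(100, 0), "charge")
    for (z in 1:3) {
        m <- 687.3188
        expect_equal(neutralFromMz(mzFromNeutral(m, z), z), m,
                     tolerance = 1e-9)
    }
})

test_that("residue masses and peptide mass conventions are consistent", {
    rm <- residueMasses()
    expect_equal(unname(rm["Gly"]), 57.02146, tolerance = 1e-5)
    expect_equal(unname(rm["hOrn"]), 172.08479, tolerance = 1e-5)
    expect_equal(unname(rm["Leu/Ile"]), 113.08406, tolerance = 1e-5)
    # cyclic Gly3-hOrn3 equals the C27H45N9O12 formula mass
    expect_equal(cyclicPeptideMass(rep(c("Gly", "hOrn"), each = 3)),
                 monoisotopicMass("C27H45N9O12"), tolerance = 1e-6)
    expect_equal(linearPeptideMass("Gly"), 75.0320, tolerance = 1e-4)
    # cyclic and linear differ by exactly one water for any sequence
    seqs <- list("Ala", c("Ala", "Arg"), rep("Ser", 4))
    for (s in seqs)
        expect_equal(linearPeptideMass(s) - cyclicPeptideMass(s),
                     monoisotopicMass("H2O"), tolerance = 1e-9)
    expect_error(cyclicPeptideMass(character(0)), "empty")
    expect_error(cyclicPeptideMass("Xyz"), "unknown residue")
})

test_that("library matching mirrors input filtering and reports isomer ties", {
    lib <- list(
        toySpectrum("compound_A", 400, c(90, 140, 190, 240, 290),
                    c(10, 20, 30, 40, 50)),
        toySpectrum("compound_B", 700, c(500.5, 600.5), c(5, 5)))
    query <- toyNode("N1", 400.001, c(90, 140, 190, 240, 290),
                     c(10, 20, 30, 40, 50))
    hits <- libraryMatch(query, lib)
    expect_equal(hits$name, "compound_A")
    expect_equal(hits$score, 1, tolerance = 1e-9)

    # a query sharing only 3 peaks fails the matched-peak minimum
    partial <- toyNode("N2", 400.001, c(90, 140, 190), c(10, 20, 30))
    expect_equal(nrow(libraryMatch(partial, lib)), 0L)

    expect_warning(none <- libraryMatch(query, list()), "empty")
    expect_equal(nrow(none), 0L)

    # structural isomers with identical spectra are both returned, tied
    iso <- list(
        toySpectrum("isomer_1", 298.31, c(57.07, 88.1, 120.2, 150.3, 200.4),
                    c(10, 30, 50, 30, 10)),
        toySpectrum("isomer_2", 298.31, c(57.07, 88.1, 120.2, 150.3, 200.4),
                    c(10, 30, 50, 30, 10)))
    q <- toyNode("N3", 298.3102, c(57.07, 88.1, 120.2, 150.3, 200.4),
                 c(10, 30, 50, 30, 10))
    both <- libraryMatch(q, iso)
    expect_equal(nrow(both), 2L)
    expect_equal(both$score[1], both$score[2])
})

test_that("mass-shift analogues are named from decoded neutral masses", {
    ref <- 687.3188
    mkNode <- function(id, neutral, z = 1L)
        toyNode(id, mzFromNeutral(neutral, z), c(100, 150, 200, 250),
                z = z)
    nodes <- list(
        mkNode("ref", ref),
        mkNode("deoxy", 671.3239),               # -O
        mkNode("acetyl", 729.3294, z = 2L),      # +C2H2O, doubly charged
        mkNode("odd", 643.2926),                 # -C2H4O: not in the table
        mkNode("same", ref))
    net <- new("MolecularNetwork", nodes = nodes,
               edges = data.frame(nodeA = character(),
                                  nodeB = character(), cosine = numeric(),
                                  matchedPeaks = integer()),
               familyId = stats::setNames(rep(1L, 5),
                   vapply(nodes, nodeId, character(1))))
    an <- findAnalogues(net, "ref")
    expect_setequal(an$name[an$node_id == "deoxy"], "-O")
    expect_setequal(an$name[an$node_id == "acetyl"], "+C2H2O")
    # the 44.026 Da loss matches no named delta and stays uncalled
    expect_false("odd" %in% an$node_id)
    # zero mass difference is never called as an analogue
    expect_false("same" %in% an$node_id)

    # symmetry up to sign: from the acetylated node, ref is -C2H2O
    back <- findAnalogues(net, "acetyl")
    expect_equal(back$name[back$node_id == "ref"], "-C2H2O")

    expect_error(findAnalogues(net, "ghost"), "unknown reference")
})

test_that("fragment ladders recover planted tags and reject noise", {
    core <- c("Ala", "Arg", "Ala", "Leu/Ile", "Ser", "Leu/Ile")
    sp <- theoreticalPeptideSpectrum(core, charge = 1)
    tags <- peptideLadder(sp)
    expect_true(coreMotif() %in% tags$tag)

    # random peaks with no residue spacing yield no tag
    set.seed(66)
    noise <- toySpectrum("noise", 900,
                         mz = sort(runif(12, 100, 800) + 0.123))
    expect_equal(nrow(peptideLadder(noise)), 0L)

    # a single residue step is below the minimum tag length
    short <- toySpectrum("short", 500, mz = c(200, 313.08406))
    expect_equal(nrow(peptideLadder(short)), 0L)

    # fewer than two peaks cannot form a ladder
    expect_equal(nrow(peptideLadder(toySpectrum("one", 500, 100))), 0L)
})

test_that("doubly-charged ladders are read at half residue spacing", {
    sp <- theoreticalPeptideSpectrum(c("Gly", "Ala", "Arg", "Ala",
                                       "Leu/Ile", "Ser", "Leu/Ile"),
                                     charge = 2)
    tags2 <- peptideLadder(sp, charges = c(1, 2))
    expect_true(any(tags2$ladder_charge == 2))
    expect_true(any(grepl(coreMotif(), tags2$tag, fixed = TRUE)))
})

test_that("conserved motifs are the longest shared residue substring", {
    m <- conservedMotif(c("Ala-Arg-Ala-Leu/Ile-Ser-Leu/Ile",
                          "Gly-Ala-Arg-Ala-Leu/Ile-Ser-Leu/Ile"))
    expect_equal(m$motif, coreMotif())
    expect_true(all(m$support))

    disjoint <- conservedMotif(c("Ala-Arg", "Ser-Gly"))
    expect_equal(disjoint$motif, "")

    expect_equal(conservedMotif(character(0))$motif, "")

    # threshold below 1 tolerates one divergent tag
    part <- conservedMotif(c("Ala-Arg-Ala", "Ala-Arg-Ala", "Ser-Gly-Ser"),
                           threshold = 0.6)
    expect_equal(part$motif, "Ala-Arg-Ala")
})
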