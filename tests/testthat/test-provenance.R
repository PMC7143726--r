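# metadata with 2 species x 2 strains x 2 stages plus two blanks
provMetadata <- function() {
    grid <- expand.grid(strain = c("AO1", "AO2", "AM1", "AM2"),
                        stage = c("saprophytic", "predatory"),
                        stringsAsFactors = FALSE)
    grid$species <- ifelse(grepl("^AO", grid$strain), "A_oligospora",
                           "A_musiformis")
    fungal <- data.frame(
        sample_id = paste0(grid$strain, "_",
                           ifelse(grid$stage == "saprophytic", "sap",
                                  "pred")),
        species = grid$species, strain_id = grid$strain,
        stage = grid$stage, is_blank = FALSE, blank_kind = "none",
        extract_phase = "organic", stringsAsFactors = FALSE)
    blanks <- data.frame(
        sample_id = c("bl_med", "bl_worm"), species = "none",
        strain_id = "none", stage = "not_applicable", is_blank = TRUE,
        blank_kind = c("medium", "worm"), extract_phase = "organic",
        stringsAsFactors = FALSE)
    rbind(fungal, blanks)
}

nodeIn <- function(id, samples)
    toyNode(id, 400, c(100, 200), members = paste0(id, "_", samples),
            samples = samples)

test_that("node categories follow stage presence with blank precedence", {
    meta <- provMetadata()
    nodes <- list(
        nodeIn("pred3", c("AO1_pred", "AO2_pred", "AM1_pred")),
        nodeIn("mixed", c("AO1_sap", "AO1_pred")),
        nodeIn("sap1", "AM1_sap"),
        nodeIn("grey", c("AO1_sap", "AO2_sap", "AO1_pred", "AO2_pred",
                         "AM1_pred", "bl_med")))
    prov <- assignProvenance(nodes, meta)
    expect_equal(prov$category,
                 c("predatory_only", "both_stages", "saprophytic_only",
                   "blank"))
    # category partition is exhaustive
    expect_equal(sum(table(prov$category)), length(nodes))
})

test_that("venn summary excludes blanks and percentages sum to 100", {
    meta <- provMetadata()
    nodes <- c(
        lapply(1:5, function(i) nodeIn(paste0("b", i),
                                       c("AO1_sap", "AO1_pred"))),
        lapply(1:2, function(i) nodeIn(paste0("s", i), "AO1_sap")),
        lapply(1:3, function(i) nodeIn(paste0("p", i), "AO1_pred")))
    vs <- vennSummary(assignProvenance(nodes, meta))
    expect_equal(vs$percent[vs$category == "both_stages"], 50)
    expect_equal(vs$percent[vs$category == "saprophytic_only"], 20)
    expect_equal(vs$percent[vs$category == "predatory_only"], 30)
    expect_equal(sum(vs$percent), 100)

    allBlank <- list(nodeIn("g1", "bl_med"))
    expect_warning(empty <- vennSummary(assignProvenance(allBlank, meta)),
                   "blank")
    expect_equal(nrow(empty), 0L)
})

test_that("a planted 60/15/25 category split is recovered within 3 points", {
    meta <- provMetadata()
    set.seed(404)
    draw <- sample(c("both", "sap", "pred"), 400, replace = TRUE,
                   prob = c(0.60, 0.15, 0.25))
    nodes <- lapply(seq_along(draw), function(i)
        nodeIn(paste0("n", i), switch(draw[i],
            both = c("AO1_sap", "AO1_pred"),
            sap = "AO1_sap", pred = "AO1_pred")))
    vs <- vennSummary(assignProvenance(nodes, meta))
    expect_lt(abs(vs$percent[vs$category == "both_stages"] - 60), 3)
    expect_lt(abs(vs$percent[vs$category == "saprophytic_only"] - 15), 3)
    expect_lt(abs(vs$percent[vs$category == "predatory_only"] - 25), 3)
    # and exactly matches the empirical draw
    expect_equal(vs$n[vs$category == "both_stages"], sum(draw == "both"))
})

test_that("parent-mass histogram conserves counts over half-open bins", {
    meta <- provMetadata()
    nodes <- list(
        toyNode("lo", 149.99, c(50, 60), members = "lo_AO1_sap",
                samples = "AO1_sap"),
        toyNode("edge", 150.0, c(50, 60), members = "edge_AO1_sap",
                samples = "AO1_sap"),
        toyNode("hi", 825.0, c(50, 60), members = "hi_AO1_pred",
                samples = "AO1_pred"),
        toyNode("grey", 400, c(50, 60), members = "grey_bl",
                samples = "bl_med"))
    prov <- assignProvenance(nodes, meta)
    h <- parentMassDistribution(prov, nodes, binWidth = 50)
    expect_equal(sum(h$count), 3L)             # blank excluded
    # 149.99 falls in [100,150), 150.0 in [150,200)
    sap <- h[h$category == "saprophytic_only", ]
    expect_equal(sort(sap$bin_start), c(100, 150))
    expect_true(all(h$bin_end - h$bin_start == 50))
    expect_equal(nrow(parentMassDistribution(prov[0, ], nodes)), 0L)
})

test_that("detection-frequency differential covers shared nodes only", {
    meta <- provMetadata()
    allSap <- paste0(c("AO1", "AO2", "AM1", "AM2"), "_sap")
    allPred <- paste0(c("AO1", "AO2", "AM1", "AM2"), "_pred")
    nodes <- list(
        nodeIn("everywhere", c(allSap, allPred)),        # delta = 0
        nodeIn("enriched", c(allPred, allSap[1:2])),     # 1 - 0.5 = +0.5
        nodeIn("redonly", allPred))                      # not reported
    prov <- assignProvenance(nodes, meta)
    fd <- detectionFrequencyDifferential(prov)
    expect_setequal(fd$node_id, c("everywhere", "enriched"))
    expect_equal(fd$freq_diff[fd$node_id == "everywhere"], 0)
    expect_equal(fd$freq_diff[fd$node_id == "enriched"], 0.5)
    expect_equal(attr(fd, "n_positive"), 1L)
    expect_true(all(fd$freq_diff >= -1 & fd$freq_diff <= 1))

    # antisymmetry under swapping the stage labels
    swapped <- meta
    swapped$stage[swapped$stage == "predatory"] <- "tmp"
    swapped$stage[swapped$stage == "saprophytic"] <- "predatory"
    swapped$stage[swapped$stage == "tmp"] <- "saprophytic"
    fd2 <- detectionFrequencyDifferential(assignProvenance(nodes, swapped))
    expect_equal(fd2$freq_diff[fd2$node_id == "enriched"], -0.5)
})

test_that("species-prevalence filter is strict and monotone", {
    meta <- provMetadata()
    # detected in both A_musiformis strains (2/2), absent from A_oligospora
    nodes <- list(nodeIn("amOnly", c("AM1_pred", "AM2_pred")),
                  nodeIn("half", "AM1_pred"),   # exactly half: must fail
                  nodeIn("both", c("AO1_pred", "AO2_pred", "AM1_pred")))
    prov <- assignProvenance(nodes, meta)
    hits <- speciesPrevalenceFilter(prov, minFraction = 0.5)
    expect_true("amOnly" %in% hits$node_id)
    expect_false("half" %in% hits$node_id)     # 1/2 is not > 1/2
    amRow <- hits[hits$node_id == "amOnly", ]
    expect_true(amRow$pass_A_musiformis)
    expect_false(amRow$pass_A_oligospora)
    expect_equal(amRow$species, "A_musiformis")

    # raising the threshold never adds nodes
    for (f in c(0.5, 0.7, 0.9)) {
        lo <- speciesPrevalenceFilter(prov, minFraction = f)$node_id
        hi <- speciesPrevalenceFilter(prov,
                                      minFraction = min(f + 0.2, 0.99))$node_id
        expect_true(all(hi %in% lo))
    }
})
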