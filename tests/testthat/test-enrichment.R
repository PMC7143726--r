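# hand-built feature table: columns ordered as smallMetadata() samples
# (s_sap1, s_sap2, s_pred1, s_pred2, blank1)
handFeatures <- function(rows) {
    ft <- data.frame(feature_id = names(rows),
                     mz = seq(200, by = 10, length.out = length(rows)),
                     rt = 100, stringsAsFactors = FALSE)
    areas <- do.call(rbind, rows)
    colnames(areas) <- c("s_sap1", "s_sap2", "s_pred1", "s_pred2",
                         "blank1")
    cbind(ft, as.data.frame(areas))
}

test_that("the four filter steps apply in order with a full audit trail", {
    meta <- smallMetadata()
    ft <- handFeatures(list(
        # blank mean 2e5 >= 1e5: fails step i regardless of everything else
        dirty = c(1, 1, 1e7, 1e7, 2e5),
        # blank 0, pred 1e6, sap 5e5: fold 2 < 10 fails step iii
        weak = c(5e5, 5e5, 1e6, 1e6, 0),
        # clean and strongly enriched: passes i-iii, tested in iv
        good = c(1e4, 1.2e4, 2e6, 2.2e6, 0),
        # zero blank mean with positive predatory mean passes step ii
        zeroes = c(0, 0, 3e6, 3.1e6, 0)))
    res <- enrichmentFilter(ft, meta)
    expect_false(res$passed_i[res$feature_id == "dirty"])
    expect_false(res$selected[res$feature_id == "dirty"])
    expect_true(res$passed_ii[res$feature_id == "weak"])
    expect_false(res$passed_iii[res$feature_id == "weak"])
    expect_true(res$passed_iii[res$feature_id == "good"])
    expect_true(res$passed_ii[res$feature_id == "zeroes"])
    expect_equal(res$fold_pred_vs_blank[res$feature_id == "zeroes"], Inf)
    # selected iff all four steps passed
    expect_equal(res$selected, res$passed_i & res$passed_ii &
                 res$passed_iii & res$passed_iv)
    # BH-adjusted p never below the raw p
    tested <- !is.na(res$p_value)
    expect_true(all(res$adjusted_p[tested] >= res$p_value[tested]))
})

test_that("degenerate designs are refused or flagged untestable", {
    meta <- smallMetadata()
    ft <- handFeatures(list(f = c(1e4, 1e4, 1e6, 1e6, 0)))
    noBlank <- meta[!meta$is_blank, ]
    expect_error(enrichmentFilter(ft[, -ncol(ft)], noBlank), "blank")

    onePred <- meta[meta$sample_id != "s_pred2", ]
    ft2 <- ft[, names(ft) != "s_pred2"]
    res <- enrichmentFilter(ft2, onePred)
    expect_true(all(res$untestable))
    expect_false(any(res$selected))
})

test_that("tightening fold or blank ceiling shrinks the respective survivor sets", {
    set.seed(77)
    sim <- simulateEnrichmentStudy(nFeatures = 120, nEnriched = 10,
                                   nPerStage = 8, seed = 77)
    base <- enrichmentFilter(sim$features, sim$metadata, fold = 5)
    strict <- enrichmentFilter(sim$features, sim$metadata, fold = 20)
    expect_true(all(strict$feature_id[strict$selected] %in%
                    base$feature_id[base$selected]))
    lowCeil <- enrichmentFilter(sim$features, sim$metadata,
                                blankMax = 2e4)
    highCeil <- enrichmentFilter(sim$features, sim$metadata,
                                 blankMax = 1e6)
    expect_true(all(lowCeil$feature_id[lowCeil$passed_i] %in%
                    highCeil$feature_id[highCeil$passed_i]))
})

test_that("the planted-enrichment simulation is recovered by the filter", {
    sim <- simulateEnrichmentStudy(seed = 3)
    res <- enrichmentFilter(sim$features, sim$metadata)
    sel <- res$feature_id[res$selected]
    expect_gte(sum(sim$enriched %in% sel), 18)
    expect_lte(sum(!(sel %in% sim$enriched)),
               0.05 * (nrow(sim$features) - length(sim$enriched)))
})

test_that("ranking keeps predatory-skewed survivors in area order with stable ties", {
    meta <- smallMetadata()
    ft <- handFeatures(list(
        big = c(0, 0, 5e6, 5e6, 0),
        mid = c(0, 0, 3e6, 3e6, 0),
        sml = c(0, 0, 1e6, 1e6, 0),
        tie_b = c(0, 0, 3e6, 3e6, 0),
        down = c(5e6, 5e6, 1e3, 1e3, 0)))
    res <- enrichmentFilter(ft, meta)
    ranked <- rankForIdentification(res, onlySelected = FALSE)
    keep <- ranked$feature_id
    expect_false("down" %in% keep)             # not predatory-skewed
    expect_equal(keep[1], "big")
    # tie on mean area broken by feature id: "mid" sorts before "tie_b"
    expect_lt(match("mid", keep), match("tie_b", keep))
    expect_equal(nrow(rankForIdentification(res, topN = 1,
                                            onlySelected = FALSE)), 1L)
})

test_that("feature tables validate on ingest and link to nodes by ppm", {
    ft <- handFeatures(list(f = c(1, 1, 1, 1, 0)))
    bad <- ft; bad$mz[1] <- -1
    expect_error(validateFeatureTable(bad), "> 0")
    dup <- rbind(ft, ft)
    expect_error(validateFeatureTable(dup), "duplicated")
    neg <- ft; neg$s_sap1 <- -5
    expect_error(validateFeatureTable(neg), ">= 0")

    nodes <- list(toyNode("N1", 200.0005, c(100, 150)),
                  toyNode("N2", 210.5, c(100, 150)))
    links <- linkFeaturesToNodes(ft, nodes, ppm = 5)
    expect_equal(links$node_id, "N1")          # 2.5 ppm away
    expect_equal(nrow(linkFeaturesToNodes(ft, nodes, ppm = 1)), 0L)
})
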