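# shared fixtures and independent oracles for the test suite

toySpectrum <- function(id, prec, mz, int = rep(1, length(mz)), z = 1L,
                        sample = NA_character_) {
    Spectrum(id, precursorMz = prec, mz = mz, intensity = int, charge = z,
             sampleId = sample)
}

toyNode <- function(id, prec, mz, int = rep(1, length(mz)), z = 1L,
                    members = paste0(id, "_m1"), samples = character(0)) {
    o <- order(mz)
    new("ConsensusNode", nodeId = id, precursorMz = prec,
        charge = as.integer(z), peaks = cbind(mz = mz[o],
                                              intensity = int[o]),
        memberSpectrumIds = members, sampleIds = samples)
}

# exhaustive maximum-weight one-to-one matching over the candidate pairs
# of the modified cosine (direct or precursor-shifted alignment); written
# independently of the greedy implementation it checks
exactModifiedCosine <- function(specA, specB, fragmentTol = 0.5,
                                transform = "sqrt") {
    wa <- normalizeForCosine(specA, transform = transform)
    wb <- normalizeForCosine(specB, transform = transform)
    delta <- attr(wa, "precursorMz") - attr(wb, "precursorMz")
    cand <- list()
    for (i in seq_len(nrow(wa)))
        for (j in seq_len(nrow(wb))) {
            d <- wa[i, "mz"] - wb[j, "mz"]
            if (abs(d) <= fragmentTol || abs(d - delta) <= fragmentTol)
                cand[[length(cand) + 1L]] <-
                    c(i, j, wa[i, "weight"] * wb[j, "weight"])
        }
    best <- 0; bestN <- 0L
    recurse <- function(k, usedA, usedB, score, n) {
        if (score > best || (score == best && n > bestN)) {
            best <<- score; bestN <<- n
        }
        if (k > length(cand)) return()
        recurse(k + 1L, usedA, usedB, score, n)   # skip pair k
        p <- cand[[k]]
        if (!(p[1] %in% usedA) && !(p[2] %in% usedB))
            recurse(k + 1L, c(usedA, p[1]), c(usedB, p[2]),
                    score + p[3], n + 1L)
    }
    recurse(1L, integer(0), integer(0), 0, 0L)
    list(cosine = min(best, 1), matchedPeaks = bestN)
}

randomSpectrum <- function(id, nPeaks = sample(3:6, 1)) {
    toySpectrum(id, prec = runif(1, 200, 800),
                mz = sort(runif(nPeaks, 100, 500)),
                int = runif(nPeaks, 1, 100))
}

# reference (slow) family-size capping: recompute components from scratch
# after every single edge removal, using plain union-find
slowCapFamilies <- function(ids, edges, cap) {
    comps <- function(ed) {
        parent <- stats::setNames(ids, ids)
        find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
        if (nrow(ed)) for (r in seq_len(nrow(ed))) {
            a <- find(ed$nodeA[r]); b <- find(ed$nodeB[r])
            if (a != b) parent[[a]] <- b
        }
        vapply(ids, find, character(1))
    }
    repeat {
        cc <- comps(edges)
        sizes <- table(cc)
        bigRoots <- names(sizes)[sizes > cap]
        if (!length(bigRoots) || !nrow(edges)) break
        inBig <- cc[edges$nodeA] %in% bigRoots
        cand <- which(inBig)
        o <- cand[order(edges$cosine[cand], edges$matchedPeaks[cand],
                        edges$nodeA[cand], edges$nodeB[cand])][1L]
        edges <- edges[-o, , drop = FALSE]
    }
    edges
}

coreMotif <- function() {
    paste(c("Ala", "Arg", "Ala", "Leu/Ile", "Ser", "Leu/Ile"),
          collapse = "-")
}

smallMetadata <- function() {
    data.frame(
        sample_id = c("s_sap1", "s_sap2", "s_pred1", "s_pred2", "blank1"),
        species = c(rep("A_oligospora", 4), "none"),
        strain_id = c("ST1", "ST2", "ST1", "ST2", "none"),
        stage = c("saprophytic", "saprophytic", "predatory", "predatory",
                  "not_applicable"),
        is_blank = c(FALSE, FALSE, FALSE, FALSE, TRUE),
        blank_kind = c(rep("none", 4), "medium"),
        extract_phase = "organic",
        stringsAsFactors = FALSE)
}
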