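Package: TrapNet
Title: Molecular Networking and Stage-Differential Metabolomics of
    Nematode-Trapping Fungi
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative LC-MS/MS metabolomics of nematode-trapping
    fungi across their saprophytic and predatory life stages. Builds molecular
    networks from tandem mass spectra with the modified cosine similarity,
    collapses repeated spectra into consensus metabolite nodes, classifies
    nodes by life stage and species provenance, applies a four-step
    blank-filtered predatory-stage enrichment screen to quantified features,
    and annotates metabolites by spectral library matching, mass-shift
    analogue logic and peptide fragment-ladder sequence tags. A bundled
    synthetic-data generator emulates the multi-species, multi-strain,
    two-stage study design with planted ground truth so every stage of the
    pipeline can be exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Metabolomics, MassSpectrometry, Network, Annotation
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'TrapNet-package.R'
    'accessors.R'
    'annotation-mass.R'
    'preprocess.R'
    'networking.R'
    'annotation-match.R'
    'consensus.R'
    'spectra-io.R'
    'enrichment.R'
    'provenance.R'
    'synthetic-data.R'
    'pipeline.R'
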