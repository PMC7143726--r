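---
title: "TrapNet methods: molecular networking and stage-differential analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TrapNet methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TrapNet)
```

TrapNet analyses untargeted LC–MS/MS data from nematode-trapping fungi
sampled in two lifestyles — saprophytic (no traps) and predatory (traps
formed after nematode exposure) — across many wild strains of several
species. This vignette records the models, the parameter choices and
their rationale, what the bundled synthetic data do and do not emulate,
and the numerical decisions a maintainer would want spelled out.

## The spectral model

A `Spectrum` is a positive-mode MS/MS scan: precursor m/z, charge,
retention time (seconds) and a peak matrix sorted strictly ascending in
m/z (exact duplicates are merged at construction). Charge sign is
ignored throughout because acquisition is positive-mode; a missing
charge on import defaults to 1 and is logged.

Two cleaning steps precede all similarity scoring:

* **Precursor-window removal** (`removePrecursorWindow`, default 17 Da,
  *boundary inclusive*): residual precursor signal, its isotopes and
  neutral losses otherwise dominate the cosine. We read "within ±17 Da"
  as a closed interval and pin that choice with a test; the practical
  difference is a measure-zero boundary case.
* **Square-root intensity weighting** (`normalizeForCosine`): weights
  are √intensity scaled to unit Euclidean norm, damping base-peak
  dominance. The transform is configurable (`"none"` skips the root)
  because the upstream workflow version does not document it; the
  square root is the de facto standard for molecular networking.

## Modified cosine and the network

`modifiedCosine(a, b, fragmentTol = 0.5)` admits fragment pairs aligned
directly or after shifting by Δ = precursor(a) − precursor(b), then
selects a one-to-one matching greedily by descending weight product.
Greedy matching is not guaranteed optimal for arbitrary weights, so the
test suite keeps an exhaustive maximum-weight matching oracle and checks
equality on randomly generated small spectra (and `≤` always); on
realistic peak spacings the two coincide because few peaks contend for
the same partner. Scores are clamped to [0, 1]; symmetry holds to 1e−9.

`buildNetwork` applies, in a fixed order: the cosine threshold
(≥ 0.65) and matched-peak minimum (≥ 4, inclusive — the workflow
literature uses "more than 4" for the network and "at least 4" for
library search, and the upstream implementation treats the parameter
inclusively, so one inclusive parameter with default 4 is used for
both); then the mutual top-K rule (K = 10, partner ranking ties broken
by node id); then molecular-family capping (components larger than 500
lose their lowest-cosine edge — ties broken by lower matched peaks,
then lexicographic node pair — until all families fit). Whether top-K
should precede the cosine threshold is undocumented upstream; we fix
threshold-then-top-K, which can only remove additional edges.

## Consensus nodes

The clustering that collapses repeated scans of one analyte is
deliberately simple and deterministic, because the reference
implementation's heuristics are unpublished at the necessary
granularity: spectra are sorted by descending total intensity
(ties: precursor m/z, then spectrum id) and each joins the first node
whose *seed* lies within 0.02 Da of its precursor, shares its charge
and scores ≥ 0.7 modified cosine against the seed — else it seeds a new
node. This yields a partition, invariant under permutation of the
input. The within-node threshold (0.7) is intentionally stricter than
the edge threshold (0.65), mirroring the separation of clustering from
networking upstream. Consensus peaks merge member fragments within the
0.5 Da fragment tolerance by intensity-weighted mean m/z and summed
intensity; a singleton node reproduces its member spectrum exactly.
Node counts on any real dataset depend on these internals, so absolute
node counts are not a meaningful comparison surface; topology
properties and planted-truth recovery are.

## Provenance, Venn split and differentials

"Detected in a sample" means ≥ 1 member scan from that sample — no
intensity floor, since the published node colouring derives from the
network rather than the quantification table. Blank membership (any of
solvent, medium, worm or internal-standard samples) overrides
everything: a node seen in 50 fungal samples and one medium blank is
grey. That conservative precedence is what makes the internal standard
— spiked into every sample — land in the blank class rather than
polluting the fungal categories. Detection-frequency differentials use
sample-level fractions; the species-prevalence rule uses strain-level
denominators and a *strict* > ½ comparison (9 of 18 strains fails).

## The enrichment screen

Steps i–iii are arithmetic on group means (blank ceiling 10⁵; fold
threshold 10 against blank and against the saprophytic stage; a zero
blank mean passes step ii when the predatory mean is positive). Step iv
is a two-sided Welch t-test on log₁₀(area + 1) — the +1 pseudo-count
makes zero areas well-defined — with Benjamini–Hochberg adjustment
computed across the features that reached step iv, adjusted p < 0.05.
The upstream software reports only "adjusted p-value", so the test and
adjustment are configurable (`mannwhitney`, `bonferroni`); Welch + BH
is the standard choice for untargeted fold-change screens. Adjustment
is per analysis run (in a two-phase study, per extract phase), chosen
because the two phases are separate acquisitions and networks. With
fewer than two samples in a stage the feature is flagged untestable and
never selected. Note that features absent from many strains (species-
restricted compounds) carry zero-inflated group variances; at small
strain counts the Welch test is honestly underpowered for them, which
is why the screen's operating characteristics are established on a
complete-detection simulation and on the full-scale strain census.

## Annotation

*Mass arithmetic.* Monoisotopic element masses (C 12, H 1.0078250,
N 14.0030740, O 15.9949146, P 30.9737615, S 31.9720707) and the proton
mass 1.0072765 Da are embedded constants. Residue masses derive from
elemental compositions; hOrn is N⁵-acetyl-N⁵-hydroxyornithine
(C₇H₁₂N₂O₃, 172.08479 Da), the hydroxamate monomer of ferrichrome-type
siderophores. A cyclic peptide is the plain residue sum; linear adds
one water. Leu and Ile are isobaric at this resolution and always
reported as the merged symbol.

*Analogues.* Neutral masses are decoded as z·(m/z − m_p), so
doubly-charged nodes participate correctly. Named deltas (−O ≈
−15.9949, ±C₂H₂O ≈ ±42.0106) are matched within 0.01 Da, by default
within the reference's molecular family. A neutral difference that
matches no named delta — e.g. a 44.026 Da loss, which is C₂H₄O, not
C₂H₂O — is deliberately left uncalled rather than forced to the nearest
label.

*Peptide ladders.* Sequence tags are chains of peaks whose consecutive
m/z differences equal residue masses within 0.02 Da (half-mass spacing
for doubly-charged ladders). Two virtual terminal anchors — the
protonated N-terminus at m/z = m_p and the C-terminus at water/z + m_p
— let a b₁ or y₁ ion contribute its own residue, so an unbroken b
series reads out the complete sequence. Enumeration is exhaustive over
the peak DAG (spectra are small); maximal tags of ≥ 3 residues are
kept. Two reading-direction facts shape the design: y-series ladders
read the backbone C→N, so every tag is direction-ambiguous, and
`conservedMotif` therefore counts a motif as supported when it occurs
in a tag *or its reversal* (reporting the lexicographically smaller
orientation); and the ±17 Da precursor window of the *scoring* pipeline
can delete mid-chain fragments of doubly-charged peptides (the
full-length y ion of a 2+ precursor sits exactly at the precursor m/z),
so ladder reading runs on the raw member scans, not the windowed
consensus. Reading member scans also heals per-scan peak dropout: a
fragment missing from one scan is usually present in another.

## The synthetic-data generator

`generateDataset(syntheticConfig(seed))` emulates the study design —
three *Arthrobotrys* species, many wild strains, paired
saprophytic/predatory cultures, blank controls (solvent, medium, worm,
internal standard spiked everywhere) — with planted compound families:
a broad both-stage background; predatory-only and saprophytic-only
sets; a ferrichrome-type siderophore set (reference plus −O, +C₂H₂O,
−C₂H₂O analogues, one of them doubly charged) restricted to two
species and quantitatively stage-enriched; and a trap-associated
peptide series restricted to one species' predatory stage, every member
containing the core Ala-Arg-Ala-Leu/Ile-Ser-Leu/Ile with varying
flanks. Peptide spectra are exact b/y series; other compounds get
seeded fragment scaffolds, with family members sharing a base scaffold
whose fragments are partly offset by the compounds' neutral-mass
difference so the family genuinely networks. Noise: Gaussian m/z jitter
(sd 0.003 Da, an order below the clustering tolerance), lognormal
intensity variation (CV 0.25), per-peak dropout (5%), and a
data-dependent-acquisition effect — saprophytic-stage occurrences of
stage-enriched compounds trigger MS/MS with probability 0.6, the
mechanism behind positive detection-frequency differentials in real
DDA data.

Scale defaults are desk-sized: 10/9/9 strains per species (the minority
species kept at half their real 64/18/18 census so strain-fraction
rules retain granularity — with 6 strains, a detection in exactly 3 is
precisely half and the strict rule becomes a coin flip of the binomial
draw), ~40 compounds, ~2000 scans per dataset; `scale = "full"`
restores the real census. The planted peptide prevalence is 14/18, the
detectability the analysis is built around. All randomness flows from
one seed; identical configurations give byte-identical output files.

What the generator does **not** emulate: chromatographic peak shapes,
isotope envelopes, adducts and in-source fragments, retention-time
structure, correlated (matrix-dependent) noise, and the sheer scan
count of the real study. Passing the end-to-end tests therefore shows
the pipeline's logic is sound under the planted model, not that its
defaults are optimal for any particular instrument's data.

## Problem sizes and budgets

The test-suite simulations use the desk-scale generator (10 seeds of
~2000 scans for end-to-end recovery), the complete-detection
enrichment simulation at the stated operating point (20 planted 50×
features among 480 nulls, 30 samples per stage), a 20-seed × 1000-
feature global-null calibration of the significance step (run with the
fold gate open so the test is actually exercised), and 50 + 1000 random
spectrum pairs for the matching oracle and symmetry/bound properties.
These sizes were chosen so the full suite completes in about a minute
while every statistical check retains enough replicates to be
meaningful.

## Known limitations

* Greedy consensus clustering is a reproducible stand-in, not a
  reimplementation, of the reference clustering; node counts differ.
* The ladder reader has no cyclic-permutation scoring, so cyclic
  peptides are only read through their linearised fragments.
* Library matching uses the bundled toy library format (MGF with NAME
  headers); no external library download is attempted.
* The enrichment test treats samples as independent; the paired
  structure (same strain, two stages) is not yet exploited.
* mzXML/mzML readers are out of scope; MGF is the interchange format,
  and the two extract phases of a real study should be run as two
  separate analyses (networks are never merged across phases).
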