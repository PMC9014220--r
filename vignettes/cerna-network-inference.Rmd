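---
title: "Inferring circRNA-associated ceRNA networks: methods and design notes"
author: "ceRNAnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring circRNA-associated ceRNA networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Circular RNAs (circRNAs) are covalently closed transcripts produced by
back-splicing; lacking free ends, they escape exonucleolytic decay and can
accumulate to high levels in brain tissue. When a circRNA carries binding
sites for a microRNA it can act as a *competing endogenous RNA* (ceRNA, a
"sponge"): by sequestering the miRNA it derepresses that miRNA's mRNA
targets. A circRNA-associated ceRNA network is the tripartite
circRNA-miRNA-mRNA graph summarising which sponge relationships are
plausible in a given contrast — here, aging versus young hippocampus,
within a control and within a surgery condition (a 2x2 design with three
replicates per cell).

`ceRNAnet` implements the full desk-side inference: class-specific
normalisation, differential expression (DE), miRNA seed-site matching on
linear and circular targets, triplet scoring by expression correlation,
network assembly, and term enrichment — plus a synthetic-data generator
that plants known sponge triplets so that every stage can be verified
against a ground truth without access to sequencing archives.

## Normalisation units

Each RNA class has its own unit, reflecting how its reads are generated:

* **SRPBM** for circRNAs: back-splice-junction reads per billion mapped
  reads, `count / library_size * 1e9`. Only junction-crossing reads
  identify the circle, so there is no length term.
* **TPM** for mature miRNAs, implemented as reads per million class-mapped
  reads, `count / column_sum * 1e6`. Mature miRNAs are uniformly ~22 nt,
  so transcript-length normalisation degenerates to a constant; each
  sample column of the output sums to exactly 10^6.
* **FPKM** for mRNAs: `count / (length_kb) / (library_millions)`, with the
  exon-model length supplied as a two-column TSV.

Library sizes default to per-class column sums, which keeps synthetic runs
self-contained; a mapping-total file can override them (the definition of
the SRPBM denominator — total clean reads versus class-mapped reads — is a
convention choice, and the override makes either reproducible).

## Differential expression

Replicate counts are pooled per group and each feature is tested with the
two-sided Fisher exact test on the 2x2 table
`[[count_a, lib_a - count_a], [count_b, lib_b - count_b]]` (point-probability
summation). P values are Benjamini-Hochberg adjusted across features; the
selection rule is `|log2FC| >= 1` and raw `P <= 0.05` (both configurable),
with fold changes computed on class-unit group means with a pseudocount of
0.1 so zero-count features stay finite.

**Known limitation (important).** Pooling replicates makes the Fisher test
model *counting noise only*. Under realistic biological overdispersion
(negative binomial dispersion ~0.1, i.e. a ~32% biological CV), the
between-group variance of pooled counts is tens of times larger than the
hypergeometric null allows, and the raw-P criterion rejects massively: the
package's own null calibration (`fisher_null_experiment()`,
`analysis/07_calibration.R`) measures a raw-P `<= 0.05` rejection rate of
~0.78 on null data where the nominal level is 0.05. The fold-change filter
absorbs almost all of it (joint rate ~0.01), which is presumably why this
test family remains usable in practice, but P values from pooled exact
tests should not be read as calibrated error rates. A dispersion-aware
exact NB test (as in edgeR) is the principled alternative and is deliberately
out of scope here; the pooled test is what the pipeline specifies.

## Seed matching, on lines and on circles

The default site definition is the strict canonical rule: perfect
Watson-Crick complementarity to miRNA positions 2-8 (7mer-m8), G:U
disallowed, upgraded to 8mer when the target base opposite miRNA position 1
is an adenine. 6mer/7mer-A1 variants are opt-in. Coordinates are 0-based
half-open on the target as given.

Circular targets are scanned by doubling the back-splice-joined sequence
and keeping matches that start in the first copy; positions are reported
modulo the circle length and `spans_junction` marks sites that wrap the
back-splice joint — sites a linear scan structurally cannot find. The
implementation is verified against an exhaustive rotation-enumeration
oracle, and rotation invariance of the site multiset is a tested property.

## Triplet scoring and the sensitivity correlation

Candidate pairs require both members to pass the DE filter and at least
one seed site. miRNAs present in pairs of both kinds ("shared" miRNAs)
define candidate triplets. For each triplet the package computes Pearson
correlations on `log2(x + 1)`-transformed class-unit expression across the
six samples of the comparison (the log tames NB skew), and the sensitivity
correlation

S = cor(x, y) − pcor(x, y | m),  pcor = (cor_xy − cor_cm·cor_tm) / √((1−cor_cm²)(1−cor_tm²)),

i.e. how much of the circRNA-mRNA correlation disappears once the shared
miRNA is conditioned out. A triplet is kept when `cor_xy >= 0.7` and
`S >= 0.3` (defaults, recorded in output metadata). No correlation P
values are computed: with six samples they carry almost no information, so
the thresholds are effect-size based.

**Known limitation (important).** With n = 6 samples S is a very unstable
statistic. Whenever the sample correlations saturate (|cor_cm| or
|cor_tm| near 1, which *strong* coupling makes common), the partial
correlation's denominator nearly vanishes and S collapses toward zero even
for genuine sponge triplets; with moderate coupling the population value
of S itself sits only ~0.1 above the 0.3 threshold. Across the calibration
experiments a planted triplet passes the S gate only about half the time,
capping edge recall near 0.5 (mean F1 ~0.5-0.55 over seeds;
`analysis/07_calibration.R` prints the measured values). Nothing in the
estimator is wrong — the oracle checks confirm S equals the
regression-residual definition to 10^-10 — the instability is intrinsic to
partial correlations at this sample size. Studies with n = 3 per group
should treat S-thresholded networks as candidate lists, not inference.

The DE-direction constraint on pairs (miRNA opposite to both partners)
defaults **off**: the published tables this package mirrors retain a
down-regulated circRNA paired with a down-regulated miRNA, so enforcing
opposition would delete printed edges (`analysis/06_printed_tables.R`
demonstrates this).

## Network assembly

Valid triplets are merged into a graph whose nodes carry class, DE
direction and log2FC, and whose edges (circRNA-miRNA, miRNA-mRNA) carry
seed-site counts and owning triplet ids. The graph is bipartite between
miRNAs and the other classes by construction; node and edge order is
deterministic. Exports: edge/triplet TSV and GraphML for Cytoscape-style
rendering.

## Enrichment

Gene lists (the network mRNAs) are scored against user-supplied GMT
collections by the upper-tail hypergeometric test over a configurable
background (default: all quantified mRNAs), BH-corrected, and filtered at
`P < 0.05`, count `>= 3`, enrichment factor `> 1.5`. Passing terms become a
term-similarity network with edges where Cohen's kappa of the membership
vectors over the background exceeds 0.3 — kappa being the documented
convention behind "similarity" in the Metascape-style workflow this
mirrors. Multi-list runs produce a terms x lists `-log10 P` matrix for
heatmaps. No live database queries are made; collections are supplied as
files so analyses stay hermetic and version-pinned.

## The synthetic generator

The generator emulates exactly the statistical structure the inference
assumes, and nothing more:

* **Sequences.** Mature miRNAs (20-24 nt, pairwise-distinct seeds),
  circRNAs (400 nt) and 3'UTRs (800 nt) over {A,C,G,U}. Planted triplets
  embed the reverse complement of the miRNA 2-8 seed: two sites in the
  circRNA (one spanning the back-splice junction) and one in the 3'UTR.
  All non-planted sequences are rejection-sampled (bounded at 1,000
  attempts) to contain no seed site for *any* generated miRNA, and planted
  targets are verified to carry exactly the requested sites for exactly
  the intended miRNA. Planting is therefore fully discoverable and the
  no-planting universe is provably site-free.
* **Counts.** Negative binomial with `variance = mean + dispersion·mean²`
  (dispersion 0 degenerates to Poisson). Defaults: baseline mean 500,
  dispersion 0.1 — a typical bulk RNA-seq biological CV of ~32%. DE
  features multiply their mean by `2^log2FC` in aging samples under both
  conditions (the aging effect is the planted contrast; no age x condition
  interaction is modelled, matching a two-contrast analysis). Planted
  effects default to +2 (circRNA, mRNA) and −2 (miRNA) log2 units,
  the sponge-derepression pattern.
* **Coupling.** Per (triplet, sample), a latent miRNA-activity factor
  `a ~ LogNormal(0, σ)` multiplies the circRNA and mRNA means and divides
  the miRNA mean, producing the positive circ-mRNA and negative miR-target
  correlations the scoring step looks for. The default σ = 0.5 is the
  "strong coupling" scenario: population circ-mRNA correlation ~0.87 and
  population S ~0.4, while the latent noise it adds to observed fold
  changes (SD ~0.7 in log2) still leaves the planted ±2 effect detectable
  at the fold-change ≥ 2 filter. Larger σ pushes correlations toward
  saturation (where S collapses, see above) and washes out DE; smaller σ
  weakens the correlation signature — σ was fixed once from these
  population calculations, not tuned on outcomes.
* **Universe sizes.** Defaults 100/50/200 (circ/miR/mRNA) with 5 planted
  triplets. Sizes were chosen so planted features cannot dominate
  per-class library sizes: with very small universes the planted features'
  latent swings distort the column sums and hence every other feature's
  normalised expression, an instructive composition artefact but not the
  property under test.

What the generator does **not** emulate: read-level sequencing, isoform
structure, batch effects, GC/length biases, cross-hybridising seed
families, or partial (wobble) sites. Passing recovery tests therefore
show that the inference chain is self-consistent — that it finds exactly
the structure it assumes — not that the assumptions hold in real tissue.

## Numerical and design choices

* Fisher P values come from `stats::fisher.test` (point-probability,
  two-sided); tests verify equality with exhaustive hypergeometric
  enumeration to 10^-12. BH comes from `stats::p.adjust`; hypergeometric
  enrichment from `stats::phyper` — all standard implementations behind
  the package's validated interfaces.
* Zero-variance expression vectors make Pearson correlation undefined;
  such triplets are dropped with a message rather than scored.
* Ties in DE tables are broken lexicographically by feature id; site
  tables sort by (target, start, type); node/edge tables by (class, id) —
  all outputs are byte-reproducible under a fixed seed.
* T/U are interchangeable on input; the internal alphabet is RNA.
* Problem sizes in the test-suite and calibration experiments (2,000
  null features x 10 seeds for the Fisher calibration; 20 recovery seeds;
  100 leakage seeds at a 30/20/60 universe) were chosen as the smallest
  sizes at which the Monte-Carlo standard errors are well below the
  margins being tested.

## Interpreting the packaged printed tables

The two packaged circRNA-miRNA tables reproduce the published networks'
circRNA layers (6 circRNAs / 6 unique miRNAs under control; 13 / 8 under
surgery) and are used as parsing and pairing fixtures. Their fold changes
and P values are taken as printed — the upstream read processing that
produced them is out of scope, so they are fixtures, not recomputation
targets.
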