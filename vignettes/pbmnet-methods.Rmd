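---
title: "From protein binding microarrays to a regulatory network: models and design choices"
author: "pbmnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From protein binding microarrays to a regulatory network: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A protein binding microarray (PBM) measures, in vitro, how strongly a
transcription factor (TF) binds every short DNA word: the TF is incubated on
a double-stranded oligonucleotide array and the fluorescence of each probe
reports occupancy. Translating those probe intensities into a list of target
*genes* requires several inferential steps, each of which this package
implements and tests:

1. **k-mer scoring** — summarise probe intensities into a per-word
   enrichment score (ES);
2. **promoter scanning** — map high-scoring words onto promoters to get a
   raw target tier (P);
3. **co-expression filtering** — retain targets whose co-expression
   neighbourhood is enriched for other targets of the same TF (P+COE);
4. **phylogenetic footprinting** — flag binding sites falling in promoter
   regions conserved across related species, with an empirical resampling
   FDR (conserved P+COE);
5. **network assembly** — combine all TFs' target tiers into a regulatory
   network annotated with functional-module enrichments mapped to ten
   GO-slim categories.

## The enrichment score

For a word $w$ (8 informative positions, optionally split by one internal
run of up to three wildcard Ns) the probes are divided into a foreground
$F$ (probes containing $w$ or its reverse complement — the array is
double-stranded, so matching is always strand-symmetric) and background
$B$. The score is the rescaled Mann–Whitney statistic

$$\mathrm{ES}(w) \;=\; \frac{U}{|F|\,|B|} - \tfrac12,\qquad
U = \#\{(f,b): I_f > I_b\} + \tfrac12\,\#\{(f,b): I_f = I_b\},$$

which lies in $[-0.5, +0.5]$: $+0.5$ means every foreground probe outranks
every background probe. The original assay literature computes its ES from
truncated ranked probe lists; the exact formula is not printed anywhere we
could verify, so we adopt the rank-AUC form above, which shares the range
and the threshold conventions (significance at $\mathrm{ES} \ge 0.40$,
promoter-scanning seeds at $\mathrm{ES} > 0.45$). Exactness is guaranteed by
tests against a brute-force pair-enumeration oracle, and
$\mathrm{ES}(w) = \mathrm{ES}(\bar w)$ holds identically by construction.

**Minimum foreground.** `score_all_patterns()` omits words observed in
fewer than `min_foreground = 8` probes. The null spread of a rank-AUC score
is roughly $1/\sqrt{12\,n_F}$, so a word seen once or twice can reach
$\pm 0.5$ by chance; commercial all-k-mer designs guarantee every word many
occurrences, and the filter restores that guarantee's effect at desk scale.
`enrichment_score()` (the single-word operation) applies no such filter.

## Core words, fingerprints, PWMs, clustering

Significant words are summarised three ways. *Core words* (ungapped 6-mers
and 7-mers with one internal N) are selected by a greedy cover: candidates
are all such subwords of the significant words, scored by their best per-TF
median ES; the cover repeatedly takes the candidate covering the most
uncovered significant words, breaking ties by score and then
lexicographically. Published core-word selections combine a preferred-k-mer
statistic with visual curation and are not reproducible from their
descriptions; the greedy cover is our deterministic surrogate and is
flagged as such. *Fingerprints* are
boxplot statistics (type-7 quartiles, whiskers at the last point within
1.5×IQR) of the ES of significant words containing each core word.
*Position weight matrices* align the top-n ungapped words to the top-1 seed
by best-overlap offset (≥ 6 overlapping positions, either orientation) and
accumulate ES-weighted base counts with a 0.01 pseudocount.

The word × TF specificity matrix is biclustered with
`stats::hclust` (average linkage; Euclidean distance for words,
1 − Pearson for TFs; both configurable). The figure source names only the
plotting software, so the metric/linkage choice is ours; missing cells
(word never observed for a TF) are imputed as ES 0 — the absence of
enrichment — for distance computation only.

## Promoters and tier P

A promoter is the up-to-1000 bp region immediately upstream of the
annotated gene start, truncated when the nearest annotated gene boundary on
either strand is closer, and at chromosome edges. We anchor at the gene
feature, not a transcript TSS, and truncate on the nearest boundary
regardless of the neighbour's strand — the source rule names only "the
adjacent upstream gene". Promoters that are mostly N are dropped with a
message. Scanning reports every (possibly overlapping) offset of every seed
word on both strands; a gene with at least one hit enters tier P. By
default the seed set includes gapped words (configurable), since nothing in
the rule restricts it to ungapped ones.

## Co-expression filter (tier P+COE)

For each compendium, each gene's co-expression cluster is its top-`n`
neighbours by Pearson correlation (at genome scale the convention is the
top-100 of roughly 22k genes, and that is the default).
A tier-P target is retained when, in at least one compendium, its cluster
is enriched for tier-P targets of the same TF at hypergeometric
$p < 0.05$ (raw, as the source states; a Benjamini–Hochberg option exists
but is off by default). The "at least one compendium" rule is our reading
of an ambiguous pooling description; "all" and "majority" are available.
The neighbourhood size must scale with the universe: at the desk-scale 150
genes used in tests we take top-15, since a top-100 neighbourhood spanning
two thirds of the universe has no discriminating power.

## Phylogenetic footprinting and the empirical FDR

Orthologous promoters are aligned to the query by an iterative masked local
aligner: the best Smith–Waterman alignment (match +1, mismatch −1, gap open
−2, gap extend −1) is decomposed into gap-free segments; each segment's
maximal-scoring sub-run is kept as a block if it is ≥ 8 bp and ≥ 70%
identical; the aligned region is masked and the search repeats while the
alignment score reaches `min_score = 20`. This stands in for the dedicated
promoter-alignment tools of genome-scale footprinting studies, whose
scoring parameters are unpublished; the contract it preserves is
"non-overlapping gap-free local blocks". The score threshold was set from
the Karlin–Altschul expectation for 1 kb random pairs (expected optimal
local score ≈ 12.5 under this scoring): at 20 a random pair rarely yields
any block, while a 40 bp window at 5% divergence scores far above the
threshold and is recovered reliably (the test suite checks both sides on
randomized and planted inputs).

Per-nucleotide support counts the species whose blocks cover each query
position; footprints are maximal runs with support ≥ c for each level c.
Significance is empirical: 1000 null samples (tests use 100–200) redraw one
non-orthologous promoter per species, rerun align→aggregate→extract, and a
null sample beats an observed footprint if it contains a footprint with at
least the observed support *and* length — the operational reading of
"similar or better conservation", which the source does not define. The
footprint FDR is the beaten fraction; a hit is *conserved* when its
interval lies entirely inside an FDR < 5% footprint.

Published descriptions leave ambiguous whether the FDR applies per
footprint or per gene; we expose both (`footprints$fdr` and
`gene_fdr = min`). A known property of
the per-gene summary: on fully random promoters long enough to carry
several nested footprints, taking the minimum of their FDRs is a multiple
dependent test and can roughly double the nominal per-gene false-positive
rate. At the desk-scale genome's average promoter length the calibration
test bounds the rate at 0.07.

## Network and functional modules

All P+COE targets of all TFs become TF→gene edges, each flagged if its
binding site is conserved. Per TF, functional modules are tested for target
enrichment (hypergeometric, raw p < 0.05); the GO terms of enriched modules
are propagated to ancestors through a user-supplied parent map, intersected
with the GO-slim vocabulary, and mapped to the ten functional categories
shipped in `go_slim_categories()` (tropism; cellular homeostasis; stress,
cell death and signalling; transport; signal transduction and response to
endogenous stimulus; catabolic process; energy, lipid, carbohydrate and
secondary metabolism; cell cycle; translation and protein metabolism;
growth, reproduction and development). Modules are partitioned by whether
five or more TFs target them. Curated-interaction recovery restricts its
denominator to TFs present in the network. The perturbation analysis
clusters the focal TF and its candidate targets across conditions
(Euclidean, average linkage) and partitions targets by the sign of their
correlation with the focal profile.

## The synthetic-data generator

No raw inputs are redistributable, so every stage is exercised on seeded
synthetic data with planted ground truth.

* **PBM** (`simulate_pbm`): a de Bruijn backbone covering every ungapped
  6-mer is chopped into overlapping 30 bp probes and topped up with random
  probes (2000 total, two replicates). Each TF has an 8-mer consensus
  (defaults TTGCGTAA, TACGTCAA, TTACTTGC — one word per specificity group
  the assay family distinguishes) extended by two preferred flanking bases
  per side. Twenty coverage probes per TF carry the planted site (flanks
  resampled at 0.6), emulating the array's guaranteed word coverage;
  intensity is `(baseline + amplitude * s) * exp(N(0, 0.25))` with `s` the
  best relative PWM score over both strands (core positions 0.95, flanks
  0.6). The flank sharing is what creates a realistic *family* of
  significant words per TF rather than a single word.
* **Genome** (`simulate_genome`): tandem genes on one chromosome, intergenic
  gaps from a short/long mixture so some promoters truncate; true targets
  (10% of genes per TF) get one planted extended-consensus copy at a random
  promoter offset and strand.
* **Expression** (`simulate_expression`): per compendium a latent activity
  per TF; targets load on it with effect 1.5 and sign (+ with probability
  0.8 — perturbation compendia are typically activator-dominated),
  background is unit noise; DE sets are targets passing a 2-fold simulated
  contrast. Note the sign split is why repressed targets are the hardest
  for the co-expression filter.
* **Orthologs** (`simulate_orthologs`): target promoters diverge at 0.35
  substitutions/site except a 40 bp window around the planted site at 0.05;
  non-target genes get fresh composition-matched sequence (fully null).
* **Modules** (`simulate_modules`): some modules are drawn 80% from one
  TF's targets, the rest at random; GO labels are slim terms or children of
  slim terms through an emitted parent map.

What the generator does *not* emulate: probe position and sequence biases,
replicate-specific spatial artifacts, transcript isoform structure,
overlapping genes, indel evolution in promoters, batch structure in
compendia, and the breadth of a real GO graph. Passing tests therefore
demonstrate correctness of the machinery and calibration of its statistics
under the stated generative model, not performance on Arabidopsis data.

## Problem sizes and determinism

Integration tests and the acceptance script run at desk scale: 150 genes
(50–120 for repeated-seed suites), 4 species, 2 compendia × 30 samples,
2000 probes (1000–1500 in repeated-seed suites), 40–200 resampling draws,
top-15 neighbourhoods. These sizes were chosen once as the smallest at
which every planted effect is comfortably detectable. All generators and
the pipeline are pure functions of their seed; `run_pipeline()` writes a
manifest with the config echo and the md5 of every artifact, and re-running
a configuration reproduces byte-identical outputs (sorting uses radix order
throughout to stay locale-independent).

## Known limitations

* The ES is a stand-in for the truncated-list variants used with
  commercial arrays; absolute values are comparable only within this
  package.
* The greedy core-word cover reproduces the *role* of curated core-word
  lists, not any particular published list.
* Pattern matching treats N in a sequence as unmatchable; promoters more
  than half N are dropped.
* The aligner is not phylogeny-aware: each species contributes
  independently, and deep species trees would overcount correlated
  lineages.
* `design_switch_site()` searches substitution neighbourhoods only
  (insertions and deletions are out of scope for a fixed-length element)
  and scores variants by table lookup, so words absent from the enrichment
  table score 0.
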