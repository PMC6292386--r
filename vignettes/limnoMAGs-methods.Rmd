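---
title: "Methods: genome-resolved biogeochemistry of stratified lakes"
author: "limnoMAGs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-resolved biogeochemistry of stratified lakes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limnoMAGs)
```

## What this package models

limnoMAGs analyses genome-resolved metagenomic time series from stratified
lakes: a large eutrophic lake sampled in its epilimnion (`mendota_epi`), and
a small humic bog lake sampled separately in its epilimnion
(`troutbog_epi`) and hypolimnion (`troutbog_hypo`). The computational
pipeline takes tabular outputs of standard upstream tools as inputs — IMG
style per-gene functional annotations, CheckM-style completeness and
contamination estimates, BLAST tabular homology hits, dbCAN-style CAZyme
annotations, read-mapping coverage tables — and implements five analysis
arms:

1. **MAG quality control and deduplication.** Metagenome-assembled genomes
   (MAGs) are retained when estimated completeness is at least 50% and
   contamination is strictly below 10%, the medium/high-quality draft
   criterion. Bins assembled independently from different thermal layers can
   represent one population; pairs with average nucleotide identity (ANI)
   above 99% are linked, and populations are the connected components of
   that graph (single linkage, because the ANI table only flags pairs). The
   default threshold is 99%, with the looser 97% convention selectable via
   the `threshold` argument — both conventions circulate and neither is
   endorsed by the package.
2. **Pathway presence calling.** A pathway, defined as a list of enzymatic
   steps each carrying annotation-id synonyms across KEGG orthologs, COG,
   PFAM and TIGRFAM, is called *present* in a MAG when at least 50% of its
   steps are covered (inclusive) and every step flagged *unique*
   (diagnostic) is covered. A step is covered when any synonym appears among
   the MAG's annotations; multi-copy genes count once, because the rule is
   about presence, not dosage. Unique steps also count toward the
   completeness fraction — they are steps of the pathway. Calls are
   aggregated by site and *effective phylum*: Proteobacteria are keyed by
   class because the phylum spans too much metabolic diversity to be one
   group.
3. **Functional marker gene survey.** ORF-vs-marker homology hits from
   unassembled reads are filtered at 30% identity (inclusive) and reduced to
   the best hit per ORF (highest bitscore, ties to the lexicographically
   smallest subject), so related markers of one family never double-count an
   ORF. Counts are aggregated by function category and normalized to hits
   per million reads; per-million is conventional and dimensionless, and a
   base-pair denominator is available behind `perBasePair`. Two site pairs
   are contrasted with two-sided Wilcoxon rank-sum tests — the two
   epilimnia, and the two bog layers; the cross-lake epi-vs-hypo contrast is
   deliberately never run because it confounds lake and depth. Bonferroni
   correction spans the full family actually tested (categories × 2 pairs),
   the most conservative plain reading; direction is reported by the larger
   median, consistent with a rank-based test.
4. **Glycoside hydrolase (GH) metrics.** GH coding density is the
   percentage of a MAG's genes annotated as a GH; diversity is the number
   of distinct GH families (subfamilies such as `GH13_10` collapse to
   `GH13` by default). Their association is summarised by a Pearson
   correlation (r² with the t-transform p-value), matching the r² language
   customary for this relation. Non-GH CAZyme classes are parsed and
   ignored.
5. **Time-series linkage.** MAG abundance is read coverage normalized by
   genome length and metagenome size (per gigabase; metagenome size is
   `read_count × 150` bp when base counts are absent, matching 150 bp
   reads). The dominant MAG of a group in a year is the member with the
   highest within-year mean coverage — a mean over the season is stable, and
   a dominance ratio (top/runner-up) is reported for transparency.
   Nitrogenase marker series (the three Mo–Fe subunit markers pooled as one
   "nitrogen fixation" category) are correlated with the dominant MAG's
   coverage by Pearson on inner-joined dates (raw scale by default;
   `log1p` and Spearman are available as flags).

## The synthetic-data generator

Real inputs at study scale live in public archives and are too large to
ship, so the package includes generators that plant known structure and let
every stage be tested offline. Their defaults *are* the emulated study
conditions and are not tuning knobs:

- `simulateMags()`: 99 + 31 + 63 MAGs across the three sites, completeness
  drawn uniformly on 50–99%, a freshwater-typical taxon mix with
  Proteobacteria carried at class rank. Each planted pathway contributes
  one gene per step; every gene is then dropped independently with
  probability 1 − completeness. This i.i.d. dropout is the simplest
  mechanism that erodes pathway calls the way real partial bins do.
  Contamination adds `Binomial(100, rate)` foreign annotations per MAG from
  catalog ids outside the planted set.
- `simulateMarkerHits()`: hit counts per (metagenome, category) are
  negative-binomial with mean `baseRate × read_count × site effect` and
  size `nbDispersion = 5`; overdispersed counts are the standard null for
  metagenomic hit counts and give the rank-sum comparison realistic noise.
  Identities are uniform on [30, 100] with a configurable fraction of
  sub-threshold decoys on [10, 30) to exercise the cutoff.
- `simulateTimeseries()`: five years of 19 samples (94 metagenomes, the
  Mendota design), one Cyanobacteria MAG per year following a Gaussian
  bloom (random mid-season peak, σ = 30 days, amplitude 10) in its year and
  a flat 0.05 baseline elsewhere. Nitrogenase counts couple only to
  diazotroph coverage (`copyFactor` hits per million per coverage unit),
  so years whose dominant MAG is a planted diazotroph (2008, 2011, 2012 by
  default) — and only those — carry a bloom-shaped marker signal. The flat
  off-year baseline is what makes the planted-null years genuinely null;
  giving off-year populations small blooms instead would manufacture
  spurious seasonal correlations that say nothing about the method.
- `simulateCazymeAnnotations()`: a lognormal degradation propensity sets
  each MAG's GH family repertoire (Poisson, drawn from a 130-family pool);
  each family carries 1 + negative-binomial gene copies. Genomes gain GH
  breadth mainly by acquiring families, so density and diversity are
  strongly positively coupled by construction — the generator emulates the
  existence of that coupling, not any particular published coefficient.

What the generators deliberately do **not** emulate: phylogenetic sequence
evolution, assembly and binning artefacts, compositionality of coverage,
uneven annotation quality across taxa, and within-year succession beyond a
single bloom. Green tests on synthetic data therefore demonstrate that the
statistical machinery behaves as specified under its stated assumptions,
not that those assumptions hold in any particular lake.

## Numerical and design choices

- **Boundary semantics** are fixed once: completeness ≥ 50 and
  contamination < 10 ("at least" vs "less than"); pathway completeness
  ≥ 0.5 inclusive; identity cutoff ≥ 30 inclusive.
- **Rank-sum mechanics**: exact null enumeration when the smaller group has
  ≤ 8 observations and there are no ties; otherwise the normal
  approximation with tie and continuity corrections. The implementation
  delegates to `stats::wilcox.test`, which computes exactly these branches;
  the test suite checks the exact branch against an independent enumeration
  of all rank splits for every group size up to 6.
- **Nitrogen per residue** counts full-molecule nitrogen (backbone amide
  plus side chain): 14 residues carry 1, N/Q/K/W carry 2, H 3, R 4; `X`
  contributes the unweighted 20-residue mean 29/20; stops are ignored.
  Peptide-bond water loss does not move any nitrogen, so the question of
  residue vs free-molecule formulas is moot for this element.
- **Ties** break lexicographically everywhere (best hit subject, dominant
  MAG, population representative after completeness and contamination), so
  all outputs are permutation-invariant.
- **Degenerate inputs** error loudly rather than returning NaN: empty
  proteomes, constant correlation inputs, fewer than three shared dates,
  empty rank-sum groups.
- **Matrix output** is written at 17 significant digits so that write/read
  round-trips are bit-exact.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic data at
the emulated design scale: 193 MAGs for QC, pathway and GH checks; 47
metagenomes per contrasted site with 100 seeded replicates for the
planted-effect power check; 500 null replicates for type-I calibration;
10,000 draws for negative-binomial calibration; 50 seeded replicates of the
five-year bloom series for the correlation-pattern check. These sizes were
chosen to keep Monte-Carlo error comfortably below the margins being
asserted.

## A worked example

```{r example}
cfg <- simConfig(seed = 1)
sim <- simulateMags(cfg)
qc <- qcFilter(sim$mags)
table(qc$site)

pm <- callAll(sim$annotations, demoPathwayCatalog(), magIds = qc$mag_id)
head(aggregatePresence(pm, qc))
```

## Known limitations

- The shipped pathway catalog is a small demonstration set; real analyses
  should supply a curated catalog in the same YAML schema. How the original
  curation weighted KEGG vs MetaCyc definitions when both cover a pathway
  is not reconstructible from the sources this package follows; the format
  therefore forces one merged definition per pathway and records provenance
  as free text.
- Whether a marker survey should count all passing hits or best-hit-per-ORF
  is a genuine methodological fork; best-hit is the default and the
  alternative sits behind `bestHitOnly = FALSE`.
- The GH density denominator is the MAG's total gene count as given in its
  metadata; no attempt is made to exclude RNA genes.
- Population grouping by single linkage can chain distinct populations
  through intermediates; the dominance of pairwise ANI tables makes this
  the least-assumption closure, but representatives should be inspected
  when chains are long.
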