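---
title: "Identifying enhancer CpG islands and their tumorigenic hypermethylation"
author: "ecgi package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying enhancer CpG islands and their tumorigenic hypermethylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

About half of human CpG islands (CGIs) sit at protein-coding promoters;
the rest — orphan CGIs — are intergenic or intragenic, and a subset of
them carries the chromatin signature of active enhancers (open chromatin
by DNase I hypersensitivity, H3K27ac) while producing no transcript of
its own. This package implements a complete, testable workflow for
identifying these *enhancer CGIs* (eCGIs), assigning their target genes
through chromatin interactions, and quantifying what happens to them in
tumors: focal hypermethylation, loss of enhancer marks, and silencing of
their targets (which are enriched for transcription regulators and tumor
suppressors).

Everything is exercised end to end on synthetic data with planted ground
truth, because the workflow's correctness — not any particular public
dataset — is what the package establishes.

## The classification model

Each CGI receives exactly one of four labels by a fixed decision cascade:

1. **pCGI** — overlaps the promoter window (TSS ± 1 kb, strand-aware) of a
   protein-coding gene (refGene ids starting with "NM"). Promoter status
   trumps everything else.
2. **orphan_inactive** — otherwise, if the CGI does *not* overlap both an
   H3K27ac peak and a DHS peak. Activity requires both marks.
3. **npCGI** — an active orphan overlapping transcription-start evidence:
   a CAGE-derived TSS interval, or a de-novo transcript TSS expanded by
   the same ±1 kb window.
4. **eCGI** — an active orphan with no transcription-start evidence.

*Typical enhancers* are the comparison class: H3K27ac-harboring DHS peaks
(anchored on the DHS coordinates) overlapping no CGI and no
transcription-start evidence.

Design choices made where the definition was genuinely open:

- **Coordinates** are 0-based half-open (BED convention) everywhere
  internally; one convention end to end avoids off-by-one drift across
  six data layers. "Overlap" means at least one shared base — no minimum
  fraction is imposed.
- **"Within 1 kb of the TSS"** is a symmetric window `[tss − 1000,
  tss + 1000]` (so the interval `[tss−1000, tss+1001)` half-open), not
  upstream-only.
- De-novo transcript TSSs get the same ±1 kb promoter window as annotated
  genes; CAGE intervals are used as given (they already delimit the TSS
  region).
- Only coding ("NM") gene promoters define pCGIs; noncoding ("NR")
  promoters do not remove a CGI from the orphan pool. The cascade order
  (promoter > activity > transcript evidence) is normative.
- Chromosome names are matched verbatim.

## Target assignment and interaction statistics

Chromatin-interaction links (two anchors plus a tag count, BEDPE-like)
are filtered to tag count ≥ 3, the conventional threshold for significant
Pol2 ChIA-PET interactions. A region targets a gene when some filtered
link has one anchor overlapping the region and the other anchor
overlapping the gene's promoter window; anchors are interchangeable.
Multiple supporting links aggregate per (region, gene) pair by the
maximum tag count (sum available via `agg = "sum"`). When no interactome
is available (as for a cell type without ChIA-PET data), the nearest gene
by TSS-to-midpoint distance is the documented fallback.

Interaction strength between eCGI-promoter pairs and typical-enhancer
promoter pairs is compared with a **two-sample rank-sum (Mann-Whitney)
test**, not a signed-rank test: the two sets of pairs are unpaired
samples, so the rank-sum form is the statistically valid choice; a paired
signed-rank variant remains available (`paired = TRUE`) for genuinely
matched designs. Both rank tests are implemented with exact small-sample
null distributions — full enumeration of group assignments for the
rank-sum test (both n ≤ 10), sign-assignment convolution for the
signed-rank test (n ≤ 25) — handling ties exactly via midranks, and a
tie-corrected normal approximation with continuity correction beyond
that. `stats::wilcox.test` serves as an independent cross-check in the
test suite, never as the implementation.

## Enrichment tests

**Regulator permutation test.** The observed statistic is the number of
distinct transcription-regulator genes contacted by the region set
through filtered links. Each of `n_perm` permutations (default 1000)
replaces the regions with random DNA segments — chromosome- and
length-matched, a normative strengthening of "the same number of random
segments" that preserves the test's validity (count-only matching is
available via `length_matched = FALSE`) — and recounts. The empirical
p-value uses the add-one convention `p = (1 + #{null ≥ obs}) / (1 +
n_perm)`, so p is never zero and is reproducible bit-exactly given the
seed. Counting distinct regulator genes (rather than link events) matches
the "number of transcription regulators" readout; a link-count mode is
behind `statistic = "links"`.

**Fisher's exact test.** TSG/oncogene enrichment of hyper-eCGI targets
uses the hypergeometric two-sided exact test, implemented by direct
point-probability summation (probabilities ≤ the observed table's, with
the usual 1 + 1e-7 relative tolerance on the comparison); the odds ratio
reported is the sample cross-product (a·d)/(b·c). The regulator/TSG/
oncogene universes are input gene lists — the workflow does not recompute
them.

## Methylation model

Per-CpG differential methylation is `dm = beta_tumor − beta_normal` over
CpGs present with non-missing betas in both conditions (450K-style: one
value per CpG site, strand-collapsed upstream; missing betas drop the
site from that contrast only). Region-level hypermethylation uses the
**mean** dm of contained CpGs — the any-CpG alternative is provided
behind `mode = "any_cpg"` but the mean is the default for robustness —
with a **strict** threshold (`mean_dm > 0.5` for cell-line contrasts,
`> 0.1` for clinical group-mean contrasts, where betas per condition are
group means). Selection is monotone in the threshold by construction.

Target silencing is measured as `(expr_tumor + 0.1) / (expr_normal +
0.1)` per target gene (the 0.1 RPKM pseudocount guards zero
denominators), with a one-sample signed-rank test that log folds lie
below zero and a two-sample contrast against targets exclusive to
non-hypermethylated regions. Enhancer-mark loss at hypermethylated eCGIs
is a paired signed-rank test on per-region coverage deltas.

## Signal metaprofiles

Metaprofiles average bp-weighted coverage in `n_bins` equal bins over
`[center − flank, center + flank)` windows, then across regions. The
defaults (flank 5 kb, 200 bins = 50 bp resolution) match the visual
resolution of the genre's figures; no bin width is canonical. The region
center is `floor((start + end)/2)` — even-length regions have no true
center, so flooring is fixed normatively. Windows clipped at chromosome
start contribute only their defined bases. Raw coverage is averaged; no
peak normalization or fragment smoothing is applied. `2·flank` must be a
multiple of `n_bins` so that bins align with whole bases, which is what
makes the per-bp materialization oracle an exact check (tolerance 1e-9,
pure floating-point accumulation error).

## The synthetic cohort

`generate_dataset()` emits every input layer, mutually consistent with
planted labels under the cascade, plus a machine-readable ground-truth
manifest. The defaults are the study conditions the workflow is designed
around:

| parameter | default | rationale |
|---|---|---|
| genome | 3 × 10 Mb | non-degenerate segment permutation, seconds-scale tests |
| genes / CGIs / typical enhancers | 300 / 500 / 150 | desk-scale but statistically useful |
| class mix | .50/.15/.20/.15 (pCGI/npCGI/eCGI/inactive) | ~half of CGIs are promoter CGIs; the active-orphan share is scaled up from the single-digit percentages seen genome-wide so every downstream contrast has power at this scale |
| multi-target eCGI fraction | 0.6 | eCGIs contact multiple genes |
| regulator link preference | 3× | planted regulator targeting |
| tag-count shift | +2 | eCGI interactions are stronger |
| hyper eCGIs | 30, planted dm 0.6, CpG noise sd 0.05 | clearly above the 0.5 threshold, realistic array noise |
| silencing fold | 3×, log-normal noise sd 0.3 (log2) | conventional RNA-seq abundance noise model |
| CpGs | 25 per CGI + 1/100 bp background (outside CGIs) | island density vs genomic background |
| TSG preference for silenced genes | 3× | planted tumor-suppressor enrichment |

Placement uses disjoint 30-kb cells, one feature per cell (pCGIs share
their host gene's cell), each feature confined to the central third of
its cell. Any two features on a chromosome are therefore > 9 kb apart,
which makes the planted classes identifiable *by construction* when
noise-free: that is what licenses the 100%-recovery acceptance checks.
Class counts are apportioned deterministically from the mix by largest
remainder, so configured class sizes are exact. Background CpGs are
excluded from CGI spans so they cannot dilute region-level dm.
Sub-threshold noise links (tag counts 1–2) are planted to exercise the
filter; background peaks carry only one mark each so the planted typical
enhancers are the exact positive set.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: realistic sequence composition (no sequences
are generated; `sequence_stats()` exists for characterizing real
catalogues), overlapping or nested genes, peak-width and signal
heterogeneity beyond uniform draws, inter-chromosomal contact structure,
copy-number or purity effects on betas, and replicate-level biological
variance. Classification noise is modeled only as independent peak
dropout.

## Numerical and testing choices

- Exact rank-test paths switch to tie-corrected normal approximations at
  n > 10 per group (rank-sum) / n > 25 (signed-rank); all-zero deltas
  yield a degenerate flag with p = 1.
- The permutation test's null calibration is checked on a genome where
  link anchors are placed uniformly at random and the region set is
  redrawn per replicate — the construction under which observed and null
  counts share one distribution. Fixture sizes (200 genes, 400 links, 100
  × 2 kb regions on 2 × 1 Mb) are chosen so the count statistic is
  well-resolved; with a coarsely discrete statistic the empirical p-value
  is lumpy for reasons unrelated to correctness.
- Problem sizes in the test suite (e.g. 200 random fixtures × 1000 CGIs
  for the cascade oracle, 500 calibration replicates at 199 permutations,
  100 power replicates) are the package's chosen desk-scale study
  conditions; they complete in minutes on one CPU.
- Known limitations: coverage readers assume non-overlapping bedGraph
  segments per chromosome; no BAM/bigWig input; the nearest-gene fallback
  ignores interaction evidence entirely; Fisher universes must be
  supplied, not derived.

## Running the workflow

The numbered drivers under `analysis/` run the whole study on the
simulated cohort and narrate their findings:

```sh
Rscript analysis/01_simulate.R     # synthetic cohort + ground truth
Rscript analysis/02_classify.R     # CGI classes, typical enhancers
Rscript analysis/03_profiles.R     # DHS/H3K27ac metaprofiles
Rscript analysis/04_targets.R      # ChIA-PET targets, strength, folds
Rscript analysis/05_enrichment.R   # regulator permutation test
Rscript analysis/06_methylation.R  # hypermethylation and silencing
```

All tables land under `results/`. `run_pipeline()` performs the same
stages programmatically on any dataset in the documented formats.
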