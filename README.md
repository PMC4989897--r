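# ecgi — enhancer CpG islands and their tumorigenic hypermethylation

Roughly half of human CpG islands (CGIs) lie away from protein-coding
promoters. A subset of these *orphan* CGIs carries the chromatin
signature of active enhancers — DNase I hypersensitivity plus H3K27ac —
while producing no transcript of its own. `ecgi` is an R package, plus a
numbered analysis workflow, for scientists studying these **enhancer CpG
islands (eCGIs)**: it classifies a CGI catalogue, assigns enhancer target
genes from ChIA-PET chromatin interactions, tests regulator and
tumor-suppressor enrichment, and quantifies tumor hypermethylation of
eCGIs together with silencing of their targets.

## The method in brief

Each CGI gets exactly one label by a fixed cascade over the evidence
tracks:

```
overlaps coding-gene promoter (TSS ± 1 kb)      ─► pCGI
else not (H3K27ac peak AND DHS peak)            ─► orphan_inactive
else overlaps CAGE TSS or de-novo TSS window    ─► npCGI
else                                            ─► eCGI
```

Typical enhancers (the comparison class) are H3K27ac-harboring DHS peaks
overlapping no CGI and no TSS evidence. Downstream:

- **Targets** — a region targets gene *G* when a filtered link
  (tag count ≥ 3) has one anchor in the region and the other in *G*'s
  promoter window; anchors are interchangeable.
- **Regulator enrichment** — observed count of distinct regulator genes
  contacted vs. 1000 sets of chromosome/length-matched random segments;
  empirical p with add-one smoothing, p = (1 + #{null ≥ obs})/(1 + n).
- **Interaction strength / methylation contrasts** — exact small-sample
  rank tests (Mann-Whitney for unpaired classes, Wilcoxon signed-rank for
  paired deltas), tie-corrected normal approximation at larger n.
- **Hypermethylation** — per-CpG dm = β_tumor − β_normal; a region is
  hypermethylated when its mean dm strictly exceeds 0.5 (cell lines) or
  0.1 (clinical group means). Target silencing is the fold change
  (expr_tumor + 0.1)/(expr_normal + 0.1) with a one-sided signed-rank
  test; TSG/oncogene enrichment is Fisher's exact test.

A synthetic-data generator (`generate_dataset()`) emits every input layer
with planted ground truth — class labels, eCGI→gene links, hyper-eCGIs,
silenced genes — so the full workflow is testable offline. See the
vignette (`vignettes/ecgi-workflow.Rmd`) for the model, parameter
defaults and limitations.

## Worked example

```sh
Rscript analysis/01_simulate.R && Rscript analysis/02_classify.R
```

prints

```
Simulated cohort written to results/synthetic
  CGIs: 500 (eCGI=100, npCGI=75, orphan_inactive=75, pCGI=250)
  ChIA-PET links: 422 (372 with tag count >= 3)
  CpGs with betas: 307106; hyper eCGIs planted: 30
CGI classes: pCGI=250, npCGI=75, eCGI=100, orphan_inactive=75
Agreement with planted labels: 100.0%
Typical enhancers called: 150
K562-specific: 76.5% of 1134 eCGIs; Mcf7-specific: 56.9% of 619
```

i.e. the classifier recovers every planted label on the noise-free
cohort, calls exactly the planted typical enhancers, and the worked set
arithmetic on the published K562/Mcf7 eCGI counts (867 and 352 specific,
267 common) gives the 76.5% / 56.9% specificity figures. Continuing,

```sh
Rscript analysis/04_targets.R && Rscript analysis/05_enrichment.R \
  && Rscript analysis/06_methylation.R
```

```
Multi-target fraction: eCGIs 0.63 vs typical enhancers 0.44
Interaction strength (tag counts) eCGI > typical: p = 1.64e-33
Regulators contacted by eCGIs: 43 observed vs 0.64 expected by chance
Permutation p (greater, 1000 permutations): 0.000999
Hypermethylated eCGIs (mean dm > 0.5): 30
Target silencing: median tumor/normal fold 0.36, signed-rank p = 1.23e-10
Signal loss at hyper eCGIs: DHS p = 9.13e-07, H3K27ac p = 9.13e-07
Fisher enrichment of targets: TSG p = 0.0373, oncogene p = 1
```

Read: eCGIs contact more genes with stronger interactions than typical
enhancers; they contact far more transcription regulators than random
segments do; exactly the 30 planted hypermethylated eCGIs are recovered
at the 0.5 threshold; their targets drop to about a third of their
normal expression (3× silencing was planted) with concomitant loss of
both enhancer marks; and the silenced targets are enriched among tumor
suppressors but not oncogenes.

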