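# ernalink

An R package and analysis workflow for integrative regulatory genomics of
innate immune activation in human monocytes. The study design it targets
profiles chromatin accessibility (ATAC-seq) and the transcriptome across
six donors and five activation states — untreated (UT), acute endotoxin
(LPS2), endotoxin tolerance by repeated (LPS6/6) or prolonged (LPS24)
exposure, and interferon-γ (IFNG) — and asks which open-chromatin regions
respond to stimulation, whether responsive regions behave like enhancers
(distal location, enhancer RNA output, reduced sequence conservation), and
which genes those enhancers regulate.

## What the package computes

- **Recurrent (consensus) ATAC peaks** — per-sample peak calls are
  filtered (call p ≤ 1e−5, ENCODE-style blacklist), clustered across
  samples by single-linkage ≥ 1 bp overlap, and kept when called in ≥ 30%
  of samples; the consensus interval is the union of the cluster.
- **Differential count testing** — a deliberately simplified
  negative-binomial pipeline: median-of-ratios size factors, per-feature
  method-of-moments dispersion shrunk 50/50 toward a 1/μ trend, an NB
  log-linear model with condition and donor fixed effects
  (`~ Treatment + Donor`), and a two-sided Wald test. Differential calls
  use strict thresholds: |log2FC| > log2(1.5) for ATAC, > 1 for genes and
  eRNAs, with BH FDR < 0.05.
- **Distal/proximal annotation and conservation** — a peak is distal when
  its midpoint lies > 3 kb from the nearest TSS; distal over-representation
  of differential peaks is tested with a two-tailed Fisher exact test, and
  phyloP-style conservation is profiled in 10-bp bins over midpoint ± 1 kb
  (200 bins).
- **Enhancer RNA (eRNA)** — each consensus-peak midpoint ± 1 kb window
  that avoids expressed-gene boundaries (max TPM ≥ 0.5, padded ± 3 kb)
  is quantified from RNA fragments, kept at max CPM ≥ 1, tested for
  differential expression, and its log2FC correlated (Pearson) with the
  source peak's ATAC log2FC.
- **eQTL linking** — each peak is linked to at most one eGene through the
  most significant in-peak eQTL (p < 1e−5) across conditions; lead eQTLs
  of a focal stimulation are tested for enrichment among
  differential-peak/DE-gene links of that stimulation against leads of a
  comparison condition, using a two-tailed Fisher exact test with a
  conditional maximum-likelihood odds ratio (the noncentral hypergeometric
  ψ solving E[X | ψ, margins] = a, found in log space so tables with
  margins in the tens of thousands do not underflow).

The raw data of such studies sit under managed access, so the package
ships a seeded simulator (`simulation_spec()`, `simulate_study()`) that
reproduces the design — NB counts with planted condition effects and donor
factors, jittered per-sample peak calls with a detection probability,
center-peaked conservation with lower amplitude at differential peaks,
correlated eRNA effects, and context-specific eQTL credible sets — plus
truth tables, so every stage is validated by parameter recovery.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
simulated study (2,000 genes, 2,000 peaks, seed 1) and write their tables
under `results/`:

```sh
Rscript analysis/01_simulate.R 1
Rscript analysis/02_consensus_peaks.R
Rscript analysis/03_differential.R
Rscript analysis/04_annotation_conservation.R
Rscript analysis/05_erna.R
Rscript analysis/06_eqtl_linking.R
```

Output printed by the run above:

```
simulated 2000 genes, 2000 peaks (400 differential, 50% distal), 6624 eQTL records; seed 1
88108 of 94399 filtered calls -> 1672 consensus peaks (support >= 18)
ATAC IFNG vs UT: 79 differential of 1672 tested
...
distal: 61.9% of differential vs 45.1% of non-differential peaks (p = 3.46e-08, OR = 1.98)
809 eRNA regions; 56.5% expressed at max CPM >= 1
eRNA vs ATAC log2FC over 102 differential-eRNA pairs: r = 0.681 (p = 3.59e-15)
ATAC-eGene concordance (IFNG vs UT): r = 0.969 over 42 links
context specificity: 17.2% of IFNG leads vs 0.4% of LPS24 leads in matched set (p = 7.37e-12, OR = 49.3)
```

Reading this: the recurrence filter keeps 1,672 of the merged peak
clusters; differential peaks concentrate in distal regions (61.9% vs
45.1%, Fisher p ≈ 3e−08); eRNA output tracks chromatin change (r ≈ 0.68
over differential-eRNA pairs, by construction centred on the planted 0.6);
linked eGenes move with their enhancers (r ≈ 0.97); and lead eQTLs mapped
in the IFNγ state are strongly enriched among IFNγ-specific
enhancer–gene links relative to LPS24 leads.

The same pipeline runs in one call with `run_demo(simulation_spec(seed = 1),
outdir = "results/demo")`.

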