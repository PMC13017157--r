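# spliceburden

Single-sample differential splicing analysis for tumor RNA-seq cohorts,
built for settings — like pediatric CNS tumors — where matched normal
tissue is unavailable and each tumor must be compared to the rest of its
cohort. The package is aimed at computational biologists analyzing
rMATS-style junction-count output across tens to hundreds of tumors.

## What it computes

**PSI.** Each splice event (SE / A5SS / A3SS / RI / MXE, rMATS dialect) is
quantified by length-normalized percent spliced in,
`PSI = (I/L_I) / (I/L_I + S/L_S)` from inclusion and skipping junction
counts, with cells kept only when `I + S >= 10`.

**Differential calls.** Sample *i* is differential for event *j* iff
`|PSI_ij − μ_j| > 0.2` **and** `|PSI_ij − μ_j| / σ_j > 2`, where `μ_j`,
`σ_j` are the cohort mean and SD over covered samples. Calls in ≥ 2
samples define recurrent events, with inclusion / skipping / mixed
direction classes and per-histology specificity summaries.

**Splicing Burden Index.** `SBI_i` = proportion of sample *i*'s evaluable
events called differential; quartile groups (high ≥ Q3, low ≤ Q1) feed
correlation analyses (TMB, splicing-factor expression) and survival
models.

**Clustering.** Hierarchical clustering (Ward / Euclidean) of samples on
the top 5000 most variable events; cluster–histology enrichment by Fisher
exact test with Haldane-corrected odds ratios; PSI variance partitioned
against marker-based cell-type scores.

**Prioritization.** Recurrent events are projected from genomic to
protein coordinates through transcript models (strand-aware, clipped to
the CDS, floored to codons) and intersected with protein features
(domains, disulfide bonds, localization signals, modified residues), then
filtered through an ordered cascade: feature impact → kinase → splicing
kinase → median TPM > 10 → called in > 10 tumors → not RI/RI-like, with
survivor counts recorded at every stage.

**Outcomes.** Cox proportional-hazards models (Efron ties, explicit
reference levels, interactions such as SBI × cluster), Kaplan–Meier
stratification with log-rank tests, and an ordered age-group trend test
for oncofetal splicing patterns.

**Synthetic cohort.** A fully deterministic generator plants ground truth
for every stage — Beta-distributed cluster-structured PSI, junction
counts that invert the length normalization, per-sample differential
outliers, burden-coupled splicing-factor expression, cell-type fractions,
survival effects, and a toy genome whose CLK1-like skipped exon sits
inside a kinase-domain feature. The methods vignette
(`vignettes/splicing-burden-methods.Rmd`) documents the model and every
tunable parameter.

## Worked example

The numbered scripts under `analysis/` run the full study on the
reference synthetic cohort (200 samples × 20,000 cassette-exon events,
seed 71), writing tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_differential_burden.R
Rscript analysis/03_clustering_celltypes.R
Rscript analysis/04_prioritize_candidates.R
Rscript analysis/05_survival_agetrend.R
```

Script 02 prints:

```
psi_matrix: 20008 events x 200 samples (100.0% covered, min_reads=10)
differential calls: 91089 across 200 samples
recurrent events (N >= 2): 18075 (27.0% skipping-only)
median SBI: 0.0224 (2.24%); high/low groups: 50/50
SF genes significantly DE between high and low SBI: 100.0% (50/50)
```

— the median burden of 2.24% matches the planted per-sample differential
fraction (mean 2%), and all 50 burden-coupled splicing-factor genes
separate the high- and low-SBI groups. Script 03 recovers the ten planted
clusters and their histology enrichments (e.g. cluster 5 vs GNT,
OR = 1396.1, BH-adjusted p = 1.6e-19). Script 04 prints the cascade audit:

```
 stage                         description n_events
     1       recurrent differential events    18075
     2 predicted functional-feature impact        7
     3                         kinase gene        6
     4          splicing-regulatory kinase        5
     5                     median TPM > 10        4
     6               called in > 10 tumors        3
     7                   not RI or RI-like        1
final candidates: 1  (CLK1, skipping, 17 samples)  — the planted truth
```

Each planted decoy exits at exactly the stage it was designed to fail.
Script 05 fits the survival models (several clusters carry significant
hazard ratios, as planted) and confirms the candidate exon's inclusion
declines across age groups (Spearman rho = −0.27, p = 9.2e-05).

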