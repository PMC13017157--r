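---
title: "Methods: single-sample differential splicing, splicing burden, and exon-level prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-sample differential splicing, splicing burden, and exon-level prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `spliceburden`, the
parameters that matter, the synthetic cohort the package validates itself
against, and the design decisions taken where the analysis was genuinely
open. It states no empirical result that the package's tests and the
acceptance script do not themselves compute.

## The problem

Pediatric CNS tumors rarely have matched normal tissue, so differential
splicing cannot be defined against a per-patient control. The approach
implemented here instead compares each tumor to the rest of its cohort:
every splice event in every sample is scored against the cohort's
distribution for that event, per-sample burdens are summarized in a single
index, samples are clustered on their splicing profiles, recurrent events
are projected onto protein functional annotation to find candidates with
plausible functional impact, and all of these derived quantities are
carried into proportional-hazards outcome models.

## Quantifying splicing: length-normalized PSI

Events are represented in the rMATS junction-count dialect: inclusion
junction count $I$, skipping junction count $S$, and effective form
lengths $L_I$, $L_S$. Percent spliced in is the length-normalized ratio

$$\mathrm{PSI} = \frac{I / L_I}{I / L_I + S / L_S},$$

undefined when $I = S = 0$. All genomic coordinates follow the rMATS
convention (0-based start, exclusive end) throughout the package. A cell
(event $\times$ sample) enters the analysis only when $I + S \ge 10$; the
threshold applies to the sum of the junction counts (the common reading of
an "at least 10 junction reads" filter — a per-junction minimum is
available through `min_reads` if a stricter reading is wanted). The
variable region of an event is the cassette exon (SE), the alternative
extension segment (A5SS/A3SS), the retained intron (RI), or the first
alternative exon (MXE); MXE events are parsed and carried through the
matrix but excluded from protein-coordinate mapping, where a single
variable region is required.

## Single-sample differential calls

For event $j$ let $\mu_j$ and $\sigma_j$ be the mean and sample standard
deviation (denominator $n-1$) of PSI over covered samples. Sample $i$ is
called differential for event $j$ iff

$$|z_{ij}| > 2 \quad \text{and} \quad |\Delta\mathrm{PSI}_{ij}| > 0.2,
\qquad \Delta\mathrm{PSI}_{ij} = \mathrm{PSI}_{ij} - \mu_j,\;
z_{ij} = \Delta\mathrm{PSI}_{ij} / \sigma_j,$$

with strict inequalities and the thresholds applied to magnitudes, so
skipping outliers (negative $\Delta$PSI) are called symmetrically with
inclusion outliers. Events with fewer than 10 covered samples or zero
variance are non-evaluable (a zero-variance event would otherwise produce
infinite z-scores). By default the sample is included in its own cohort
statistics — the "sample compared to cohort" design; a leave-one-out mode
(`mode = "loo"`) removes the self-inflation of $\mu_j, \sigma_j$ and
agrees with the full-cohort mode as the cohort grows (the suite checks
max $|z|$ discrepancy $< 0.1$ at $n = 500$).

Recurrent events are those called in at least 2 samples; their direction
class is *inclusion* if no call is negative, *skipping* if none is
positive, otherwise *mixed*. Histology-specific events are recurrent
events whose calls all fall in one histology, reported per histology
normalized by its patient count.

## Splicing Burden Index

The SBI of sample $i$ is the proportion of its evaluable events called
differential:

$$\mathrm{SBI}_i = \frac{\#\{j : \text{call}_{ij}\}}
{\#\{j : \text{covered}_{ij} \wedge \text{evaluable}_j\}}.$$

The denominator is per-sample rather than the global event count so that
samples with unequal coverage remain comparable (a global-denominator mode
exists). High and low burden groups are samples at or above the third /
at or below the first cohort quartile. Quartiles are interpolated sample
quantiles (R type 7): with distinct values this labels exactly the top and
bottom quarters, which is the behavior the group definitions intend;
nearest-rank quantiles would put Q3 on an observed value and pull an extra
sample into the high group. The type is configurable. If all samples share
one value the rules degenerate (everything is both high and low); such
samples are assigned to `mid` with a warning.

Correlates of SBI (tumor mutation burden, splicing-factor expression) use
Pearson or Spearman correlation with BH adjustment across each
invocation, with an optional exclusion filter (default hypermutation
cutoff TMB > 10 mutations/Mb, configurable — the cutoff is a convention,
not a fitted value). Differential expression of splicing-factor genes
between high- and low-SBI groups uses a two-sided Wilcoxon rank-sum test
per gene on $\log_2(\mathrm{TPM}+1)$ with BH adjustment; the effect is the
difference of group means on that scale. A rank-based test was chosen
because the comparison is between sample groups on a normalized abundance
scale where count-model assumptions are unavailable.

## Clustering and cell-type variance partitioning

Samples are clustered on the top 5000 most variable events among those
covered in at least 75% of samples (variance over covered cells;
deterministic tie-break by event key). Missing cells are imputed with the
event median — deliberately minor because of the 75% coverage filter.
Agglomerative clustering uses Ward linkage on Euclidean distance by
default, with $(1-\mathrm{Pearson})$ distance and average linkage as
flags; the tree is cut at $k = 10$. Distance, linkage, and imputation are
explicit package choices: the upstream analysis this design follows does
not specify them. A silhouette scan over $k$ is provided as a diagnostic
and never auto-applied. Cluster ids are renumbered by the smallest sample
id they contain, so the labeling is invariant to input order.

Cluster–label enrichment uses a one-vs-rest 2×2 table per (cluster,
label): two-sided Fisher exact p (the suite checks it against full
hypergeometric enumeration for every table with $n \le 30$), odds ratio
$(ad)/(bc)$ with the Haldane–Anscombe 0.5 correction when any cell is
zero (the infinite raw ratio is flagged), BH across all pairs.

Cell-type scores are marker-gene summaries of bulk expression: per type,
the mean across its markers of z-scored $\log_2(\mathrm{TPM}+1)$. A
mean-of-z score rather than a full deconvolution is sufficient here
because only the *relative* scores enter the downstream regression.
Per event, PSI is regressed on all cell-type scores plus an intercept
over covered samples; $R^2 = 1 - \mathrm{RSS}/\mathrm{TSS}$ is binned at
0.30 and 0.50 with the middle bin closed on both edges. Events with fewer
than (number of types + 2) covered samples or zero variance are skipped.
Under a pure-noise PSI the expected $R^2$ is approximately $p/(n-1)$ for
$p$ scores, which the suite verifies at $n = 200$, $p = 6$.

## Exon-to-protein projection and the prioritization cascade

The projection of a genomic interval onto protein coordinates is defined
as: intersect the interval with the transcript's CDS, map the
intersection onto spliced-CDS base offsets (strand-aware; minus-strand
transcripts read right to left), and convert 0-based base offsets to
1-based amino acids by $\lfloor \mathrm{offset}/3 \rfloor + 1$ at both
ends. This contract — clip to CDS, floor to codon, strand-aware — is this
package's own definition (no published procedure exists for it), and it
is validated against an independent per-base enumeration oracle on random
multi-exon models of both strands, including junction-straddling and
UTR-overlapping intervals.

A protein feature is impacted when its amino-acid interval intersects the
projection of the event's variable region, except disulfide bonds, which
are impacted only when a bonded *endpoint* residue falls inside the
projection (the span between bonded cysteines is not an annotated
functional region). Impact direction follows the event's cohort direction
class: inclusion → gain, skipping → loss, mixed → mixed. When a gene has
several models, impacts are computed per model and unioned — the
alternative (pick one canonical model) discards information and no rule
for choosing it is given anywhere authoritative.

The cascade then filters recurrent differential events through ordered
stages, recording survivors after each: (1) recurrence; (2) at least one
feature impact; (3) kinase; (4) splicing-regulatory kinase (default list:
CLK1–4, FASTK, MARK2, PKN2, PRKDC, SMG1, SRPK1, SRPK3); (5) expressed,
cohort median TPM > 10 (median chosen as the cohort summary; a
per-calling-sample mode exists); (6) called in > 10 tumors (counted per
event, not per gene); (7) drop RI events and "RI-like" A5SS/A3SS events
whose variable region spans an entire annotated intron of any model —
intron-retention signal from short reads has an elevated false-positive
rate, and read-through alternative splice-site calls share the same
failure mode. Survivor counts are monotone non-increasing by
construction, and the final set is order-invariant.

## Survival models and the age trend

Cox proportional-hazards fits use Efron tie handling (Breslow by flag).
Factor covariates carry explicit reference levels — cluster 1 and
gross/near-total resection; the resection reference is a package decision,
configurable, since only contrasts were ever printed upstream.
Interactions (e.g. SBI × cluster) are written in the model formula.
Continuous PSI covariates enter per unit (0 → 1); because a 0-to-1 change
in PSI is a large biological contrast, per-unit hazard ratios far from 1
are expected and a per-0.1 rescaling is a trivial reparameterization left
to the caller. Histologies with fewer than 3 samples can be collapsed
into a single level (`collapse_small_levels()`) to keep them in the
model. Complete separation is detected from the partial-likelihood
diagnostics and raised as an error naming the term, never returned as a
silent huge coefficient. Kaplan–Meier stratification splits at the median
score (or a given cut) and reports the two-sided log-rank p.

The age-trend ("oncofetal") test takes per-sample values and ordered age
groups, runs a two-sided rank-sum test per adjacent pair (BH-adjusted),
and summarizes the trend as the Spearman correlation between values and
group rank; a declining oncofetal pattern gives a negative trend
statistic.

## The synthetic cohort and what it does (not) show

All validation runs on a generator with planted ground truth; its
defaults are the reference study conditions:

* 200 samples in 10 equal clusters; 20,000 cassette-exon events.
* Each event has a base mean PSI drawn uniformly on [0.05, 0.95]; 10% of
  events are cluster-informative, their per-cluster means split ±0.15
  around the base (between-cluster separation 0.3).
* Sample PSI is Beta-distributed around its target with concentration
  $c = 200$ (biological sd ≈ 0.035 at mid-range PSI).
* Junction counts invert the length normalization: total reads per cell
  are lognormal with mean 100 (sdlog 0.5) — junction depths typical of
  moderately expressed genes in clinical RNA-seq — and inclusion reads
  are drawn binomially with success probability
  $\psi L_I / (\psi L_I + (1-\psi) L_S)$, so length-normalized PSI is
  unbiased for the target. This inversion is the subtle part of emulating
  rMATS counts.
* Differential outliers are planted per sample at a fraction averaging 2%
  (uniformly spread across samples between 0.5% and 3.5%, so true burdens
  differ and burden *ranking* is a meaningful target), with effect size
  Δ = 0.3 by default. The shift direction is random where both directions
  stay inside (0.01, 0.99) and otherwise the feasible one; configurations
  where neither direction is feasible are rejected before any data are
  written. Outliers are planted only on non-informative events so the
  truth set is unambiguous.
* The toy annotation carries ~50 multi-exon genes (both strands,
  contiguous CDS, frame-closed by construction) with protein features of
  four categories at known positions, and eight planted cascade events:
  one true candidate — a skipped exon in a CLK1-like splicing kinase
  whose cassette exon projects inside a kinase-domain feature, highly
  expressed, with skipping planted in 25 samples — and decoys designed to
  fail exactly one stage each (no-feature gene, non-kinase, non-splicing
  kinase, median TPM 5, 5-sample recurrence, an RI event whose intron is
  coding in a retained-intron isoform, and an RI-like A5SS reading
  through an intron into coding sequence). Twenty-five planted samples
  give the ">10 tumors" filter headroom against the caller's expected
  per-call miss rate at these events, which is substantially higher than
  for the bulk outliers: planting a tenth of the cohort at one event
  inflates that event's own cohort standard deviation (self-dilution),
  pushing planted z-scores toward the threshold.
* The candidate exon's inclusion declines mildly with age (oncofetal
  pattern), splicing-factor gene expression is linear in the standardized
  planted burden, marker genes are driven by Dirichlet cell-type
  fractions, and survival is exponential with cluster, resection, and
  candidate-PSI log-hazard effects and ~30% independent censoring.

Ground truth is serialized separately from the fixtures (under `truth/`)
and is never read by the pipeline.

What passing these tests shows: the implementation recovers exactly what
it was asked to recover under a model whose assumptions it shares. What
it does not show: robustness to features of real tumor RNA-seq the
generator does not emulate — overdispersed or correlated junction counts,
coverage that tracks expression and histology, batch effects, isoform
complexity beyond one variable region per event, non-proportional
hazards, or informative censoring. Conclusions about real cohorts need
the real data.

## Numerical choices and problem sizes

Fixed 6-decimal formatting for PSI serialization makes write→read→write
cycles byte-identical; coordinates are always written as plain integers.
Event keys concatenate type, chromosome, strand, and all coordinates, so
identity is injective and file-order-independent. Variance tie-breaks are
by event key. The degenerate all-equal SBI distribution resolves to
`mid`. Beta draws are clipped away from {0, 1} by $10^{-6}$ — a generator
artifact documented here, irrelevant at the default concentration.

The validation suite sizes its simulations to exercise the asymptotics
that matter while staying light: five 200 × 20,000 cohorts for
call-recovery, ten 200 × 2,000 cohorts for cluster recovery, fifty
n = 1,000 survival simulations for CI coverage, and one full-scale
pipeline double-run for byte-reproducibility. The methods' guarantees are
asymptotic in cohort size, not event count, so recovery results at
2,000 events transfer to 20,000.

## Known limitations

The single-sample z-score design inflates cohort variance when many
samples are outliers at the same event (self-dilution); at 10–30%
outlier prevalence per event, sensitivity degrades — visible in the
generator itself when planted fractions are made large relative to the
cohort. The RI-like rule is an operationalization of a remark about
mis-annotated retained introns, not a validated classifier. The
cell-type variance partition attributes to composition any PSI signal
correlated with marker expression, including genuine tumor-intrinsic
splicing that tracks lineage. GSVA-style pathway scores are consumed as
external covariates and never computed here.
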