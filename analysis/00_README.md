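# Analysis workflow

Numbered drivers over the `spliceburden` package. Run from the repository
root in order; each writes its tables under `results/`:

    Rscript analysis/01_simulate_cohort.R
    Rscript analysis/02_differential_burden.R
    Rscript analysis/03_clustering_celltypes.R
    Rscript analysis/04_prioritize_candidates.R
    Rscript analysis/05_survival_agetrend.R

`01` generates the reference synthetic cohort (200 samples, 20,000
cassette-exon events, planted ground truth) under `results/fixtures/`; the
later scripts consume those fixtures and the intermediate tables.
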