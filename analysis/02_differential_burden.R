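#!/usr/bin/env Rscript
# Assemble the cohort PSI matrix, call per-sample differential splice
# events against cohort statistics, summarize recurrence and histology
# specificity, and compute the Splicing Burden Index with its clinical
# correlates.

suppressMessages(library(spliceburden))

cohort <- read_cohort("results/fixtures")
pm <- assemble_psi_matrix(cohort$tables, min_reads = 10)
print(pm)
write_psi_matrix(pm, "results/psi_matrix.tsv", "results/psi_coverage.tsv")

stats <- cohort_event_stats(pm)
calls <- call_differential(pm, stats, z_thresh = 2, dpsi_thresh = 0.2)
write.table(calls, "results/calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("differential calls: %d across %d samples\n", nrow(calls),
            length(unique(calls$sample))))

rec <- recurrence(calls, min_recurrence = 2)
write.table(rec, "results/recurrent.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("recurrent events (N >= 2): %d (%.1f%% skipping-only)\n",
            nrow(rec), 100 * mean(rec$direction_class == "skipping")))

hs <- histology_specific(rec, calls, cohort$manifest)
write.table(hs$per_histology, "results/histology_specific.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(head(hs$per_histology, 5))

sbi <- assign_sbi_groups(compute_sbi(calls, pm, stats))
write.table(sbi, "results/sbi.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("median SBI: %.4f (%.2f%%); high/low groups: %d/%d\n",
            median(sbi$sbi), 100 * median(sbi$sbi),
            sum(sbi$group == "high"), sum(sbi$group == "low")))

mf <- cohort$manifest[match(sbi$sample, cohort$manifest$sample), ]
tmb <- grouped_correlation(mf$TMB, sbi$sbi)
tmb_nohyper <- grouped_correlation(mf$TMB, sbi$sbi, exclude = mf$TMB > 10)
cat(sprintf("TMB~SBI Pearson r = %.3f (p = %.2g); excluding hypermutant: r = %.3f\n",
            tmb$r, tmb$p, tmb_nohyper$r))

sf <- read.delim("results/fixtures/sf_genes.tsv")$gene
assoc <- sf_expression_association(cohort$tpm, sbi, sf)
write.table(assoc, "results/sf_association.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("SF genes significantly DE between high and low SBI: %.1f%% (%d/%d)\n",
            100 * mean(assoc$significant), sum(assoc$significant),
            nrow(assoc)))
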