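#!/usr/bin/env Rscript
# Cluster samples on the most variable splice events, test cluster-label
# enrichment, and partition PSI variance by marker-based cell-type scores.

suppressMessages(library(spliceburden))

cohort <- read_cohort("results/fixtures")
pm <- assemble_psi_matrix(cohort$tables)

top <- top_variable_events(pm, k = 5000, min_coverage_frac = 0.75)
cl <- cluster_samples(pm, k = 10, subset_events = top)
print(cl)
write.table(data.frame(sample = names(cl$cluster), cluster = cl$cluster),
            "results/clusters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

mf <- cohort$manifest
enr <- cluster_enrichment(cl$cluster, setNames(mf$histology, mf$sample))
write.table(enr, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sig <- enr[enr$adj_p < 0.05, ]
best <- sig[order(-sig$odds_ratio), ][1:5, c("cluster", "label",
                                             "odds_ratio", "adj_p")]
cat("top cluster-histology enrichments:\n"); print(best, row.names = FALSE)

scores <- celltype_scores(cohort$tpm, cohort$marker_sets)
write.table(data.frame(sample = rownames(scores), scores),
            "results/celltype_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

ve <- psi_variance_explained(pm, scores, subset_events = top)
write.table(ve, "results/variance_explained.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("PSI variance explained by cell-type composition:\n")
print(round(100 * table(ve$bin) / nrow(ve), 1))
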