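#!/usr/bin/env Rscript
# Map recurrent splice events onto protein functional features and run the
# kinase / expression / recurrence prioritization cascade.

suppressMessages(library(spliceburden))

cohort <- read_cohort("results/fixtures")
pm <- assemble_psi_matrix(cohort$tables)
stats <- cohort_event_stats(pm)
calls <- call_differential(pm, stats)
rec <- recurrence(calls)

imp <- affected_features(rec, pm$events, cohort$models, cohort$features)
write.table(imp, "results/impacts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("events with predicted feature impact: %d\n",
            length(unique(imp$event_key))))

casc <- run_cascade(rec, pm$events, imp, cohort$tpm,
                    kinases = cohort$kinases,
                    splicing_kinase_list = cohort$splicing_kinases,
                    tpm_threshold = 10, recurrence_threshold = 10,
                    models = cohort$models)
print(casc)
write.table(casc$stages, "results/cascade_stages.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(casc$candidates, "results/candidates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- readLines("results/fixtures/truth/candidate_keys.txt")
cat(sprintf("planted candidate recovered: %s\n",
            identical(sort(casc$candidates$event_key), sort(truth))))
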