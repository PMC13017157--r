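#!/usr/bin/env Rscript
# Survival models (cluster, SBI, SBI x cluster interaction, candidate-exon
# PSI), Kaplan-Meier stratification, and the oncofetal age-trend test.

suppressMessages(library(spliceburden))

cohort <- read_cohort("results/fixtures")
mf <- cohort$manifest
clusters <- read.delim("results/clusters.tsv")
sbi <- read.delim("results/sbi.tsv")
cand <- read.delim("results/candidates.tsv")
pm <- assemble_psi_matrix(cohort$tables)

d <- data.frame(
  time = mf$OS_days, status = mf$OS_status,
  cluster = relevel(factor(clusters$cluster[match(mf$sample,
                                                  clusters$sample)]),
                    ref = "1"),
  resection = relevel(factor(mf$resection), ref = "gross/near total"),
  age = mf$age,
  sbi = sbi$sbi[match(mf$sample, sbi$sample)])

f1 <- fit_cox(d, ~ cluster + resection + age)
cat("OS ~ cluster + resection + age:\n"); print(f1)
write.table(f1$terms, "results/cox_cluster.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

f2 <- fit_cox(d, ~ cluster * sbi + resection + age)
write.table(f2$terms, "results/cox_sbi_interaction.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
it <- f2$terms[grepl(":sbi", f2$terms$term), ]
cat(sprintf("SBI x cluster interactions with p < 0.05: %d of %d\n",
            sum(it$p < 0.05), nrow(it)))

if (nrow(cand) > 0) {
  psi <- pm$psi[cand$event_key[1], mf$sample]
  ok <- !is.na(psi)
  dp <- cbind(d[ok, ], histology = collapse_small_levels(mf$histology[ok]),
              psi = psi[ok])
  f3 <- fit_cox(dp, ~ psi + resection + histology + age)
  cat("OS ~ candidate-exon PSI + resection + histology + age:\n")
  print(f3)
  write.table(f3$terms, "results/cox_candidate_psi.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)

  km <- km_strata(d[ok, ], psi[ok])
  cat(sprintf("KM high vs low candidate PSI: log-rank p = %.3g\n",
              km$logrank_p))
  write.table(km$curves, "results/km_curves.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)

  grp <- cut(mf$age[ok], c(0, 5, 12, 20), labels = c("0-5", "5-12", "12-20"))
  at <- age_trend(psi[ok], droplevels(grp))
  cat("candidate-exon inclusion by age group (oncofetal check):\n")
  print(at)
  write.table(at$pairwise, "results/age_trend.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
}
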