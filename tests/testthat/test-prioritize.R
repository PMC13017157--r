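# Genomic -> protein projection, feature-impact annotation, and the
# prioritization cascade.

test_that("projection handles first codon and junction-straddling intervals", {
  # plus strand, two exons, CDS bases 1..6 on exon 1 and 7..12 on exon 2
  m <- list(transcript_id = "t1", gene = "g", chrom = "chr1", strand = "+",
            exons = cbind(start = c(100L, 200L), end = c(106L, 206L)),
            cds = cbind(start = c(100L, 200L), end = c(106L, 206L)),
            cds_len = 12L)
  class(m) <- "transcript_model"
  expect_equal(genomic_to_protein(c(100, 103), m),
               c(aa_start = 1L, aa_end = 1L))
  # genomic span of CDS bases 4..9: positions 103..105 + 200..202
  expect_equal(genomic_to_protein(c(103, 203), m),
               c(aa_start = 2L, aa_end = 3L))
  # minus-strand mirror: translation reads right to left
  m2 <- m; m2$strand <- "-"
  expect_equal(genomic_to_protein(c(103, 203), m2),
               c(aa_start = 2L, aa_end = 3L))
  # interval outside CDS -> none
  expect_null(genomic_to_protein(c(110, 150), m))
  expect_error(genomic_to_protein(c(150, 110), m), "malformed")
})

test_that("projection equals the per-base enumeration oracle on random models", {
  set.seed(19)
  n_checked <- 0
  for (i in 1:200) {
    m <- random_model()
    span <- c(min(m$exons) - 50, max(m$exons) + 50)
    for (j in 1:4) {
      a <- sample(span[1]:span[2], 1)
      b <- sample(span[1]:span[2], 1)
      iv <- c(min(a, b), max(a, b) + 1)
      got <- genomic_to_protein(iv, m)
      want <- aa_oracle(iv, m)
      expect_identical(got, want)
      if (!is.null(want)) n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 200)
})

test_that("feature impacts follow interval intersection and the disulfide endpoint rule", {
  m <- list(transcript_id = "t1", gene = "KIN", chrom = "chr1",
            strand = "+",
            exons = cbind(start = 0L, end = 300L),
            cds = cbind(start = 0L, end = 300L), cds_len = 300L)
  class(m) <- "transcript_model"
  models <- list(t1 = m)
  events <- data.frame(event_key = "ev1", event_type = "SE",
                       GeneID = "G", geneSymbol = "KIN", chr = "chr1",
                       strand = "+", var_start = 57L, var_end = 90L,
                       stringsAsFactors = FALSE)      # aa 20..30
  rec <- data.frame(event_key = "ev1", direction_class = "skipping",
                    stringsAsFactors = FALSE)
  feats <- rbind(
    data.frame(gene = "KIN", transcript = NA, feature_type = "domain",
               feature_id = "d1", aa_start = 10, aa_end = 50),
    data.frame(gene = "KIN", transcript = NA, feature_type = "domain",
               feature_id = "d2", aa_start = 60, aa_end = 70),
    data.frame(gene = "KIN", transcript = NA,
               feature_type = "disulfide_bond", feature_id = "s1",
               aa_start = 12, aa_end = 80),
    data.frame(gene = "KIN", transcript = NA,
               feature_type = "disulfide_bond", feature_id = "s2",
               aa_start = 25, aa_end = 80))
  imp <- affected_features(rec, events, models, feats)
  # d1 spans the projection -> impacted as loss; d2 disjoint -> absent
  expect_true("d1" %in% imp$feature_id)
  expect_false("d2" %in% imp$feature_id)
  expect_equal(unique(imp$predicted), "loss")
  # bond s1: both endpoints outside the projection -> not impacted even
  # though its span covers it; s2 has an endpoint inside -> impacted
  expect_false("s1" %in% imp$feature_id)
  expect_true("s2" %in% imp$feature_id)
  # inclusion events predict gain
  rec$direction_class <- "inclusion"
  expect_equal(unique(affected_features(rec, events, models,
                                        feats)$predicted), "gain")
  # MXE events are not mapped
  events$event_type <- "MXE"
  expect_equal(nrow(affected_features(rec, events, models, feats)), 0)
})

test_that("the cascade drops each planted decoy at its designed stage", {
  co <- ref_cohort()
  pm <- ref_pm()
  cc <- ref_calls()
  rec <- recurrence(cc$calls)
  ann <- co$annotation
  imp <- affected_features(rec, pm$events, ann$models, ann$features)
  casc <- run_cascade(rec, pm$events, imp, co$tpm, kinases = ann$kinases,
                      models = ann$models)
  stg <- casc$stages$n_events
  expect_true(all(diff(stg) <= 0))               # monotone non-increasing
  expect_equal(stg[2], 7)                        # 7 planted impact events
  expect_equal(stg[3], 6)                        # non-kinase dropped
  expect_equal(stg[4], 5)                        # non-splicing kinase dropped
  expect_equal(stg[5], 4)                        # low-TPM dropped
  expect_equal(stg[6], 3)                        # low-recurrence dropped
  expect_equal(stg[7], 1)                        # RI + RI-like dropped
  expect_equal(casc$candidates$event_key, co$truth$candidate_keys)
  expect_equal(casc$candidates$direction_class, "skipping")
  # input order does not change the final set
  rec2 <- rec[rev(seq_len(nrow(rec))), ]
  casc2 <- run_cascade(rec2, pm$events, imp, co$tpm,
                       kinases = ann$kinases, models = ann$models)
  expect_equal(sort(casc2$candidates$event_key),
               sort(casc$candidates$event_key))
  expect_error(run_cascade(rec, pm$events, imp, co$tpm,
                           kinases = character(0)), "empty kinase")
})

test_that("toy annotation satisfies its structural invariants", {
  cfg <- sim_config(seed = 23)
  ann <- simulate_annotation(cfg)
  # frame closure and model validity for every transcript
  for (m in ann$models) {
    expect_equal(m$cds_len %% 3, 0)
    expect_silent(validate_transcript_model(m))
  }
  # features live inside their protein
  plen <- vapply(ann$models, function(m) m$cds_len / 3, numeric(1))
  gene_of <- vapply(ann$models, `[[`, "", "gene")
  for (i in seq_len(nrow(ann$features))) {
    f <- ann$features[i, ]
    pl <- if (!is.na(f$transcript)) {
      plen[[f$transcript]]
    } else {
      max(plen[gene_of == f$gene])
    }
    expect_gte(f$aa_start, 1)
    expect_lte(f$aa_start, f$aa_end)
    expect_lte(f$aa_end, pl)
  }
  # the planted candidate exon projects inside its domain feature
  cand <- ann$planted_events[ann$planted_events$role == "candidate", ]
  models <- ann$models[gene_of == cand$gene]
  proj <- genomic_to_protein(c(cand$var_start, cand$var_end), models[[1]])
  dom <- ann$features[ann$features$feature_id == "CLK1_kinase_domain", ]
  expect_gte(proj["aa_start"], dom$aa_start)
  expect_lte(proj["aa_end"], dom$aa_end)
  # ... and agrees with the per-base oracle
  expect_identical(proj, aa_oracle(c(cand$var_start, cand$var_end),
                                   models[[1]]))
})

test_that("annotation round-trips through GTF and feature TSV", {
  cfg <- sim_config(seed = 29, n_filler_genes = 5)
  ann <- simulate_annotation(cfg)
  d <- withr::local_tempdir()
  paths <- write_annotation(ann, d)
  models <- read_transcript_models(paths$gtf)
  expect_setequal(names(models), names(ann$models))
  for (tx in names(models)) {
    expect_equal(models[[tx]]$exons, ann$models[[tx]]$exons,
                 ignore_attr = TRUE)
    expect_equal(models[[tx]]$cds, ann$models[[tx]]$cds,
                 ignore_attr = TRUE)
    expect_equal(models[[tx]]$strand, ann$models[[tx]]$strand)
    expect_equal(models[[tx]]$gene, ann$models[[tx]]$gene)
  }
  feats <- read_features(paths$features)
  expect_equal(nrow(feats), nrow(ann$features))
})
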