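# Synthetic cohort generator: determinism, distributional targets, and
# fixture integrity.

test_that("the generator is fully deterministic under a seed", {
  cfg <- sim_config(n_samples = 12, n_events = c(SE = 80), n_clusters = 3,
                    candidate_n_samples = 4, lowrec_n_samples = 2,
                    n_filler_genes = 4, seed = 101)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_equal(c1$tables, c2$tables)
  expect_equal(c1$manifest, c2$manifest)
  expect_equal(c1$tpm, c2$tpm)
  expect_equal(c1$truth$differential, c2$truth$differential)
  # written fixtures byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(c1, d1); write_cohort(c2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("zero planted fraction yields an empty bulk differential truth", {
  cfg <- sim_config(n_samples = 10, n_events = c(SE = 50), n_clusters = 2,
                    planted_frac = 0, candidate_n_samples = 3,
                    lowrec_n_samples = 2, n_filler_genes = 2, seed = 103)
  co <- simulate_cohort(cfg)
  bulk_truth <- co$truth$differential[
    !co$truth$differential$event_key %in%
      co$truth$planted_event_roles$event_key, ]
  expect_equal(nrow(bulk_truth), 0)
  expect_true(all(co$truth$planted_frac == 0))
})

test_that("empirical PSI means track the generator's targets", {
  cfg <- sim_config(n_samples = 60, n_events = c(SE = 300), n_clusters = 3,
                    delta = 0.4, concentration = 200, frac_informative = 0,
                    planted_frac = 0, candidate_n_samples = 3,
                    lowrec_n_samples = 2, n_filler_genes = 2, seed = 107)
  co <- simulate_cohort(cfg)
  pm <- assemble_psi_matrix(co$tables)
  # without cluster structure or planting, each event's observed mean PSI
  # should sit near its target; targets are not exported, but the event
  # mean over samples is itself the Monte-Carlo estimate, so check
  # cross-sample spread instead: sd about sqrt(m(1-m)/(c+1)) plus count
  # noise, far below 0.1 for c = 200
  keys <- grep("chrS", rownames(pm$psi), value = TRUE)
  sds <- apply(pm$psi[keys, ], 1, sd, na.rm = TRUE)
  expect_lt(stats::median(sds), 0.07)
  # planted events: mean at their 0.85 base
  cand <- co$truth$candidate_keys
  expect_equal(mean(pm$psi[cand, ], na.rm = TRUE), 0.85, tolerance = 0.04)
})

test_that("junction counts invert the length normalization without bias", {
  # fixed target PSI; with L_i = 2, L_s = 1 raw inclusion fractions are
  # biased up, but length-normalized PSI must be centered on the target
  set.seed(7)
  psi_t <- rep(c(0.2, 0.5, 0.8), each = 4000)
  cnt <- spliceburden:::.draw_counts(psi_t, rep(150L, length(psi_t)), 2, 1)
  est <- compute_psi(cnt[, "ijc"], cnt[, "sjc"], 2, 1)
  for (p in unique(psi_t)) {
    expect_equal(mean(est[psi_t == p]), p, tolerance = 0.01)
  }
})

test_that("planted differential truths meet the promised effect size", {
  co <- ref_cohort()
  expect_true(all(abs(co$truth$differential$true_dpsi) >=
                    co$config$delta - 1e-9))
  # direction labels match the sign
  expect_equal(co$truth$differential$direction,
               ifelse(co$truth$differential$true_dpsi > 0, "inclusion",
                      "skipping"))
})

test_that("manifest fields are complete and plausibly distributed", {
  cfg <- sim_config(n_samples = 500, n_clusters = 4,
                    n_events = c(SE = 50), histology_purity = 1,
                    candidate_n_samples = 10, lowrec_n_samples = 2,
                    n_filler_genes = 2, seed = 109)
  co <- simulate_cohort(cfg)
  mf <- co$manifest
  expect_equal(nrow(mf), 500)
  expect_false(anyDuplicated(mf$sample) > 0)
  expect_true(all(mf$OS_status %in% c(0, 1)))
  expect_true(all(mf$OS_days > 0))
  expect_true(all(mf$TMB > 0))
  expect_setequal(unique(mf$resection),
                  c("gross/near total", "partial", "biopsy"))
  # histology proportions near the (equal) cluster proportions
  frac <- table(mf$histology) / nrow(mf)
  expect_true(all(abs(frac - 0.25) < 0.05))
  # censoring near the configured rate (high-hazard samples censor a bit
  # less often, so the realized rate sits slightly below the target)
  expect_lt(abs(mean(mf$OS_status == 0) - co$config$censor_rate), 0.08)
})

test_that("infeasible effect sizes are rejected before any work", {
  expect_error(sim_config(delta = 0.6), "infeasible")
  expect_error(sim_config(delta = 0), "positive")
  expect_error(sim_config(cluster_proportions = c(0.5, 0.2), n_clusters = 2),
               "sum to 1")
})

test_that("fixtures parse cleanly back through the rmats reader", {
  cfg <- sim_config(n_samples = 6, n_events = c(SE = 40, A5SS = 10, RI = 5),
                    n_clusters = 2, candidate_n_samples = 3,
                    lowrec_n_samples = 2, n_filler_genes = 2, seed = 113)
  co <- simulate_cohort(cfg)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  back <- read_cohort(d)
  expect_equal(names(back$tables), names(co$tables))
  for (s in names(back$tables)) {
    a <- back$tables[[s]]; b <- co$tables[[s]]
    a <- a[order(a$event_key), ]; b <- b[order(b$event_key), ]
    expect_equal(a$event_key, b$event_key)
    expect_equal(a$IJC_SAMPLE_1, b$IJC_SAMPLE_1)
    expect_equal(a$var_start, b$var_start)
  }
  # assembled matrices identical either way
  p1 <- assemble_psi_matrix(co$tables)
  p2 <- assemble_psi_matrix(back$tables)
  expect_equal(p1$psi, p2$psi)
  expect_equal(p1$covered, p2$covered)
})
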