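# Shared fixtures, built in code. Heavier simulated objects are cached for
# the session so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small deterministic rMATS-style SE table for one sample.
toy_se_table <- function(n = 3, sample_shift = 0) {
  start <- 1000L + 500L * (seq_len(n) - 1L)
  tab <- data.frame(
    ID = seq_len(n), GeneID = sprintf("G%03d", seq_len(n)),
    geneSymbol = sprintf("GENE%03d", seq_len(n)), chr = "chr1",
    strand = rep(c("+", "-"), length.out = n),
    exonStart_0base = start, exonEnd = start + 100L,
    upstreamES = start - 300L, upstreamEE = start - 200L,
    downstreamES = start + 200L, downstreamEE = start + 300L,
    IJC_SAMPLE_1 = 10L + seq_len(n) + sample_shift,
    SJC_SAMPLE_1 = 5L + sample_shift,
    IncFormLen = 2L, SkipFormLen = 1L,
    stringsAsFactors = FALSE)
  tab$IncLevel1 <- compute_psi(tab$IJC_SAMPLE_1, tab$SJC_SAMPLE_1,
                               tab$IncFormLen, tab$SkipFormLen)
  tab$event_type <- "SE"
  tab$event_key <- splice_event_key(
    "SE", tab$chr, tab$strand,
    tab[c("exonStart_0base", "exonEnd", "upstreamES", "upstreamEE",
          "downstreamES", "downstreamEE")])
  tab$var_start <- tab$exonStart_0base
  tab$var_end <- tab$exonEnd
  tab
}

# Build a psi_matrix directly from a numeric matrix (all cells covered
# unless NA); convenient for arithmetic-oracle tests.
psi_matrix_from <- function(m, covered = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("ev%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("S%03d", seq_len(ncol(m)))
  if (is.null(covered)) covered <- !is.na(m)
  events <- data.frame(event_key = rownames(m), event_type = "SE",
                       GeneID = rownames(m), geneSymbol = rownames(m),
                       chr = "chr1", strand = "+",
                       var_start = seq_len(nrow(m)) * 100L,
                       var_end = seq_len(nrow(m)) * 100L + 50L,
                       stringsAsFactors = FALSE)
  structure(list(events = events, samples = colnames(m), psi = m,
                 covered = covered, min_reads = 10),
            class = "psi_matrix")
}

# Mid-size cohort with planted truth used by several module tests.
ref_cohort <- function() {
  cached("ref_cohort", {
    cfg <- sim_config(n_samples = 200, n_events = c(SE = 2000), seed = 11)
    simulate_cohort(cfg)
  })
}

ref_pm <- function() {
  cached("ref_pm", assemble_psi_matrix(ref_cohort()$tables))
}

ref_calls <- function() {
  cached("ref_calls", {
    pm <- ref_pm()
    st <- cohort_event_stats(pm)
    list(stats = st, calls = call_differential(pm, st))
  })
}

# Adjusted Rand index between two labelings (quadratic-sum formula);
# independent of any clustering package.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}
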