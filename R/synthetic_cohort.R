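# Synthetic splicing cohort with planted ground truth.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: cluster-structured Beta-distributed PSI per event, junction
# counts whose length-normalized PSI is unbiased for the target, planted
# per-sample differential outliers, splicing-factor expression coupled to
# the planted burden, Dirichlet cell-type fractions driving marker genes,
# and exponential survival with cluster-, resection- and PSI-dependent
# hazards.

#' Simulation configuration
#'
#' Defaults describe the reference synthetic cohort: 200 samples in 10
#' clusters, 20,000 cassette-exon events with Beta concentration 200,
#' 10% cluster-informative events separated by a PSI difference of 0.3,
#' planted per-sample differential fractions averaging 2% with effect size
#' 0.3, and junction coverage averaging 100 reads per event.
#'
#' @param n_samples Number of samples.
#' @param n_clusters Number of planted clusters.
#' @param cluster_proportions Cluster membership proportions (default
#'   equal); must sum to 1.
#' @param histologies Histology label per cluster (recycled / truncated to
#'   `n_clusters`).
#' @param histology_purity Probability a sample carries its cluster's
#'   histology (otherwise a random other one).
#' @param n_events Named vector of event counts per type (default
#'   `c(SE = 20000)`).
#' @param concentration Beta concentration `c`; PSI noise sd is about
#'   `sqrt(m (1 - m) / (c + 1))`.
#' @param cluster_dpsi Between-cluster PSI separation of informative
#'   events.
#' @param frac_informative Fraction of events carrying cluster structure.
#' @param planted_frac Mean per-sample fraction of events planted as
#'   differential outliers.
#' @param planted_frac_range Relative uniform range of the per-sample
#'   fraction around `planted_frac` (gives samples distinct true burdens).
#' @param delta Planted outlier effect size (|target PSI shift|); must
#'   exceed the differential `dpsi` threshold for calls to be expected, and
#'   be feasible for every base mean (`delta <= 0.49`).
#' @param mean_total_reads,reads_sdlog Lognormal junction-coverage model
#'   (total `ijc + sjc` per cell).
#' @param inc_form_len,skip_form_len Effective form lengths written to the
#'   rMATS tables (inclusion counts are drawn with the length bias
#'   inverted, so length-normalized PSI is unbiased for the target).
#' @param n_sf_genes,sf_coupling Number of splicing-factor genes and the
#'   slope of their log2 expression on the standardized planted burden.
#' @param n_celltypes,markers_per_type,marker_strength Cell-type mixture:
#'   Dirichlet fractions per sample and marker-gene log2-expression slope
#'   per unit fraction.
#' @param baseline_hazard Daily baseline hazard of the exponential survival
#'   model.
#' @param cluster_loghr Per-cluster log hazard ratios (reference cluster 1
#'   at 0; recycled / truncated to `n_clusters`).
#' @param psi_loghr Log HR per unit candidate-exon PSI (negative: inclusion
#'   protective).
#' @param resection_loghr Log HRs for resection levels (gross/near total,
#'   partial, biopsy).
#' @param censor_rate Approximate fraction of censored samples.
#' @param n_filler_genes Toy-annotation filler genes.
#' @param candidate_n_samples,lowrec_n_samples Planted call counts for the
#'   cascade candidate / the low-recurrence decoy.
#' @param seed Integer seed; fully determines all output.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_samples = 200,
                       n_clusters = 10,
                       cluster_proportions = NULL,
                       histologies = c("LGG", "MB", "EPN", "HGG", "DMG",
                                       "ATRT", "CPG", "GNT", "CPT", "SCHW"),
                       histology_purity = 0.85,
                       n_events = c(SE = 20000),
                       concentration = 200,
                       cluster_dpsi = 0.3,
                       frac_informative = 0.10,
                       planted_frac = 0.02,
                       planted_frac_range = c(0.25, 1.75),
                       delta = 0.3,
                       mean_total_reads = 100,
                       reads_sdlog = 0.5,
                       inc_form_len = 2L,
                       skip_form_len = 1L,
                       n_sf_genes = 50,
                       sf_coupling = 0.8,
                       n_celltypes = 6,
                       markers_per_type = 5,
                       marker_strength = 5,
                       baseline_hazard = log(2) / 1500,
                       cluster_loghr = c(0, 0.4, -0.4, 0.8, -0.8, 0.4,
                                         -0.4, 0.8, -0.8, 0.4),
                       psi_loghr = -1.5,
                       resection_loghr = c(0, 0.3, 0.6),
                       censor_rate = 0.3,
                       n_filler_genes = 42,
                       candidate_n_samples = 25,
                       lowrec_n_samples = 5,
                       seed = 1) {
  if (is.null(cluster_proportions)) {
    cluster_proportions <- rep(1 / n_clusters, n_clusters)
  }
  if (abs(sum(cluster_proportions) - 1) > 1e-8) {
    stop("cluster_proportions must sum to 1")
  }
  if (length(cluster_proportions) != n_clusters) {
    stop("cluster_proportions length must equal n_clusters")
  }
  if (delta > 0.49) {
    stop("delta > 0.49 is infeasible: no shift direction keeps mid-range ",
         "base means inside (0.01, 0.99)")
  }
  if (delta <= 0) stop("delta must be positive")
  histologies <- rep_len(histologies, n_clusters)
  cluster_loghr <- rep_len(cluster_loghr, n_clusters)
  cfg <- list(n_samples = n_samples, n_clusters = n_clusters,
              cluster_proportions = cluster_proportions,
              histologies = histologies,
              histology_purity = histology_purity, n_events = n_events,
              concentration = concentration, cluster_dpsi = cluster_dpsi,
              frac_informative = frac_informative,
              planted_frac = planted_frac,
              planted_frac_range = planted_frac_range, delta = delta,
              mean_total_reads = mean_total_reads,
              reads_sdlog = reads_sdlog, inc_form_len = inc_form_len,
              skip_form_len = skip_form_len, n_sf_genes = n_sf_genes,
              sf_coupling = sf_coupling, n_celltypes = n_celltypes,
              markers_per_type = markers_per_type,
              marker_strength = marker_strength,
              baseline_hazard = baseline_hazard,
              cluster_loghr = cluster_loghr, psi_loghr = psi_loghr,
              resection_loghr = resection_loghr, censor_rate = censor_rate,
              n_filler_genes = n_filler_genes,
              candidate_n_samples = candidate_n_samples,
              lowrec_n_samples = lowrec_n_samples,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Draw junction counts whose length-normalized PSI is unbiased for psi:
# inclusion reads are over-represented by the form-length ratio, so draw
# ijc ~ Binomial(n, p) with p = psi L_i / (psi L_i + (1 - psi) L_s).
.draw_counts <- function(psi, n_total, li, ls) {
  p <- psi * li / (psi * li + (1 - psi) * ls)
  ijc <- stats::rbinom(length(psi), n_total, p)
  cbind(ijc = ijc, sjc = n_total - ijc)
}

#' Simulate a synthetic splicing cohort with planted ground truth
#'
#' Generates, fully in memory: per-sample rMATS-dialect event tables
#' (the bulk synthetic events plus the toy annotation's planted cascade
#' events), a clinical manifest, a TPM expression matrix with
#' burden-coupled splicing-factor genes and cell-type marker genes, the toy
#' annotation, and a `truth` bundle recording every planted quantity.
#'
#' @param config From [sim_config()].
#' @return List of class `sim_cohort`: `tables` (named per-sample list of
#'   rMATS-dialect tables), `manifest`, `tpm`, `marker_sets`, `annotation`,
#'   `truth`, `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ann <- simulate_annotation(config)
  set.seed(config$seed)
  ns <- config$n_samples
  samples <- sprintf("S%04d", seq_len(ns))
  cl <- sample(seq_len(config$n_clusters), ns, replace = TRUE,
               prob = config$cluster_proportions)

  age <- round(stats::runif(ns, 0.5, 20), 2)

  # ---- bulk events ------------------------------------------------------
  bulk <- .simulate_bulk_events(config, samples, cl)

  # ---- planted cascade events from the annotation -----------------------
  # (the candidate exon's inclusion declines with age: oncofetal pattern)
  pl <- .simulate_planted_events(config, ann, samples, age)

  # ---- per-sample rMATS tables ------------------------------------------
  tables <- lapply(seq_len(ns), function(j) {
    data.table::rbindlist(list(.bulk_sample_table(bulk, config, j),
                               .planted_sample_table(pl, config, j)),
                          fill = TRUE)
  })
  tables <- lapply(tables, as.data.frame)
  names(tables) <- samples

  # ---- clinical manifest and survival -----------------------------------
  hist_lab <- vapply(cl, function(k) {
    if (stats::runif(1) < config$histology_purity) {
      config$histologies[k]
    } else {
      sample(config$histologies[-k], 1)
    }
  }, character(1))
  subtype <- paste0(hist_lab, "_", sample(c("a", "b"), ns, replace = TRUE))
  resection <- sample(c("gross/near total", "partial", "biopsy"), ns,
                      replace = TRUE, prob = c(0.5, 0.3, 0.2))
  res_idx <- match(resection, c("gross/near total", "partial", "biopsy"))
  burden <- bulk$planted_frac
  tmb <- exp(stats::rnorm(ns, log(2), 0.8) +
               0.1 * as.numeric(scale(burden)))
  hyper <- stats::runif(ns) < 0.02
  tmb[hyper] <- tmb[hyper] * 20

  cand_psi <- pl$target_psi[pl$events$role == "candidate", ]

  lp <- config$cluster_loghr[cl] +
    config$psi_loghr * (cand_psi - mean(cand_psi)) +
    config$resection_loghr[res_idx]
  draw_surv <- function(mult) {
    t_ev <- stats::rexp(ns, rate = config$baseline_hazard * mult * exp(lp))
    c_rate <- config$baseline_hazard * mult *
      config$censor_rate / (1 - config$censor_rate)
    t_c <- stats::rexp(ns, rate = c_rate)
    data.frame(time = round(pmin(t_ev, t_c)) + 1, status = as.integer(t_ev <= t_c))
  }
  os <- draw_surv(1)
  efs <- draw_surv(1.3)
  manifest <- data.frame(
    sample = samples, histology = hist_lab, molecular_subtype = subtype,
    age = age, resection = resection, OS_days = os$time,
    OS_status = os$status, EFS_days = efs$time, EFS_status = efs$status,
    TMB = round(tmb, 3), stringsAsFactors = FALSE)

  # ---- expression -------------------------------------------------------
  expr <- .simulate_expression(config, ann, samples, burden)

  truth <- list(
    cluster = stats::setNames(cl, samples),
    planted_frac = stats::setNames(burden, samples),
    differential = rbind(bulk$diff_truth, pl$diff_truth),
    candidate_keys = pl$events$event_key[pl$events$role == "candidate"],
    planted_event_roles = pl$events[, c("event_key", "role", "n_planted")],
    celltype_fractions = expr$fractions,
    sf_genes = expr$sf_genes,
    candidate_psi = stats::setNames(cand_psi, samples),
    survival = list(baseline_hazard = config$baseline_hazard,
                    cluster_loghr = config$cluster_loghr,
                    psi_loghr = config$psi_loghr,
                    resection_loghr = config$resection_loghr))
  structure(list(tables = tables, manifest = manifest, tpm = expr$tpm,
                 marker_sets = expr$marker_sets, annotation = ann,
                 truth = truth, config = config),
            class = "sim_cohort")
}

# Bulk synthetic events: cluster-informative + null + planted outliers.
.simulate_bulk_events <- function(config, samples, cl) {
  ns <- length(samples)
  counts <- config$n_events
  types <- rep(names(counts), counts)
  ne <- length(types)
  # synthetic coordinates: one locus per event on chrS, with each event
  # class carrying its native rMATS coordinate columns
  start <- 1000L + 4000L * (seq_len(ne) - 1L)
  exon_len <- 100L + 3L * (seq_len(ne) %% 50L)
  strand <- ifelse(seq_len(ne) %% 2 == 0, "+", "-")
  base_df <- data.frame(
    ID = seq_len(ne), GeneID = sprintf("G_SYN%05d", seq_len(ne)),
    geneSymbol = sprintf("SYN%05d", seq_len(ne)), chr = "chrS",
    strand = strand, stringsAsFactors = FALSE)
  blocks <- lapply(unique(types), function(et) {
    i <- which(types == et)
    b <- base_df[i, , drop = FALSE]
    s <- start[i]; le <- exon_len[i]
    co <- switch(
      et,
      SE = data.frame(exonStart_0base = s, exonEnd = s + le,
                      upstreamES = s - 1000L, upstreamEE = s - 900L,
                      downstreamES = s + le + 900L,
                      downstreamEE = s + le + 1000L),
      A5SS = ,
      A3SS = data.frame(longExonStart_0base = s, longExonEnd = s + le + 48L,
                        shortES = s, shortEE = s + le,
                        flankingES = s + le + 500L,
                        flankingEE = s + le + 600L),
      RI = data.frame(riExonStart_0base = s, riExonEnd = s + le + 300L,
                      upstreamES = s, upstreamEE = s + le,
                      downstreamES = s + le + 200L,
                      downstreamEE = s + le + 300L),
      MXE = data.frame(X1stExonStart_0base = s, X1stExonEnd = s + le,
                       X2ndExonStart_0base = s + le + 200L,
                       X2ndExonEnd = s + le + 300L,
                       upstreamES = s - 1000L, upstreamEE = s - 900L,
                       downstreamES = s + le + 900L,
                       downstreamEE = s + le + 1000L))
    b <- cbind(b, co)
    b$event_type <- et
    b$event_key <- splice_event_key(et, b$chr, b$strand,
                                    b[.rmats_coord_cols[[et]]])
    b$row_index <- i
    b
  })
  static <- as.data.frame(data.table::rbindlist(blocks, fill = TRUE))
  static <- static[order(static$row_index), ]
  static$row_index <- NULL
  rownames(static) <- NULL
  static <- .variable_region(static)

  lo <- 0.05 + config$cluster_dpsi / 2
  hi <- 0.95 - config$cluster_dpsi / 2
  base <- stats::runif(ne, 0.05, 0.95)
  n_inf <- round(config$frac_informative * ne)
  inf_idx <- if (n_inf > 0) seq_len(n_inf) else integer(0)
  M <- matrix(base, ne, ns)
  if (n_inf > 0) {
    base_inf <- stats::runif(n_inf, lo, hi)
    updown <- matrix(sample(c(-0.5, 0.5), n_inf * config$n_clusters,
                            replace = TRUE), n_inf, config$n_clusters)
    clmeans <- base_inf + updown * config$cluster_dpsi
    M[inf_idx, ] <- clmeans[, cl, drop = FALSE]
    base[inf_idx] <- base_inf
  }

  # planted outliers: per-sample fraction varies to give distinct burdens;
  # planted only on non-informative events so truth is unambiguous
  f_range <- config$planted_frac * config$planted_frac_range
  f_i <- stats::runif(ns, f_range[1], f_range[2])
  null_idx <- setdiff(seq_len(ne), inf_idx)
  diff_truth <- NULL
  if (config$planted_frac > 0 && length(null_idx) > 0) {
    n_pl <- pmin(round(f_i * ne), length(null_idx))
    ev_pl <- unlist(lapply(n_pl, function(k) sample(null_idx, k)))
    sm_pl <- rep(seq_len(ns), n_pl)
    m0 <- M[cbind(ev_pl, sm_pl)]
    up_ok <- m0 + config$delta <= 0.99
    dn_ok <- m0 - config$delta >= 0.01
    sgn <- ifelse(up_ok & dn_ok,
                  sample(c(-1, 1), length(m0), replace = TRUE),
                  ifelse(up_ok, 1, -1))
    M[cbind(ev_pl, sm_pl)] <- m0 + sgn * config$delta
    diff_truth <- data.frame(
      sample = samples[sm_pl], event_key = static$event_key[ev_pl],
      true_dpsi = sgn * config$delta,
      direction = ifelse(sgn > 0, "inclusion", "skipping"),
      stringsAsFactors = FALSE)
    f_true <- n_pl / ne
  } else {
    f_true <- rep(0, ns)
    diff_truth <- data.frame(sample = character(), event_key = character(),
                             true_dpsi = numeric(), direction = character())
  }

  c_ <- config$concentration
  psi <- matrix(stats::rbeta(ne * ns, M * c_, (1 - M) * c_), ne, ns)
  psi <- pmin(pmax(psi, 1e-6), 1 - 1e-6)
  n_tot <- matrix(
    pmax(1L, round(stats::rlnorm(ne * ns, log(config$mean_total_reads),
                                 config$reads_sdlog))), ne, ns)
  cnt <- .draw_counts(as.vector(psi), as.vector(n_tot),
                      config$inc_form_len, config$skip_form_len)
  list(static = static,
       ijc = matrix(cnt[, "ijc"], ne, ns),
       sjc = matrix(cnt[, "sjc"], ne, ns),
       planted_frac = f_true, diff_truth = diff_truth)
}

# Planted cascade events: high-inclusion events on annotated genes with
# skipping planted in a fixed number of samples each. The candidate
# event's base inclusion declines with age (oncofetal pattern).
.simulate_planted_events <- function(config, ann, samples, age) {
  ev <- ann$planted_events
  ns <- length(samples)
  ne <- nrow(ev)
  M <- matrix(rep(ev$base_mean, ns), ne, ns)
  cand <- which(ev$role == "candidate")
  for (i in cand) {
    M[i, ] <- pmin(0.95, pmax(0.05, M[i, ] - 0.006 * (age - 10)))
  }
  rows <- list()
  for (i in seq_len(ne)) {
    picked <- sample(seq_len(ns), ev$n_planted[i])
    M[i, picked] <- M[i, picked] - config$delta
    rows[[i]] <- data.frame(
      sample = samples[picked], event_key = ev$event_key[i],
      true_dpsi = -config$delta, direction = "skipping",
      stringsAsFactors = FALSE)
  }
  c_ <- config$concentration
  psi <- matrix(stats::rbeta(ne * ns, M * c_, (1 - M) * c_), ne, ns)
  psi <- pmin(pmax(psi, 1e-6), 1 - 1e-6)
  n_tot <- matrix(
    pmax(1L, round(stats::rlnorm(ne * ns, log(config$mean_total_reads),
                                 config$reads_sdlog))), ne, ns)
  cnt <- .draw_counts(as.vector(psi), as.vector(n_tot),
                      config$inc_form_len, config$skip_form_len)
  list(events = ev, target_psi = M,
       ijc = matrix(cnt[, "ijc"], ne, ns),
       sjc = matrix(cnt[, "sjc"], ne, ns),
       diff_truth = do.call(rbind, rows))
}

.attach_counts <- function(static, ijc, sjc, config) {
  static$IJC_SAMPLE_1 <- ijc
  static$SJC_SAMPLE_1 <- sjc
  static$IncFormLen <- config$inc_form_len
  static$SkipFormLen <- config$skip_form_len
  static$IncLevel1 <- compute_psi(ijc, sjc, config$inc_form_len,
                                  config$skip_form_len)
  static
}

.bulk_sample_table <- function(bulk, config, j) {
  .attach_counts(bulk$static, bulk$ijc[, j], bulk$sjc[, j], config)
}

.planted_sample_table <- function(pl, config, j) {
  ev <- pl$events
  tab <- .attach_counts(ev[, setdiff(names(ev),
                                     c("role", "n_planted", "base_mean"))],
                        pl$ijc[, j], pl$sjc[, j], config)
  tab
}

# TPM matrix: annotation genes at their base expression, SF genes coupled
# to the planted burden, marker genes driven by Dirichlet cell-type
# fractions.
.simulate_expression <- function(config, ann, samples, burden) {
  ns <- length(samples)
  sf_genes <- sprintf("SF%03d", seq_len(config$n_sf_genes))
  marker_sets <- lapply(seq_len(config$n_celltypes), function(t) {
    sprintf("MK_T%d_%d", t, seq_len(config$markers_per_type))
  })
  names(marker_sets) <- sprintf("celltype%d", seq_len(config$n_celltypes))

  # Dirichlet(2,...,2) fractions per sample
  g <- matrix(stats::rgamma(ns * config$n_celltypes, shape = 2), ns)
  fractions <- g / rowSums(g)
  rownames(fractions) <- samples
  colnames(fractions) <- names(marker_sets)

  rows <- list()
  add <- function(gene, l2) rows[[length(rows) + 1]] <<-
    stats::setNames(data.frame(gene, t(l2)), c("gene", samples))
  zb <- as.numeric(scale(burden))
  for (i in seq_len(nrow(ann$genes))) {
    base <- log2(ann$genes$base_tpm[i] + 1)
    add(ann$genes$gene[i], base + stats::rnorm(ns, 0, 0.2))
  }
  for (g_ in sf_genes) {
    base <- stats::runif(1, 2, 6)
    add(g_, base + config$sf_coupling * zb + stats::rnorm(ns, 0, 0.4))
  }
  for (t in seq_len(config$n_celltypes)) {
    for (g_ in marker_sets[[t]]) {
      base <- stats::runif(1, 2, 5)
      add(g_, base + config$marker_strength * fractions[, t] +
            stats::rnorm(ns, 0, 0.3))
    }
  }
  df <- do.call(rbind, rows)
  tpm <- as.matrix(df[, -1])
  rownames(tpm) <- df$gene
  tpm <- pmax(2^tpm - 1, 0)
  list(tpm = tpm, marker_sets = marker_sets, fractions = fractions,
       sf_genes = sf_genes)
}

#' Write a simulated cohort to disk as analysis-ready fixtures
#'
#' Writes per-sample rMATS-dialect tables (`rmats/<sample>/<TYPE>.MATS.JC.txt`),
#' the manifest, the TPM matrix, marker sets, the toy annotation (GTF,
#' features, gene lists), and the ground truth (under `truth/`, never
#' consumed by the pipeline itself).
#'
#' @param cohort From [simulate_cohort()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rm_dir <- file.path(dir, "rmats")
  for (s in names(cohort$tables)) {
    sd <- file.path(rm_dir, s)
    dir.create(sd, recursive = TRUE, showWarnings = FALSE)
    tab <- cohort$tables[[s]]
    for (et in unique(tab$event_type)) {
      write_sample_events(tab[tab$event_type == et, , drop = FALSE],
                          file.path(sd, sprintf("%s.MATS.JC.txt", et)))
    }
  }
  utils::write.table(cohort$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tpm_df <- data.frame(gene = rownames(cohort$tpm),
                       round(cohort$tpm, 4), check.names = FALSE)
  utils::write.table(tpm_df, file.path(dir, "tpm.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mk <- do.call(rbind, lapply(names(cohort$marker_sets), function(ct) {
    data.frame(celltype = ct, gene = cohort$marker_sets[[ct]])
  }))
  utils::write.table(mk, file.path(dir, "marker_sets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = cohort$truth$sf_genes),
                     file.path(dir, "sf_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_annotation(cohort$annotation, dir)
  td <- file.path(dir, "truth")
  dir.create(td, showWarnings = FALSE)
  tr <- cohort$truth
  utils::write.table(
    data.frame(sample = names(tr$cluster), cluster = tr$cluster,
               planted_frac = tr$planted_frac),
    file.path(td, "sample_truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(tr$differential, file.path(td, "differential.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tr$planted_event_roles,
                     file.path(td, "planted_events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(tr$candidate_keys, file.path(td, "candidate_keys.txt"))
  invisible(dir)
}

#' Read cohort fixtures written by [write_cohort()]
#'
#' @param dir Fixture directory.
#' @return List: `tables` (per-sample rMATS tables), `manifest`, `tpm`,
#'   `marker_sets`, `models`, `features`, `kinases`, `splicing_kinases`.
#' @export
read_cohort <- function(dir) {
  rm_dir <- file.path(dir, "rmats")
  samples <- sort(list.dirs(rm_dir, recursive = FALSE, full.names = FALSE))
  tables <- lapply(samples, function(s) {
    fs <- list.files(file.path(rm_dir, s), pattern = "\\.MATS\\.JC\\.txt$",
                     full.names = TRUE)
    as.data.frame(data.table::rbindlist(lapply(fs, function(f) {
      read_sample_events(f, sub("\\.MATS\\.JC\\.txt$", "", basename(f)))
    }), fill = TRUE))
  })
  names(tables) <- samples
  tpm_df <- utils::read.delim(file.path(dir, "tpm.tsv"),
                              check.names = FALSE)
  tpm <- as.matrix(tpm_df[, -1]); rownames(tpm) <- tpm_df$gene
  mk <- utils::read.delim(file.path(dir, "marker_sets.tsv"))
  marker_sets <- split(mk$gene, mk$celltype)
  list(tables = tables,
       manifest = utils::read.delim(file.path(dir, "manifest.tsv"),
                                    stringsAsFactors = FALSE),
       tpm = tpm, marker_sets = marker_sets,
       models = read_transcript_models(file.path(dir,
                                                 "toy_annotation.gtf")),
       features = read_features(file.path(dir, "protein_features.tsv")),
       kinases = utils::read.delim(file.path(dir,
                                             "kinase_genes.tsv"))$gene,
       splicing_kinases = utils::read.delim(
         file.path(dir, "splicing_kinase_genes.tsv"))$gene)
}
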