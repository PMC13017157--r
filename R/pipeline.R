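# End-to-end orchestration: fixtures -> PSI -> differential -> burden ->
# clustering -> prioritization -> outcomes, with a machine-readable report.

#' Pipeline configuration
#'
#' Collects input paths, thresholds (each defaulting to the analysis'
#' canonical value), and mode switches. Thresholds: junction-read coverage
#' `min_reads = 10`, call thresholds `z = 2` and `dpsi = 0.2`,
#' recurrence >= 2, top 5000 variable events, 10 clusters, cascade
#' expression TPM > 10 and recurrence > 10 tumors.
#'
#' @param input_dir Fixture directory as written by [write_cohort()] (or
#'   assembled by hand in the same layout).
#' @param output_dir Run directory for all stage outputs.
#' @param min_reads,z_thresh,dpsi_thresh,min_recurrence,min_cohort_n
#'   Differential thresholds.
#' @param top_k,n_clusters,min_coverage_frac Clustering parameters.
#' @param tpm_threshold,recurrence_threshold Cascade thresholds.
#' @param stats_mode `"full"` or `"loo"` cohort statistics.
#' @param distance,linkage Clustering modes.
#' @param seed Seed recorded in the report (the pipeline itself is
#'   deterministic).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            min_reads = 10, z_thresh = 2,
                            dpsi_thresh = 0.2, min_recurrence = 2,
                            min_cohort_n = 10, top_k = 5000,
                            n_clusters = 10, min_coverage_frac = 0.75,
                            tpm_threshold = 10, recurrence_threshold = 10,
                            stats_mode = c("full", "loo"),
                            distance = c("euclidean", "pearson"),
                            linkage = c("ward", "average"),
                            seed = 1) {
  thr <- c(min_reads = min_reads, z_thresh = z_thresh,
           dpsi_thresh = dpsi_thresh, min_recurrence = min_recurrence,
           min_cohort_n = min_cohort_n, top_k = top_k,
           n_clusters = n_clusters, min_coverage_frac = min_coverage_frac,
           tpm_threshold = tpm_threshold,
           recurrence_threshold = recurrence_threshold)
  if (any(thr <= 0)) {
    stop("non-positive threshold(s): ",
         paste(names(thr)[thr <= 0], collapse = ", "))
  }
  cfg <- list(input_dir = input_dir, output_dir = output_dir,
              min_reads = min_reads, z_thresh = z_thresh,
              dpsi_thresh = dpsi_thresh, min_recurrence = min_recurrence,
              min_cohort_n = min_cohort_n, top_k = top_k,
              n_clusters = n_clusters,
              min_coverage_frac = min_coverage_frac,
              tpm_threshold = tpm_threshold,
              recurrence_threshold = recurrence_threshold,
              stats_mode = match.arg(stats_mode),
              distance = match.arg(distance), linkage = match.arg(linkage),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

# Hash of the semantically relevant configuration (everything except the
# output directory).
config_hash <- function(config) {
  sem <- unclass(config)
  sem$output_dir <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(sem[order(names(sem))]), collapse = ""), f)
  unname(tools::md5sum(f))
}

.required_inputs <- function(input_dir) {
  c(rmats = file.path(input_dir, "rmats"),
    manifest = file.path(input_dir, "manifest.tsv"),
    tpm = file.path(input_dir, "tpm.tsv"),
    gtf = file.path(input_dir, "toy_annotation.gtf"),
    features = file.path(input_dir, "protein_features.tsv"),
    kinases = file.path(input_dir, "kinase_genes.tsv"),
    splicing_kinases = file.path(input_dir, "splicing_kinase_genes.tsv"),
    marker_sets = file.path(input_dir, "marker_sets.tsv"),
    sf_genes = file.path(input_dir, "sf_genes.tsv"))
}

#' Run the full analysis pipeline
#'
#' Executes all stages in dependency order, writes every stage's table
#' under `config$output_dir`, and a `report.json` with the configuration
#' hash and per-stage row counts. Reruns with the same configuration and
#' inputs reproduce identical outputs. Any stage error aborts with the
#' stage name; outputs written before the failure persist.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with the main in-memory results and the
#'   report.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- .required_inputs(config$input_dir)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop("missing input path(s): ", paste(missing, collapse = ", "))
  }
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out, "pipeline.log")
  cat("", file = logf)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch({
      r <- force(expr)
      n <- if (is.data.frame(r)) nrow(r) else
        if (inherits(r, "psi_matrix")) nrow(r$psi) else length(r)
      counts[[name]] <<- n
      cat(sprintf("stage %-18s rows=%s\n", name, n), file = logf,
          append = TRUE)
      r
    }, error = function(e) {
      cat(sprintf("stage %-18s ERROR: %s\n", name, conditionMessage(e)),
          file = logf, append = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  wt <- function(d, f) {
    utils::write.table(d, file.path(out, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    d
  }

  cohort <- stage("io", read_cohort(config$input_dir))
  sf_genes <- utils::read.delim(inputs[["sf_genes"]])$gene

  pm <- stage("psi_matrix",
              assemble_psi_matrix(cohort$tables,
                                  min_reads = config$min_reads))
  write_psi_matrix(pm, file.path(out, "psi_matrix.tsv"),
                   file.path(out, "psi_coverage.tsv"))

  st <- cohort_event_stats(pm, mode = config$stats_mode,
                           min_cohort_n = config$min_cohort_n)
  calls <- stage("differential",
                 call_differential(pm, st, z_thresh = config$z_thresh,
                                   dpsi_thresh = config$dpsi_thresh))
  wt(calls, "calls.tsv")
  rec <- stage("recurrence",
               recurrence(calls, min_recurrence = config$min_recurrence))
  wt(rec, "recurrent.tsv")
  hs <- stage("histology_specific",
              histology_specific(rec, calls, cohort$manifest)$per_histology)
  wt(hs, "histology_specific.tsv")

  sbi <- stage("sbi", assign_sbi_groups(compute_sbi(calls, pm, st)))
  wt(sbi, "sbi.tsv")
  mf <- cohort$manifest[match(sbi$sample, cohort$manifest$sample), ]
  tmb_cor <- stage("tmb_correlation",
                   grouped_correlation(mf$TMB, sbi$sbi))
  wt(tmb_cor, "tmb_correlation.tsv")
  sf_assoc <- stage("sf_association",
                    sf_expression_association(cohort$tpm, sbi, sf_genes))
  wt(sf_assoc, "sf_association.tsv")

  top <- stage("top_variable",
               top_variable_events(pm, k = config$top_k,
                                   min_coverage_frac =
                                     config$min_coverage_frac))
  cl <- stage("clustering",
              cluster_samples(pm, k = config$n_clusters,
                              subset_events = top,
                              distance = config$distance,
                              linkage = config$linkage)$cluster)
  wt(data.frame(sample = names(cl), cluster = cl), "clusters.tsv")
  enr <- stage("enrichment",
               cluster_enrichment(cl, stats::setNames(mf$histology,
                                                      mf$sample)))
  wt(enr, "enrichment.tsv")
  scores <- stage("celltype_scores",
                  celltype_scores(cohort$tpm, cohort$marker_sets))
  wt(data.frame(sample = rownames(scores), scores), "celltype_scores.tsv")
  ve <- stage("variance_explained",
              psi_variance_explained(pm, scores, subset_events = top))
  wt(ve, "variance_explained.tsv")
  sbi_sf_cor <- stage(
    "sbi_sf_correlation",
    grouped_correlation(rep(sbi$sbi, length(sf_genes)),
                        as.vector(t(log2(cohort$tpm[sf_genes, sbi$sample,
                                                    drop = FALSE] + 1))),
                        grouping = rep(sf_genes, each = nrow(sbi))))
  wt(sbi_sf_cor, "sbi_sf_correlation.tsv")

  imp <- stage("feature_impacts",
               affected_features(rec, pm$events, cohort$models,
                                 cohort$features))
  wt(imp, "impacts.tsv")
  full_casc <- run_cascade(rec, pm$events, imp, cohort$tpm,
                           kinases = cohort$kinases,
                           splicing_kinase_list = cohort$splicing_kinases,
                           tpm_threshold = config$tpm_threshold,
                           recurrence_threshold =
                             config$recurrence_threshold,
                           models = cohort$models)
  casc <- stage("cascade", full_casc$candidates)
  wt(casc, "candidates.tsv")
  wt(full_casc$stages, "cascade_stages.tsv")

  surv <- data.frame(
    time = mf$OS_days, status = mf$OS_status,
    cluster = stats::relevel(factor(cl[mf$sample]), ref = "1"),
    resection = stats::relevel(factor(mf$resection),
                               ref = "gross/near total"),
    age = mf$age, sbi = sbi$sbi)
  cox_cl <- stage("cox_cluster",
                  fit_cox(surv, ~ cluster + resection + age)$terms)
  wt(cox_cl, "cox_cluster.tsv")
  cox_int <- stage("cox_sbi_interaction",
                   fit_cox(surv, ~ cluster * sbi + resection + age)$terms)
  wt(cox_int, "cox_sbi_interaction.tsv")
  cox_psi <- NULL
  if (nrow(casc) > 0) {
    key <- casc$event_key[1]
    psi_cand <- pm$psi[key, mf$sample]
    ok <- !is.na(psi_cand)
    sp <- cbind(surv[ok, ],
                histology = collapse_small_levels(mf$histology[ok]),
                psi = psi_cand[ok])
    cox_psi <- stage("cox_candidate_psi",
                     fit_cox(sp, ~ psi + resection + histology + age)$terms)
    wt(cox_psi, "cox_candidate_psi.tsv")
  }

  report <- list(
    package_version = as.character(utils::packageVersion("spliceburden")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_hash = config_hash(config),
    seed = config$seed,
    stage_rows = counts)
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(psi = pm, calls = calls, recurrent = rec, sbi = sbi,
                 clusters = cl, enrichment = enr, candidates = casc,
                 cascade_stages = full_casc$stages, cox_cluster = cox_cl,
                 cox_sbi_interaction = cox_int,
                 cox_candidate_psi = cox_psi, report = report))
}
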