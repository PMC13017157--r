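# Feature-impact annotation and the kinase/expression/recurrence
# prioritization cascade.

#' Default splicing-kinase gene set
#'
#' Kinases with established roles in splicing regulation, used as the
#' default stage-4 restriction of [run_cascade()].
#' @return Character vector of 11 gene symbols.
#' @export
splicing_kinases <- function() {
  c("CLK1", "CLK2", "CLK3", "CLK4", "FASTK", "MARK2", "PKN2", "PRKDC",
    "SMG1", "SRPK1", "SRPK3")
}

#' Protein features impacted by recurrent splice events
#'
#' For every transcript model of an event's gene, projects the event's
#' variable genomic region onto amino-acid coordinates
#' ([genomic_to_protein()]) and intersects it with the gene's annotated
#' protein features. A feature is impacted iff its amino-acid interval
#' intersects the projection, except disulfide bonds, which are impacted iff
#' either bonded endpoint residue lies in the projection. The predicted
#' consequence follows the event's cohort direction class: inclusion ->
#' gain, skipping -> loss, mixed -> mixed. Impacts are reported per model
#' and unioned over models downstream.
#'
#' @param recurrent From [recurrence()], with a `direction_class` column.
#' @param events Event metadata (the `events` element of a `psi_matrix`):
#'   needs event_key, event_type, geneSymbol, chrom, var_start, var_end.
#' @param models From [read_transcript_models()].
#' @param features `data.frame` with columns gene, transcript (may be NA),
#'   feature_type (`domain`, `disulfide_bond`, `localization_signal`,
#'   `modified_residue`), feature_id, aa_start, aa_end.
#' @param event_types_mapped Event classes projected onto protein; MXE is
#'   excluded by default (its two-exon semantics do not reduce to one
#'   variable region).
#' @return `data.frame`: event_key, gene, transcript_id, feature_id,
#'   feature_type, feature_aa_start, feature_aa_end, proj_aa_start,
#'   proj_aa_end, predicted.
#' @export
affected_features <- function(recurrent, events, models, features,
                              event_types_mapped = c("SE", "A5SS", "A3SS",
                                                     "RI")) {
  ev <- events[match(recurrent$event_key, events$event_key), , drop = FALSE]
  models_by_gene <- split(models, vapply(models, `[[`, "", "gene"))
  pred_of <- c(inclusion = "gain", skipping = "loss", mixed = "mixed")
  rows <- list()
  for (i in seq_len(nrow(recurrent))) {
    if (!(ev$event_type[i] %in% event_types_mapped)) next
    gene <- ev$geneSymbol[i]
    mods <- models_by_gene[[gene]]
    if (is.null(mods)) next
    feats <- features[features$gene == gene, , drop = FALSE]
    if (nrow(feats) == 0) next
    for (m in mods) {
      if (m$chrom != ev$chr[i]) next
      proj <- genomic_to_protein(c(ev$var_start[i], ev$var_end[i]), m)
      if (is.null(proj)) next
      fm <- feats[is.na(feats$transcript) | feats$transcript == "" |
                    feats$transcript == m$transcript_id, , drop = FALSE]
      if (nrow(fm) == 0) next
      bond <- fm$feature_type == "disulfide_bond"
      hit_span <- fm$aa_start <= proj["aa_end"] &
        fm$aa_end >= proj["aa_start"]
      in_proj <- function(p) p >= proj["aa_start"] & p <= proj["aa_end"]
      hit_bond <- in_proj(fm$aa_start) | in_proj(fm$aa_end)
      hit <- ifelse(bond, hit_bond, hit_span)
      if (!any(hit)) next
      fh <- fm[hit, , drop = FALSE]
      rows[[length(rows) + 1]] <- data.frame(
        event_key = recurrent$event_key[i], gene = gene,
        transcript_id = m$transcript_id, feature_id = fh$feature_id,
        feature_type = fh$feature_type, feature_aa_start = fh$aa_start,
        feature_aa_end = fh$aa_end,
        proj_aa_start = unname(proj["aa_start"]),
        proj_aa_end = unname(proj["aa_end"]),
        predicted = unname(pred_of[recurrent$direction_class[i]]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(event_key = character(), gene = character(),
                      transcript_id = character(), feature_id = character(),
                      feature_type = character(),
                      feature_aa_start = integer(),
                      feature_aa_end = integer(), proj_aa_start = integer(),
                      proj_aa_end = integer(), predicted = character())
  }
  rownames(out) <- NULL
  out
}

# An A5SS/A3SS event is RI-like when its variable region contains an entire
# annotated intron of some model of its gene.
.is_ri_like <- function(ev_row, models_by_gene) {
  mods <- models_by_gene[[ev_row$geneSymbol]]
  if (is.null(mods)) return(FALSE)
  for (m in mods) {
    if (m$chrom != ev_row$chr || nrow(m$exons) < 2) next
    istart <- m$exons[-nrow(m$exons), "end"]
    iend <- m$exons[-1, "start"]
    if (any(istart >= ev_row$var_start & iend <= ev_row$var_end)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Run the functional prioritization cascade
#'
#' Ordered filters over recurrent differential events, with a survivor
#' count recorded after every stage:
#' 1. recurrent differential events (the input);
#' 2. at least one predicted protein-feature impact;
#' 3. gene is a kinase;
#' 4. gene is a splicing-regulatory kinase;
#' 5. expressed: cohort median gene TPM above `tpm_threshold`;
#' 6. recurrent in more than `recurrence_threshold` tumors;
#' 7. not a retained intron, nor an RI-like A5SS/A3SS event whose variable
#'    region spans an entire annotated intron (intron retention measured
#'    from short reads has an elevated false-positive rate).
#'
#' @param recurrent From [recurrence()].
#' @param events Event metadata (the `events` element of a `psi_matrix`).
#' @param impacts From [affected_features()].
#' @param tpm Genes x samples TPM matrix.
#' @param kinases Character vector of kinase gene symbols.
#' @param splicing_kinase_list Stage-4 gene set (default
#'   [splicing_kinases()]).
#' @param tpm_threshold,recurrence_threshold Stage-5/6 thresholds
#'   (defaults 10 / 10, both strict `>`).
#' @param drop_ri Apply stage 7 (default `TRUE`).
#' @param models Transcript models (needed for the RI-like rule; if `NULL`
#'   only annotated RI events are dropped at stage 7).
#' @return List of class `candidate_table`: `stages` (stage, description,
#'   n_events) and `candidates` (final surviving rows joined with their
#'   impacted features).
#' @export
run_cascade <- function(recurrent, events, impacts, tpm,
                        kinases, splicing_kinase_list = splicing_kinases(),
                        tpm_threshold = 10, recurrence_threshold = 10,
                        drop_ri = TRUE, models = NULL) {
  if (length(kinases) == 0) stop("empty kinase list")
  ev <- events[match(recurrent$event_key, events$event_key), , drop = FALSE]
  cur <- recurrent
  cur$gene <- ev$geneSymbol
  cur$event_type <- ev$event_type
  stages <- list()
  note <- function(desc) {
    stages[[length(stages) + 1]] <<- data.frame(
      stage = length(stages) + 1, description = desc,
      n_events = nrow(cur), stringsAsFactors = FALSE)
  }
  note("recurrent differential events")
  cur <- cur[cur$event_key %in% impacts$event_key, , drop = FALSE]
  note("predicted functional-feature impact")
  cur <- cur[cur$gene %in% kinases, , drop = FALSE]
  note("kinase gene")
  cur <- cur[cur$gene %in% splicing_kinase_list, , drop = FALSE]
  note("splicing-regulatory kinase")
  med_tpm <- apply(tpm, 1, stats::median)
  cur <- cur[cur$gene %in% rownames(tpm) &
               med_tpm[cur$gene] > tpm_threshold, , drop = FALSE]
  note(sprintf("median TPM > %g", tpm_threshold))
  cur <- cur[cur$n_samples_called > recurrence_threshold, , drop = FALSE]
  note(sprintf("called in > %d tumors", recurrence_threshold))
  if (drop_ri) {
    is_ri <- cur$event_type == "RI"
    ri_like <- rep(FALSE, nrow(cur))
    if (!is.null(models)) {
      mbg <- split(models, vapply(models, `[[`, "", "gene"))
      alt_ss <- which(cur$event_type %in% c("A5SS", "A3SS"))
      for (j in alt_ss) {
        er <- events[events$event_key == cur$event_key[j], , drop = FALSE]
        ri_like[j] <- .is_ri_like(er[1, ], mbg)
      }
    }
    cur <- cur[!(is_ri | ri_like), , drop = FALSE]
    note("not RI or RI-like")
  }
  cand <- cur
  if (nrow(cand)) {
    feat <- vapply(cand$event_key, function(k) {
      paste(sort(unique(impacts$feature_id[impacts$event_key == k])),
            collapse = ";")
    }, character(1))
    cand$impacted_features <- unname(feat)
  } else {
    cand$impacted_features <- character(0)
  }
  rownames(cand) <- NULL
  structure(list(stages = do.call(rbind, stages), candidates = cand),
            class = "candidate_table")
}

#' @export
print.candidate_table <- function(x, ...) {
  cat("prioritization cascade:\n")
  print(x$stages, row.names = FALSE)
  cat(sprintf("final candidates: %d\n", nrow(x$candidates)))
  if (nrow(x$candidates)) {
    print(x$candidates[, c("event_key", "gene", "direction_class",
                           "n_samples_called")], row.names = FALSE)
  }
  invisible(x)
}
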