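# Synthetic toy genome annotation with planted prioritization ground truth.
#
# The toy genome carries ~50 protein-coding genes with multi-exon contiguous
# CDS on both strands, UniProt-style protein features of four categories, and
# a set of planted splice events designed to exercise every stage of the
# prioritization cascade: one true candidate (a CLK1-like skipped exon whose
# cassette exon lies inside a kinase-domain feature) plus decoys that fail at
# exactly one stage each (non-kinase gene, non-splicing kinase, low
# expression, low recurrence, retained-intron and RI-like events).

# Build one toy gene. Exon coding lengths are multiples of 3; the leftmost
# exon carries a 30 bp UTR at its left edge and the rightmost a 30 bp UTR at
# its right edge, so the CDS is contiguous and frame-closed by construction.
.make_toy_gene <- function(gene, chrom, strand, tss, n_exons, coding_lens,
                           intron_lens, tx_suffix = "-201") {
  stopifnot(length(coding_lens) == n_exons,
            length(intron_lens) == n_exons - 1,
            all(coding_lens %% 3 == 0))
  utr <- 30L
  ex_len <- coding_lens
  ex_len[1] <- ex_len[1] + utr
  ex_len[n_exons] <- ex_len[n_exons] + utr
  starts <- integer(n_exons)
  starts[1] <- tss
  for (i in seq_len(n_exons - 1)) {
    starts[i + 1] <- starts[i] + ex_len[i] + intron_lens[i]
  }
  ends <- starts + ex_len
  cds <- cbind(start = starts, end = ends)
  cds[1, "start"] <- cds[1, "start"] + utr
  cds[n_exons, "end"] <- cds[n_exons, "end"] - utr
  m <- list(transcript_id = paste0(gene, tx_suffix), gene = gene,
            chrom = chrom, strand = strand,
            exons = cbind(start = starts, end = ends), cds = cds)
  m$cds_len <- sum(m$cds[, "end"] - m$cds[, "start"])
  class(m) <- "transcript_model"
  validate_transcript_model(m)
}

# Retained-intron isoform: exons j and j+1 merged, the intron coding.
.retained_intron_model <- function(m, j, tx_suffix = "-202") {
  tail_rows <- function(x) {
    if (j + 1 < nrow(x)) x[seq(j + 2, nrow(x)), , drop = FALSE] else
      x[0, , drop = FALSE]
  }
  ex <- m$exons
  new_ex <- rbind(ex[seq_len(j - 1), , drop = FALSE],
                  c(ex[j, "start"], ex[j + 1, "end"]),
                  tail_rows(ex))
  colnames(new_ex) <- c("start", "end")
  cds <- m$cds
  new_cds <- rbind(cds[seq_len(j - 1), , drop = FALSE],
                   c(cds[j, "start"], cds[j + 1, "end"]),
                   tail_rows(cds))
  colnames(new_cds) <- c("start", "end")
  m2 <- m
  m2$transcript_id <- paste0(m$gene, tx_suffix)
  m2$exons <- new_ex
  m2$cds <- new_cds
  m2$cds_len <- sum(new_cds[, "end"] - new_cds[, "start"])
  class(m2) <- "transcript_model"
  validate_transcript_model(m2)
}

# One rMATS-dialect row (as produced by read_sample_events, minus counts)
# for a cassette-exon event on exon k of a toy model.
.se_event_row <- function(m, k, id) {
  ex <- m$exons
  row <- data.frame(
    ID = id, GeneID = paste0("G_", m$gene), geneSymbol = m$gene,
    chr = m$chrom, strand = m$strand,
    exonStart_0base = ex[k, "start"], exonEnd = ex[k, "end"],
    upstreamES = ex[k - 1, "start"], upstreamEE = ex[k - 1, "end"],
    downstreamES = ex[k + 1, "start"], downstreamEE = ex[k + 1, "end"],
    stringsAsFactors = FALSE)
  row$event_type <- "SE"
  row$event_key <- splice_event_key("SE", row$chr, row$strand,
                                    row[.rmats_coord_cols$SE])
  .variable_region(row)
}

# A5SS-dialect row whose long form reads through intron j and 30 bp into
# exon j+1: the alternative extension contains a full intron (RI-like) and
# overlaps coding sequence.
.a5ss_ri_like_row <- function(m, j, id) {
  ex <- m$exons
  row <- data.frame(
    ID = id, GeneID = paste0("G_", m$gene), geneSymbol = m$gene,
    chr = m$chrom, strand = m$strand,
    longExonStart_0base = ex[j, "start"],
    longExonEnd = ex[j + 1, "start"] + 30L,
    shortES = ex[j, "start"], shortEE = ex[j, "end"],
    flankingES = ex[j + 1, "start"], flankingEE = ex[j + 1, "end"],
    stringsAsFactors = FALSE)
  row$event_type <- "A5SS"
  row$event_key <- splice_event_key("A5SS", row$chr, row$strand,
                                    row[.rmats_coord_cols$A5SS])
  .variable_region(row)
}

# Retained-intron row over intron j.
.ri_event_row <- function(m, j, id) {
  ex <- m$exons
  row <- data.frame(
    ID = id, GeneID = paste0("G_", m$gene), geneSymbol = m$gene,
    chr = m$chrom, strand = m$strand,
    riExonStart_0base = ex[j, "start"], riExonEnd = ex[j + 1, "end"],
    upstreamES = ex[j, "start"], upstreamEE = ex[j, "end"],
    downstreamES = ex[j + 1, "start"], downstreamEE = ex[j + 1, "end"],
    stringsAsFactors = FALSE)
  row$event_type <- "RI"
  row$event_key <- splice_event_key("RI", row$chr, row$strand,
                                    row[.rmats_coord_cols$RI])
  .variable_region(row)
}

.feature_row <- function(gene, transcript, type, id, aa_start, aa_end) {
  data.frame(gene = gene, transcript = transcript, feature_type = type,
             feature_id = id, aa_start = as.integer(aa_start),
             aa_end = as.integer(aa_end), stringsAsFactors = FALSE)
}

# Random features of the four categories, avoiding a reserved aa window.
.random_features <- function(gene, plen, rng_avoid = NULL, n_per_cat = 2) {
  out <- list()
  place <- function(len) {
    for (try in 1:50) {
      s <- sample.int(max(1, plen - len), 1)
      e <- min(plen, s + len - 1)
      if (is.null(rng_avoid) || e < rng_avoid[1] || s > rng_avoid[2]) {
        return(c(s, e))
      }
    }
    NULL
  }
  k <- 0
  for (ft in c("domain", "disulfide_bond", "localization_signal",
               "modified_residue")) {
    for (i in seq_len(n_per_cat)) {
      len <- switch(ft, domain = sample(30:80, 1),
                    disulfide_bond = sample(20:60, 1),
                    localization_signal = sample(10:25, 1),
                    modified_residue = 1)
      pos <- place(len)
      if (is.null(pos)) next
      k <- k + 1
      out[[k]] <- .feature_row(gene, NA_character_, ft,
                               sprintf("%s_%s_%d", gene, ft, i),
                               pos[1], pos[2])
    }
  }
  do.call(rbind, out)
}

#' Simulate a toy genome annotation with planted prioritization truth
#'
#' Builds ~`n_filler_genes` + 8 protein-coding genes (3-10 exons, contiguous
#' CDS, both strands, CDS length divisible by 3), UniProt-style protein
#' features in four categories at known amino-acid positions, kinase gene
#' lists, and a set of planted splice events: a CLK1-like skipped exon whose
#' cassette exon projects inside a kinase-domain feature (the intended
#' cascade survivor) and six decoys, each designed to fail exactly one
#' cascade stage.
#'
#' @param config From [sim_config()]; uses `seed`, `n_filler_genes`,
#'   `candidate_n_samples`, `lowrec_n_samples`.
#' @return List of class `toy_annotation`: `models` (transcript models),
#'   `features`, `genes` (gene table with base TPM), `kinases`,
#'   `splicing_kinases`, `planted_events` (rMATS-dialect rows with
#'   `role`, `n_planted`, `base_mean` columns).
#' @export
simulate_annotation <- function(config) {
  set.seed(config$seed + 1L)
  models <- list()
  features <- list()
  genes <- list()
  add_gene <- function(gene, chrom, strand, n_exons, base_tpm,
                       intron_lens = NULL) {
    coding <- 3L * sample(20:80, n_exons, replace = TRUE)
    if (is.null(intron_lens)) {
      intron_lens <- sample(100:1000, n_exons - 1, replace = TRUE)
    }
    tss <- sample.int(1000000L, 1) + 2000000L * length(genes)
    m <- .make_toy_gene(gene, chrom, strand, tss, n_exons, coding,
                        intron_lens)
    models[[m$transcript_id]] <<- m
    genes[[length(genes) + 1]] <<- data.frame(
      gene = gene, chrom = chrom, strand = strand, base_tpm = base_tpm,
      stringsAsFactors = FALSE)
    m
  }
  proj_of <- function(m, iv) genomic_to_protein(iv, m)
  domain_over <- function(gene, tx, m, iv, id) {
    plen <- m$cds_len / 3
    aa <- proj_of(m, iv)
    .feature_row(gene, tx, "domain", id,
                 max(1, aa["aa_start"] - 3), min(plen, aa["aa_end"] + 3))
  }

  planted <- list()
  nid <- 0
  next_id <- function() { nid <<- nid + 1; nid }

  # true candidate: skipped exon inside a kinase domain, minus strand
  m <- add_gene("CLK1", "chr1", "-", 8, base_tpm = 50)
  k <- 4
  ev <- .se_event_row(m, k, next_id())
  ev$role <- "candidate"; ev$n_planted <- config$candidate_n_samples
  ev$base_mean <- 0.85
  planted[[length(planted) + 1]] <- ev
  features[[length(features) + 1]] <-
    domain_over("CLK1", NA_character_, m, c(m$exons[k, "start"],
                                            m$exons[k, "end"]),
                "CLK1_kinase_domain")
  features[[length(features) + 1]] <- .random_features(
    "CLK1", m$cds_len / 3,
    rng_avoid = proj_of(m, c(m$exons[k, "start"], m$exons[k, "end"])))

  # RI-like alternative 5' splice site in a splicing kinase -> stage 7
  m <- add_gene("CLK3", "chr1", "+", 6, base_tpm = 40)
  j <- 3
  ev <- .a5ss_ri_like_row(m, j, next_id())
  ev$role <- "decoy_ri_like"; ev$n_planted <- config$candidate_n_samples
  ev$base_mean <- 0.85
  planted[[length(planted) + 1]] <- ev
  features[[length(features) + 1]] <-
    domain_over("CLK3", NA_character_, m,
                c(m$exons[j + 1, "start"], m$exons[j + 1, "start"] + 30L),
                "CLK3_domain")

  # retained intron in a splicing kinase; the intron is coding in a second,
  # retained-intron isoform -> stage 7
  m <- add_gene("FASTK", "chr1", "+", 6, base_tpm = 30,
                intron_lens = c(300L, 99L, sample(100:1000, 3)))
  j <- 2                                     # the 99 bp (frame-closed) intron
  m2 <- .retained_intron_model(m, j)
  models[[m2$transcript_id]] <- m2
  ev <- .ri_event_row(m, j, next_id())
  ev$role <- "decoy_ri"; ev$n_planted <- config$candidate_n_samples
  ev$base_mean <- 0.85
  planted[[length(planted) + 1]] <- ev
  features[[length(features) + 1]] <-
    domain_over("FASTK", m2$transcript_id, m2,
                c(m$exons[j, "end"], m$exons[j + 1, "start"]),
                "FASTK_intron_domain")

  # splicing kinase below the expression filter -> stage 5
  m <- add_gene("MARK2", "chr2", "+", 7, base_tpm = 5)
  ev <- .se_event_row(m, 3, next_id())
  ev$role <- "decoy_low_tpm"; ev$n_planted <- config$candidate_n_samples
  ev$base_mean <- 0.85
  planted[[length(planted) + 1]] <- ev
  features[[length(features) + 1]] <-
    domain_over("MARK2", NA_character_, m,
                c(m$exons[3, "start"], m$exons[3, "end"]), "MARK2_domain")

  # splicing kinase below the recurrence filter -> stage 6
  m <- add_gene("SRPK1", "chr2", "-", 6, base_tpm = 25)
  ev <- .se_event_row(m, 4, next_id())
  ev$role <- "decoy_low_recurrence"; ev$n_planted <- config$lowrec_n_samples
  ev$base_mean <- 0.85
  planted[[length(planted) + 1]] <- ev
  features[[length(features) + 1]] <-
    domain_over("SRPK1", NA_character_, m,
                c(m$exons[4, "start"], m$exons[4, "end"]), "SRPK1_domain")

  # kinase without a splicing role -> stage 4
  m <- add_gene("AURKA", "chr2", "+", 5, base_tpm = 30)
  ev <- .se_event_row(m, 3, next_id())
  ev$role <- "decoy_not_splicing_kinase"
  ev$n_planted <- config$candidate_n_samples
  ev$base_mean <- 0.85
  planted[[length(planted) + 1]] <- ev
  features[[length(features) + 1]] <-
    domain_over("AURKA", NA_character_, m,
                c(m$exons[3, "start"], m$exons[3, "end"]), "AURKA_domain")

  # non-kinase gene with a feature impact -> stage 3
  m <- add_gene("NONKIN1", "chr2", "-", 5, base_tpm = 20)
  ev <- .se_event_row(m, 3, next_id())
  ev$role <- "decoy_not_kinase"; ev$n_planted <- config$candidate_n_samples
  ev$base_mean <- 0.85
  planted[[length(planted) + 1]] <- ev
  features[[length(features) + 1]] <-
    domain_over("NONKIN1", NA_character_, m,
                c(m$exons[3, "start"], m$exons[3, "end"]), "NONKIN1_domain")

  # annotated gene without any protein feature -> stage 2
  m <- add_gene("NOFEAT1", "chr2", "+", 4, base_tpm = 20)
  ev <- .se_event_row(m, 2, next_id())
  ev$role <- "decoy_no_feature"; ev$n_planted <- config$candidate_n_samples
  ev$base_mean <- 0.85
  planted[[length(planted) + 1]] <- ev

  # filler genes with random features
  for (i in seq_len(config$n_filler_genes)) {
    g <- sprintf("TOYG%02d", i)
    m <- add_gene(g, sample(c("chr1", "chr2"), 1), sample(c("+", "-"), 1),
                  sample(3:10, 1), base_tpm = round(stats::runif(1, 1, 40)))
    features[[length(features) + 1]] <- .random_features(g, m$cds_len / 3)
  }

  planted <- data.table::rbindlist(planted, fill = TRUE)
  structure(list(
    models = models,
    features = do.call(rbind, features),
    genes = do.call(rbind, genes),
    kinases = c(splicing_kinases(), "AURKA", "EGFR"),
    splicing_kinases = splicing_kinases(),
    planted_events = as.data.frame(planted)),
    class = "toy_annotation")
}

#' Write a toy annotation to disk (GTF, feature TSV, gene lists)
#'
#' @param ann From [simulate_annotation()].
#' @param dir Output directory (created if missing).
#' @return Named list of written paths.
#' @export
write_annotation <- function(ann, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gtf <- file.path(dir, "toy_annotation.gtf")
  lines <- character(0)
  attr_str <- function(gene_id, gene_name, tx = NULL) {
    s <- sprintf('gene_id "%s"; gene_name "%s";', gene_id, gene_name)
    if (!is.null(tx)) s <- sprintf('%s transcript_id "%s";', s, tx)
    s
  }
  for (m in ann$models) {
    gid <- paste0("G_", m$gene)
    span <- c(min(m$exons[, "start"]), max(m$exons[, "end"]))
    lines <- c(lines,
               sprintf("%s\ttoy\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                       m$chrom, span[1] + 1L, span[2], m$strand,
                       attr_str(gid, m$gene, m$transcript_id)))
    for (i in seq_len(nrow(m$exons))) {
      lines <- c(lines,
                 sprintf("%s\ttoy\texon\t%d\t%d\t.\t%s\t.\t%s",
                         m$chrom, m$exons[i, "start"] + 1L, m$exons[i, "end"],
                         m$strand, attr_str(gid, m$gene, m$transcript_id)))
    }
    for (i in seq_len(nrow(m$cds))) {
      lines <- c(lines,
                 sprintf("%s\ttoy\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                         m$chrom, m$cds[i, "start"] + 1L, m$cds[i, "end"],
                         m$strand, attr_str(gid, m$gene, m$transcript_id)))
    }
  }
  writeLines(lines, gtf)
  fp <- file.path(dir, "protein_features.tsv")
  utils::write.table(ann$features, fp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  kp <- file.path(dir, "kinase_genes.tsv")
  utils::write.table(data.frame(gene = ann$kinases), kp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sp <- file.path(dir, "splicing_kinase_genes.tsv")
  utils::write.table(data.frame(gene = ann$splicing_kinases), sp,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(gtf = gtf, features = fp, kinases = kp, splicing_kinases = sp)
}

#' Read a protein-feature table
#'
#' @param path TSV with columns gene, transcript, feature_type, feature_id,
#'   aa_start, aa_end.
#' @return `data.frame` of features.
#' @export
read_features <- function(path) {
  f <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "transcript", "feature_type", "feature_id", "aa_start",
            "aa_end")
  miss <- setdiff(need, names(f))
  if (length(miss)) stop("feature table missing column(s): ",
                         paste(miss, collapse = ", "))
  f
}
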