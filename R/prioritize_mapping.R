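# Transcript models from GTF and genomic -> protein coordinate projection.
#
# Internal convention: 0-based start, exclusive end (the rMATS convention);
# GTF's 1-based inclusive coordinates are converted on read.

#' Read transcript models from a GTF file
#'
#' Parses gene / transcript / exon / CDS records and builds one model per
#' transcript. Coordinates are converted to 0-based half-open intervals.
#'
#' @param path GTF file path.
#' @return Named list (by transcript id) of `transcript_model` objects:
#'   `transcript_id`, `gene`, `chrom`, `strand`, `exons` and `cds` (two-column
#'   matrices of start0/end, sorted by genomic position), `cds_len`.
#' @export
read_transcript_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df$start0 <- df$start - 1L                # to 0-based half-open
  keep <- df$type %in% c("exon", "CDS")
  df <- df[keep, c("seqnames", "start0", "end", "strand", "type",
                   "gene_id", "gene_name", "transcript_id")]
  models <- lapply(split(df, df$transcript_id), function(d) {
    ex <- d[d$type == "exon", ]
    cds <- d[d$type == "CDS", ]
    ex <- ex[order(ex$start0), ]
    cds <- cds[order(cds$start0), ]
    m <- list(
      transcript_id = d$transcript_id[1],
      gene = if (!is.null(d$gene_name) && !is.na(d$gene_name[1]))
        d$gene_name[1] else d$gene_id[1],
      chrom = as.character(d$seqnames[1]),
      strand = as.character(d$strand[1]),
      exons = cbind(start = ex$start0, end = ex$end),
      cds = cbind(start = cds$start0, end = cds$end))
    m$cds_len <- sum(m$cds[, "end"] - m$cds[, "start"])
    class(m) <- "transcript_model"
    validate_transcript_model(m)
  })
  models
}

#' Validate a transcript model
#'
#' Checks the structural invariants: intervals well-formed, exons
#' non-overlapping and sorted, CDS contained in the exon union, CDS length
#' divisible by 3.
#'
#' @param m A `transcript_model`.
#' @return `m`, invisibly usable; errors on violation.
#' @export
validate_transcript_model <- function(m) {
  ivs <- rbind(m$exons, m$cds)
  if (nrow(ivs) == 0) stop("transcript model with no exons: ",
                           m$transcript_id)
  if (any(ivs[, "start"] >= ivs[, "end"])) {
    stop("malformed interval (start >= end) in model ", m$transcript_id)
  }
  ex <- m$exons
  if (nrow(ex) > 1 &&
      any(ex[-1, "start"] < ex[-nrow(ex), "end"])) {
    stop("overlapping or unsorted exons in model ", m$transcript_id)
  }
  if (nrow(m$cds)) {
    if (m$cds_len %% 3 != 0) {
      stop("CDS length not divisible by 3 in model ", m$transcript_id)
    }
    inside <- vapply(seq_len(nrow(m$cds)), function(i) {
      any(m$cds[i, "start"] >= ex[, "start"] &
            m$cds[i, "end"] <= ex[, "end"])
    }, logical(1))
    if (!all(inside)) {
      stop("CDS outside exon union in model ", m$transcript_id)
    }
  }
  m
}

#' Project a genomic interval onto protein (amino-acid) coordinates
#'
#' Intersects the interval with the model's CDS, maps the intersection onto
#' spliced-CDS base offsets (strand-aware: minus-strand transcripts are read
#' right to left), and converts to 1-based inclusive amino-acid positions:
#' `aa_start = floor(first_offset/3) + 1`, `aa_end = floor(last_offset/3) + 1`
#' with 0-based base offsets.
#'
#' @param interval Numeric length-2 `c(start0, end)` (0-based half-open).
#' @param model A `transcript_model` with CDS.
#' @return `c(aa_start, aa_end)`, or `NULL` if the interval does not touch
#'   the CDS.
#' @export
genomic_to_protein <- function(interval, model) {
  validate_transcript_model(model)
  if (nrow(model$cds) == 0) return(NULL)
  qs <- interval[1]; qe <- interval[2]
  if (qs >= qe) stop("malformed query interval")
  cds <- model$cds
  widths <- cds[, "end"] - cds[, "start"]
  # spliced offset of the first (5'-most in transcript orientation) base of
  # each CDS piece
  if (model$strand == "+") {
    piece_off <- cumsum(c(0, widths))[seq_len(nrow(cds))]
  } else {
    rev_w <- rev(widths)
    piece_off <- rev(cumsum(c(0, rev_w))[seq_len(nrow(cds))])
  }
  first <- Inf; last <- -Inf
  for (i in seq_len(nrow(cds))) {
    s <- max(qs, cds[i, "start"]); e <- min(qe, cds[i, "end"])
    if (s >= e) next
    if (model$strand == "+") {
      off1 <- piece_off[i] + (s - cds[i, "start"])
      off2 <- piece_off[i] + (e - 1 - cds[i, "start"])
    } else {
      off1 <- piece_off[i] + (cds[i, "end"] - e)
      off2 <- piece_off[i] + (cds[i, "end"] - 1 - s)
    }
    first <- min(first, off1, off2)
    last <- max(last, off1, off2)
  }
  if (!is.finite(first)) return(NULL)
  c(aa_start = as.integer(first %/% 3 + 1),
    aa_end = as.integer(last %/% 3 + 1))
}
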