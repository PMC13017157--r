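# rMATS-dialect event tables and length-normalized PSI.
#
# Coordinate convention throughout the package: 0-based start ("exonStart_0base"),
# exclusive end, as written by rMATS turbo JC output.

# Per-type coordinate column sets of the rMATS *.MATS.JC.txt dialect.
.rmats_coord_cols <- list(
  SE   = c("exonStart_0base", "exonEnd", "upstreamES", "upstreamEE",
           "downstreamES", "downstreamEE"),
  A5SS = c("longExonStart_0base", "longExonEnd", "shortES", "shortEE",
           "flankingES", "flankingEE"),
  A3SS = c("longExonStart_0base", "longExonEnd", "shortES", "shortEE",
           "flankingES", "flankingEE"),
  RI   = c("riExonStart_0base", "riExonEnd", "upstreamES", "upstreamEE",
           "downstreamES", "downstreamEE"),
  MXE  = c("X1stExonStart_0base", "X1stExonEnd", "X2ndExonStart_0base",
           "X2ndExonEnd", "upstreamES", "upstreamEE", "downstreamES",
           "downstreamEE")
)

.rmats_fixed_cols <- c("ID", "GeneID", "geneSymbol", "chr", "strand")
.rmats_count_cols <- c("IJC_SAMPLE_1", "SJC_SAMPLE_1", "IncFormLen",
                       "SkipFormLen", "IncLevel1")

#' Event types supported by the rMATS dialect
#' @return Character vector of the five rMATS event classes.
#' @export
event_types <- function() names(.rmats_coord_cols)

#' Length-normalized percent spliced in
#'
#' PSI is the length-normalized fraction of transcripts supporting the
#' inclusion form: `(ijc/inc_form_len) / (ijc/inc_form_len + sjc/skip_form_len)`.
#' Vectorized over all arguments.
#'
#' @param ijc,sjc Non-negative integer inclusion / skipping junction counts.
#' @param inc_form_len,skip_form_len Positive effective form lengths.
#' @return Numeric vector in `[0,1]`; `NA` where `ijc + sjc == 0` (PSI is
#'   undefined without junction evidence).
#' @examples
#' compute_psi(10, 10, 2, 1)  # 1/3
#' @export
compute_psi <- function(ijc, sjc, inc_form_len, skip_form_len) {
  stopifnot(all(ijc >= 0), all(sjc >= 0),
            all(inc_form_len >= 1), all(skip_form_len >= 1))
  inc <- ijc / inc_form_len
  skp <- sjc / skip_form_len
  psi <- inc / (inc + skp)
  psi[ijc + sjc == 0] <- NA_real_
  psi
}

#' Deterministic event key
#'
#' Injective over (event type, chromosome, strand, all coordinates), so the
#' same event read from two files yields the same key.
#'
#' @param event_type One of [event_types()].
#' @param chrom,strand Chromosome and strand (`+`/`-`).
#' @param coords Data frame or matrix of the type's coordinate columns.
#' @return Character vector of keys.
#' @export
splice_event_key <- function(event_type, chrom, strand, coords) {
  coords <- as.data.frame(coords)
  if (nrow(coords) == 0) return(character(0))
  do.call(paste, c(list(event_type, chrom, strand), coords, list(sep = ":")))
}

.check_intervals <- function(tab, cols, path) {
  starts <- cols[seq(1, length(cols), 2)]
  ends <- cols[seq(2, length(cols), 2)]
  for (k in seq_along(starts)) {
    bad <- which(tab[[starts[k]]] >= tab[[ends[k]]])
    if (length(bad)) {
      stop(sprintf("malformed coordinates in %s: %s >= %s at data line(s) %s",
                   path, starts[k], ends[k],
                   paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  invisible(TRUE)
}

# Variable (alternatively used) genomic region of each event, 0-based half-open.
# SE: the cassette exon; A5SS/A3SS: the alternative extension segment (long
# form minus short form); RI: the retained intron; MXE: the first exon.
.variable_region <- function(tab) {
  et <- tab$event_type
  vs <- ve <- rep(NA_real_, nrow(tab))
  i <- et == "SE"
  vs[i] <- tab$exonStart_0base[i]; ve[i] <- tab$exonEnd[i]
  i <- et %in% c("A5SS", "A3SS")
  if (any(i)) {
    shares_start <- tab$longExonStart_0base[i] == tab$shortES[i]
    vs[i] <- ifelse(shares_start, tab$shortEE[i], tab$longExonStart_0base[i])
    ve[i] <- ifelse(shares_start, tab$longExonEnd[i], tab$shortES[i])
  }
  i <- et == "RI"
  vs[i] <- tab$upstreamEE[i]; ve[i] <- tab$downstreamES[i]
  i <- et == "MXE"
  vs[i] <- tab$X1stExonStart_0base[i]; ve[i] <- tab$X1stExonEnd[i]
  tab$var_start <- as.integer(vs)
  tab$var_end <- as.integer(ve)
  tab
}

#' Read one sample's rMATS-style event table
#'
#' @param path Path to a `*.MATS.JC.txt`-dialect TSV.
#' @param event_type One of [event_types()]; must match the file's header.
#' @return A `data.frame` with the file's columns plus `event_type`,
#'   `event_key`, and the derived variable region (`var_start`, `var_end`).
#' @export
read_sample_events <- function(path, event_type) {
  event_type <- match.arg(event_type, event_types())
  coord_cols <- .rmats_coord_cols[[event_type]]
  tab <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                         showProgress = FALSE))
  names(tab) <- make.names(names(tab))
  need <- c(.rmats_fixed_cols, coord_cols, .rmats_count_cols)
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop(sprintf("file %s is missing required column(s): %s",
                 path, paste(miss, collapse = ", ")))
  }
  tab <- tab[need]
  for (cc in coord_cols) {
    v <- suppressWarnings(as.integer(tab[[cc]]))
    bad <- which(is.na(v) & !is.na(tab[[cc]]))
    if (length(bad) || anyNA(v)) {
      stop(sprintf("malformed coordinate in %s column %s at data line(s) %s",
                   path, cc,
                   paste(utils::head(which(is.na(v)), 5), collapse = ", ")))
    }
    tab[[cc]] <- v
  }
  .check_intervals(tab, coord_cols, path)
  tab$event_type <- rep(event_type, nrow(tab))
  tab$event_key <- splice_event_key(event_type, tab$chr, tab$strand,
                                    tab[coord_cols])
  if (anyDuplicated(tab$event_key)) {
    stop(sprintf("duplicate event rows in %s", path))
  }
  .variable_region(tab)
}

#' Write one sample's rMATS-style event table
#'
#' Output is byte-stable for a fixed table: fixed column order, integer
#' counts, `IncLevel1` with 6 decimals (`NA` for undefined PSI).
#'
#' @param tab Table as returned by [read_sample_events()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_events <- function(tab, path) {
  event_type <- unique(tab$event_type)
  if (length(event_type) > 1) stop("one event type per file")
  if (nrow(tab) == 0 && !length(event_type)) event_type <- "SE"
  cols <- c(.rmats_fixed_cols, .rmats_coord_cols[[event_type]],
            .rmats_count_cols)
  out <- tab[intersect(cols, names(tab))]
  for (cc in setdiff(cols, names(out))) out[[cc]] <- integer(0)
  out <- out[cols]
  out$IncLevel1 <- ifelse(is.na(out$IncLevel1), "NA",
                          sprintf("%.6f", out$IncLevel1))
  # integer-valued columns are printed as plain integers (never scientific)
  for (cc in setdiff(cols, c(.rmats_fixed_cols, "IncLevel1"))) {
    out[[cc]] <- ifelse(is.na(out[[cc]]), "NA",
                        sprintf("%d", as.integer(out[[cc]])))
  }
  out$ID <- sprintf("%d", as.integer(out$ID))
  # MXE headers are written in the native rMATS spelling (leading digit);
  # read_sample_events maps them back via check.names
  names(out) <- sub("^X(1st|2nd)", "\\1", names(out))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Assemble a cohort PSI matrix from per-sample event tables
#'
#' Takes the union of events across samples. A cell is covered iff
#' `ijc + sjc >= min_reads`; PSI is computed (length-normalized) only for
#' covered cells, others are `NA`.
#'
#' @param tables Named list of per-sample tables (names are sample ids), each
#'   from [read_sample_events()] (possibly several event types `rbind`ed).
#' @param min_reads Junction-read coverage filter applied to `ijc + sjc`
#'   per cell (default 10).
#' @return A `psi_matrix` object: list with `events` (event metadata,
#'   one row per unique event, ordered by `event_key`), `samples`, `psi`
#'   (events x samples), `covered` (logical, same shape).
#' @export
assemble_psi_matrix <- function(tables, min_reads = 10) {
  if (length(tables) == 0) stop("need at least one sample table")
  if (is.null(names(tables)) || any(names(tables) == "") ||
      anyDuplicated(names(tables))) {
    stop("tables must be uniquely named by sample id")
  }
  samples <- names(tables)
  dt <- data.table::rbindlist(
    lapply(samples, function(s) {
      t <- tables[[s]]
      data.table::data.table(
        sample = s, event_key = t$event_key, event_type = t$event_type,
        GeneID = t$GeneID, geneSymbol = t$geneSymbol, chr = t$chr,
        strand = t$strand, var_start = t$var_start, var_end = t$var_end,
        ijc = t$IJC_SAMPLE_1, sjc = t$SJC_SAMPLE_1,
        inc_len = t$IncFormLen, skip_len = t$SkipFormLen)
    }))
  if (anyDuplicated(dt[, c("sample", "event_key")])) {
    stop("duplicate (sample, event) rows across input tables")
  }
  events <- unique(dt[, c("event_key", "event_type", "GeneID", "geneSymbol",
                          "chr", "strand", "var_start", "var_end")])
  data.table::setorder(events, event_key)
  events <- as.data.frame(events)
  ei <- match(dt$event_key, events$event_key)
  si <- match(dt$sample, samples)
  ne <- nrow(events); ns <- length(samples)
  psi <- matrix(NA_real_, ne, ns, dimnames = list(events$event_key, samples))
  covered <- matrix(FALSE, ne, ns, dimnames = dimnames(psi))
  idx <- cbind(ei, si)
  covered[idx] <- (dt$ijc + dt$sjc) >= min_reads
  val <- compute_psi(dt$ijc, dt$sjc, dt$inc_len, dt$skip_len)
  keep <- (dt$ijc + dt$sjc) >= min_reads
  psi[idx[keep, , drop = FALSE]] <- val[keep]
  structure(list(events = events, samples = samples, psi = psi,
                 covered = covered, min_reads = min_reads),
            class = "psi_matrix")
}

#' @export
print.psi_matrix <- function(x, ...) {
  cat(sprintf("psi_matrix: %d events x %d samples (%.1f%% covered, min_reads=%d)\n",
              nrow(x$psi), ncol(x$psi), 100 * mean(x$covered), x$min_reads))
  invisible(x)
}

#' Export a PSI matrix as TSV with a coverage sidecar
#'
#' @param pm A `psi_matrix`.
#' @param psi_path,coverage_path Output TSV paths.
#' @return `psi_path`, invisibly.
#' @export
write_psi_matrix <- function(pm, psi_path, coverage_path) {
  fmt <- function(m, f) {
    d <- data.frame(event_key = rownames(m), apply(m, 2, f),
                    check.names = FALSE)
    names(d) <- c("event_key", colnames(m))
    d
  }
  utils::write.table(
    fmt(pm$psi, function(v) ifelse(is.na(v), "NA", sprintf("%.6f", v))),
    psi_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    fmt(pm$covered, function(v) as.integer(v)),
    coverage_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(psi_path)
}

#' Read a PSI matrix exported by [write_psi_matrix()]
#'
#' Event metadata beyond the key is not stored in the TSV export; the
#' returned object carries keys only (sufficient for all matrix-level
#' operations).
#'
#' @param psi_path,coverage_path TSV paths written by [write_psi_matrix()].
#' @param min_reads Coverage threshold recorded on the object.
#' @return A `psi_matrix` object.
#' @export
read_psi_matrix <- function(psi_path, coverage_path, min_reads = 10) {
  p <- utils::read.delim(psi_path, check.names = FALSE)
  cv <- utils::read.delim(coverage_path, check.names = FALSE)
  stopifnot(identical(p$event_key, cv$event_key))
  keys <- p$event_key
  psi <- as.matrix(p[-1]); rownames(psi) <- keys
  covered <- as.matrix(cv[-1]) > 0; rownames(covered) <- keys
  structure(list(events = data.frame(event_key = keys),
                 samples = colnames(psi), psi = psi, covered = covered,
                 min_reads = min_reads),
            class = "psi_matrix")
}
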