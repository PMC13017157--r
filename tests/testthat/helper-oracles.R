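# Independent oracles for coordinate-mapping checks: a per-base CDS
# enumerator and a random toy transcript-model generator.

aa_oracle <- function(interval, model) {
  bases <- unlist(lapply(seq_len(nrow(model$cds)), function(i) {
    seq(model$cds[i, "start"], model$cds[i, "end"] - 1)
  }))
  bases <- sort(bases)
  if (model$strand == "-") bases <- rev(bases)
  hit <- which(bases >= interval[1] & bases <= interval[2] - 1)
  if (length(hit) == 0) return(NULL)
  aa <- (hit - 1) %/% 3 + 1
  c(aa_start = as.integer(min(aa)), aa_end = as.integer(max(aa)))
}

random_model <- function() {
  n_ex <- sample(1:8, 1)
  strand <- sample(c("+", "-"), 1)
  # coding lengths; total forced to a multiple of 3
  lens <- sample(3:60, n_ex, replace = TRUE)
  excess <- sum(lens) %% 3
  lens[1] <- lens[1] + (3 - excess) %% 3
  utr5 <- sample(0:20, 1); utr3 <- sample(0:20, 1)
  ex_len <- lens
  ex_len[1] <- ex_len[1] + utr5
  ex_len[n_ex] <- ex_len[n_ex] + utr3
  starts <- integer(n_ex)
  starts[1] <- sample(1000:5000, 1)
  if (n_ex > 1) {
    for (i in seq_len(n_ex - 1)) {
      starts[i + 1] <- starts[i] + ex_len[i] + sample(30:300, 1)
    }
  }
  ends <- starts + ex_len
  cds <- cbind(start = starts, end = ends)
  cds[1, "start"] <- cds[1, "start"] + utr5
  cds[n_ex, "end"] <- cds[n_ex, "end"] - utr3
  m <- list(transcript_id = "tx", gene = "g", chrom = "chr1",
            strand = strand, exons = cbind(start = starts, end = ends),
            cds = cds)
  m$cds_len <- sum(cds[, "end"] - cds[, "start"])
  class(m) <- "transcript_model"
  m
}
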