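# Splicing Burden Index (SBI), quartile groups, correlations, and
# splicing-factor expression association.

#' Compute the Splicing Burden Index
#'
#' SBI is the per-sample proportion of evaluable splice events called
#' differential: numerator = number of that sample's differential calls,
#' denominator = number of events both covered in the sample and
#' cohort-evaluable. The per-sample denominator makes samples with unequal
#' coverage comparable; set `global_denominator = TRUE` to divide every
#' sample by the total number of evaluable events instead.
#'
#' @param calls From [call_differential()].
#' @param pm The `psi_matrix` the calls were made on.
#' @param stats From [cohort_event_stats()] on the same matrix.
#' @param global_denominator Use the cohort-wide evaluable-event count for
#'   every sample (default `FALSE`).
#' @return `data.frame`: sample, n_differential, n_evaluable, sbi.
#' @export
compute_sbi <- function(calls, pm, stats, global_denominator = FALSE) {
  stopifnot(identical(stats$event_key, rownames(pm$psi)))
  obs <- pm$covered & !is.na(pm$psi)
  denom <- if (global_denominator) {
    rep(sum(stats$evaluable), length(pm$samples))
  } else {
    colSums(obs & stats$evaluable)
  }
  if (any(denom == 0)) {
    stop("samples with zero evaluable events: ",
         paste(pm$samples[denom == 0], collapse = ", "))
  }
  num <- as.integer(table(factor(calls$sample, levels = pm$samples)))
  data.frame(sample = pm$samples, n_differential = num,
             n_evaluable = as.integer(denom), sbi = num / denom,
             stringsAsFactors = FALSE)
}

#' Assign high / low / mid SBI quartile groups
#'
#' High means SBI at or above the cohort's third quartile, low at or below
#' the first quartile. Quartiles are the interpolated sample quantiles (R
#' default, type 7), so with distinct values exactly the top and bottom
#' quarters of samples are labelled; ties at a boundary are included on both
#' sides of it. If all samples share one SBI value every sample satisfies
#' both rules; those are resolved to `mid` with a warning.
#'
#' @param sbi From [compute_sbi()].
#' @param quantile_type Passed to [stats::quantile()] (default 7).
#' @return The input with a `group` column in `{high, low, mid}`.
#' @export
assign_sbi_groups <- function(sbi, quantile_type = 7) {
  if (nrow(sbi) < 4) stop("need at least 4 samples for quartile groups")
  q <- stats::quantile(sbi$sbi, c(0.25, 0.75), type = quantile_type,
                       names = FALSE)
  hi <- sbi$sbi >= q[2]
  lo <- sbi$sbi <= q[1]
  both <- hi & lo
  if (any(both)) {
    warning("samples at or beyond both quartile boundaries assigned to mid")
    hi[both] <- lo[both] <- FALSE
  }
  sbi$group <- ifelse(hi, "high", ifelse(lo, "low", "mid"))
  sbi
}

#' Grouped correlation with BH adjustment
#'
#' Pearson or Spearman correlation of two paired variables, overall or
#' within groups, with two-sided p-values and Benjamini-Hochberg adjustment
#' across the rows of one invocation. An optional exclusion filter (e.g.,
#' hypermutant tumors by TMB cutoff) drops samples before computing.
#'
#' @param x,y Paired numeric vectors.
#' @param grouping Optional factor/character of group labels (default: one
#'   group `"all"`).
#' @param method `"pearson"` or `"spearman"`.
#' @param exclude Optional logical vector; `TRUE` entries are dropped.
#' @param min_n Minimum paired observations per group (default 3).
#' @return `data.frame`: group, n, r, p, adj_p, computable.
#' @export
grouped_correlation <- function(x, y, grouping = NULL,
                                method = c("pearson", "spearman"),
                                exclude = NULL, min_n = 3) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  if (is.null(grouping)) grouping <- rep("all", length(x))
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(exclude)) keep <- keep & !exclude
  x <- x[keep]; y <- y[keep]; grouping <- grouping[keep]
  rows <- lapply(split(seq_along(x), grouping), function(i) {
    xi <- x[i]; yi <- y[i]
    if (length(i) < min_n || stats::sd(xi) == 0 || stats::sd(yi) == 0) {
      return(data.frame(n = length(i), r = NA_real_, p = NA_real_,
                        computable = FALSE))
    }
    ct <- suppressWarnings(stats::cor.test(xi, yi, method = method,
                                           exact = FALSE))
    data.frame(n = length(i), r = unname(ct$estimate), p = ct$p.value,
               computable = TRUE)
  })
  out <- do.call(rbind, rows)
  out <- data.frame(group = names(rows), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  out[c("group", "n", "r", "p", "adj_p", "computable")]
}

#' Splicing-factor expression association with SBI groups
#'
#' Per-gene two-sided Wilcoxon rank-sum test of high- vs low-SBI samples on
#' `log2(TPM + 1)`; effect is the difference of group means on that scale
#' (high minus low, a log2 fold change); BH adjustment over the supplied
#' gene list.
#'
#' @param tpm Genes x samples TPM matrix (rownames are gene symbols).
#' @param sbi_groups From [assign_sbi_groups()].
#' @param genes Character vector of genes to test (e.g., splicing factors).
#' @return `data.frame`: gene, effect, statistic, p, adj_p, significant
#'   (`adj_p < 0.05`).
#' @export
sf_expression_association <- function(tpm, sbi_groups, genes) {
  if (length(genes) == 0) {
    return(data.frame(gene = character(), effect = numeric(),
                      statistic = numeric(), p = numeric(),
                      adj_p = numeric(), significant = logical()))
  }
  miss <- setdiff(genes, rownames(tpm))
  if (length(miss)) {
    stop("genes absent from tpm matrix: ", paste(miss, collapse = ", "))
  }
  hi <- sbi_groups$sample[sbi_groups$group == "high"]
  lo <- sbi_groups$sample[sbi_groups$group == "low"]
  hi <- intersect(hi, colnames(tpm)); lo <- intersect(lo, colnames(tpm))
  if (length(hi) < 3 || length(lo) < 3) {
    stop("need at least 3 samples in each SBI group")
  }
  lx <- log2(tpm[genes, hi, drop = FALSE] + 1)
  ly <- log2(tpm[genes, lo, drop = FALSE] + 1)
  res <- lapply(seq_along(genes), function(i) {
    wt <- suppressWarnings(stats::wilcox.test(lx[i, ], ly[i, ],
                                              exact = FALSE))
    data.frame(gene = genes[i],
               effect = mean(lx[i, ]) - mean(ly[i, ]),
               statistic = unname(wt$statistic), p = wt$p.value)
  })
  out <- do.call(rbind, res)
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$adj_p < 0.05
  out
}
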