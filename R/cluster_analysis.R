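# Splicing-based clustering, cluster-label enrichment, and marker-based
# cell-type variance partitioning.

#' Select the most variable splice events
#'
#' Events are first restricted to those covered in at least
#' `min_coverage_frac` of samples, then ranked by PSI variance over covered
#' cells. Ties are broken deterministically by event key.
#'
#' @param pm A `psi_matrix`.
#' @param k Number of events to keep (default 5000).
#' @param min_coverage_frac Minimum fraction of covered samples (default
#'   0.75).
#' @return Character vector of selected event keys, most variable first.
#' @export
top_variable_events <- function(pm, k = 5000, min_coverage_frac = 0.75) {
  stopifnot(inherits(pm, "psi_matrix"), nrow(pm$psi) > 0)
  obs <- pm$covered & !is.na(pm$psi)
  frac <- rowMeans(obs)
  elig <- which(frac >= min_coverage_frac)
  if (length(elig) == 0) stop("no events pass the coverage filter")
  x0 <- ifelse(obs, pm$psi, 0)
  n <- rowSums(obs)[elig]
  s1 <- rowSums(x0)[elig]
  s2 <- rowSums(x0^2)[elig]
  v <- ifelse(n > 1, pmax(0, (s2 - s1^2 / n) / (n - 1)), 0)
  keys <- rownames(pm$psi)[elig]
  ord <- order(-v, keys)
  if (length(elig) < k) {
    warning(sprintf("only %d events pass the coverage filter (k = %d)",
                    length(elig), k))
    k <- length(elig)
  }
  keys[ord][seq_len(k)]
}

# Canonical dense cluster ids 1..k: clusters are renumbered by the
# lexicographically smallest sample id they contain, so the labelling does
# not depend on input sample order.
.canonical_clusters <- function(assign, samples) {
  first <- tapply(samples, assign, min)
  ord <- names(sort(first))                 # raw ids in canonical order
  out <- match(as.character(assign), ord)
  names(out) <- samples
  out
}

#' Hierarchical clustering of samples on PSI
#'
#' Missing cells are imputed with the event median over covered cells, then
#' samples are clustered by agglomerative hierarchical clustering (Ward
#' linkage on Euclidean distance by default; `(1 - Pearson)` distance and
#' average linkage available) and the tree is cut at `k`.
#'
#' @param pm A `psi_matrix`, usually subset to [top_variable_events()] keys
#'   via `subset_events`.
#' @param k Number of clusters (default 10).
#' @param subset_events Optional event keys to cluster on.
#' @param distance `"euclidean"` or `"pearson"` (1 - Pearson correlation).
#' @param linkage `"ward"` (ward.D2) or `"average"`.
#' @return List of class `cluster_result`: `cluster` (named integer vector,
#'   dense ids 1..k), `k`, `distance`, `linkage`, `hclust`.
#' @export
cluster_samples <- function(pm, k = 10, subset_events = NULL,
                            distance = c("euclidean", "pearson"),
                            linkage = c("ward", "average")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  x <- pm$psi
  cov <- pm$covered
  if (!is.null(subset_events)) {
    ix <- match(subset_events, rownames(x))
    if (anyNA(ix)) stop("subset_events not all present in matrix")
    x <- x[ix, , drop = FALSE]
    cov <- cov[ix, , drop = FALSE]
  }
  if (k < 2 || k > ncol(x)) stop("k must be in [2, n_samples]")
  x[!cov] <- NA
  med <- apply(x, 1, stats::median, na.rm = TRUE)
  for (i in which(rowSums(is.na(x)) > 0)) x[i, is.na(x[i, ])] <- med[i]
  m <- t(x)                                  # samples x events
  d <- if (distance == "euclidean") stats::dist(m) else
    stats::as.dist(1 - stats::cor(t(m)))
  hc <- stats::hclust(d, method = if (linkage == "ward") "ward.D2" else
    "average")
  raw <- stats::cutree(hc, k = k)
  cl <- .canonical_clusters(raw, colnames(x))
  structure(list(cluster = cl, k = k, distance = distance,
                 linkage = linkage, hclust = hc),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d samples in %d clusters (%s / %s)\n",
              length(x$cluster), x$k, x$distance, x$linkage))
  print(table(cluster = x$cluster))
  invisible(x)
}

#' Cluster-label enrichment (one-vs-rest Fisher tests)
#'
#' For every (cluster, label) pair, builds the 2x2 table of cluster
#' membership against label membership, computes the two-sided Fisher exact
#' p-value, and the sample odds ratio `(a*d)/(b*c)` with the
#' Haldane-Anscombe 0.5 correction applied when any cell is zero (the raw
#' ratio is also reported, `Inf` flagged via `or_infinite`). BH adjustment
#' across all rows.
#'
#' @param clusters Named cluster vector (from `cluster_result$cluster`).
#' @param labels Named vector of labels (histology or molecular subtype) for
#'   the same samples.
#' @return `data.frame`: cluster, label, a, b, c, d, odds_ratio,
#'   or_infinite, p, adj_p.
#' @export
cluster_enrichment <- function(clusters, labels) {
  .fisher_2x2(clusters, labels)
}

# Two-sided Fisher exact p for one 2x2 table; the single p-value path used
# by cluster_enrichment.
.fisher_p <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                     alternative = "two.sided")$p.value
}

.fisher_2x2 <- function(clusters, labels) {
  samples <- names(clusters)
  if (is.null(samples)) stop("clusters must be a named vector")
  if (!all(samples %in% names(labels))) {
    stop("labels missing for: ",
         paste(setdiff(samples, names(labels)), collapse = ", "))
  }
  labels <- labels[samples]
  rows <- list()
  for (cl in sort(unique(clusters))) {
    in_cl <- clusters == cl
    for (lb in sort(unique(labels))) {
      in_lb <- labels == lb
      a <- sum(in_cl & in_lb); b <- sum(in_cl & !in_lb)
      cc <- sum(!in_cl & in_lb); d <- sum(!in_cl & !in_lb)
      p <- .fisher_p(a, b, cc, d)
      raw_or <- (a * d) / (b * cc)
      use_corr <- a == 0 || b == 0 || cc == 0 || d == 0
      or <- if (use_corr) {
        ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
      } else raw_or
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl, label = lb, a = a, b = b, c = cc, d = d,
        odds_ratio = or, or_infinite = is.infinite(raw_or) | is.nan(raw_or),
        p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Marker-based cell-type scores from bulk expression
#'
#' For each cell type, the score of a sample is the mean across that type's
#' marker genes of the z-scored `log2(TPM + 1)` expression. Markers absent
#' from the matrix are dropped with a warning; markers with zero variance
#' across samples cannot be z-scored and are dropped likewise. A type with
#' no usable marker is an error.
#'
#' @param tpm Genes x samples TPM matrix.
#' @param marker_sets Named list: cell type -> character vector of marker
#'   genes.
#' @return Samples x cell-types numeric matrix.
#' @export
celltype_scores <- function(tpm, marker_sets) {
  lx <- log2(tpm + 1)
  ns <- ncol(lx)
  out <- matrix(NA_real_, ns, length(marker_sets),
                dimnames = list(colnames(lx), names(marker_sets)))
  for (ct in names(marker_sets)) {
    mk <- marker_sets[[ct]]
    absent <- setdiff(mk, rownames(lx))
    if (length(absent)) {
      warning(sprintf("cell type %s: dropping absent marker(s) %s", ct,
                      paste(absent, collapse = ", ")))
      mk <- setdiff(mk, absent)
    }
    if (length(mk)) {
      sds <- apply(lx[mk, , drop = FALSE], 1, stats::sd)
      flat <- mk[sds == 0]
      if (length(flat)) {
        warning(sprintf("cell type %s: dropping zero-variance marker(s) %s",
                        ct, paste(flat, collapse = ", ")))
        mk <- setdiff(mk, flat)
      }
    }
    if (length(mk) == 0) stop("cell type with no usable marker gene: ", ct)
    z <- t(scale(t(lx[mk, , drop = FALSE])))
    out[, ct] <- colMeans(z)
  }
  out
}

#' PSI variance explained by cell-type composition
#'
#' Per event, ordinary least squares of PSI on all cell-type scores plus an
#' intercept, over that event's covered samples; reports
#' `R^2 = 1 - RSS/TSS` and the bin it falls in (`<30%`, `30-50%`, `>50%`;
#' the middle bin is closed on both edges). Events with fewer than
#' `n_types + 2` covered samples or zero PSI variance are skipped.
#'
#' @param pm A `psi_matrix` (usually subset to the clustering events).
#' @param scores Samples x cell-types matrix from [celltype_scores()].
#' @param subset_events Optional event keys to fit.
#' @return `data.frame`: event_key, n, r_squared, bin; skipped events are
#'   absent.
#' @export
psi_variance_explained <- function(pm, scores, subset_events = NULL) {
  x <- pm$psi; cov <- pm$covered
  if (!is.null(subset_events)) {
    ix <- match(subset_events, rownames(x))
    if (anyNA(ix)) stop("subset_events not all present in matrix")
    x <- x[ix, , drop = FALSE]; cov <- cov[ix, , drop = FALSE]
  }
  if (!all(colnames(x) %in% rownames(scores))) {
    stop("scores missing for some samples")
  }
  sc <- scores[colnames(x), , drop = FALSE]
  p <- ncol(sc)
  ne <- nrow(x)
  keys <- character(ne); ns <- integer(ne); r2s <- numeric(ne)
  kept <- 0L
  for (i in seq_len(ne)) {
    ok <- cov[i, ] & !is.na(x[i, ])
    n <- sum(ok)
    if (n < p + 2) next
    y <- x[i, ok]
    tss <- sum((y - mean(y))^2)
    if (tss == 0) next
    fit <- stats::lm.fit(cbind(1, sc[ok, , drop = FALSE]), y)
    kept <- kept + 1L
    keys[kept] <- rownames(x)[i]
    ns[kept] <- n
    r2s[kept] <- 1 - sum(fit$residuals^2) / tss
  }
  if (kept == 0L) {
    return(data.frame(event_key = character(), n = integer(),
                      r_squared = numeric(), bin = character()))
  }
  idx <- seq_len(kept)
  data.frame(event_key = keys[idx], n = ns[idx], r_squared = r2s[idx],
             bin = r_squared_bin(r2s[idx]), stringsAsFactors = FALSE)
}

#' Bin variance-explained values at the 0.30 / 0.50 edges
#'
#' @param r2 Numeric vector in `[0,1]`.
#' @return Character vector in `{"<30%", "30-50%", ">50%"}`; the middle bin
#'   is closed (`0.30 <= r2 <= 0.50`).
#' @export
r_squared_bin <- function(r2) {
  ifelse(r2 < 0.30, "<30%", ifelse(r2 <= 0.50, "30-50%", ">50%"))
}

#' Silhouette-based scan over candidate cluster counts
#'
#' Diagnostic only: reports the mean silhouette width of [cluster_samples()]
#' partitions over a range of `k`; never auto-selects a `k` for the
#' pipeline.
#'
#' @param pm A `psi_matrix`.
#' @param ks Candidate cluster counts.
#' @param ... Passed to [cluster_samples()].
#' @return `data.frame`: k, mean_silhouette.
#' @export
silhouette_scan <- function(pm, ks = 2:12, ...) {
  x <- pm$psi
  x[!pm$covered] <- NA
  med <- apply(x, 1, stats::median, na.rm = TRUE)
  for (i in which(rowSums(is.na(x)) > 0)) x[i, is.na(x[i, ])] <- med[i]
  d <- as.matrix(stats::dist(t(x)))
  res <- lapply(ks, function(k) {
    cl <- cluster_samples(pm, k = k, ...)$cluster
    sil <- vapply(seq_along(cl), function(j) {
      own <- cl[j]
      a <- mean(d[j, cl == own & seq_along(cl) != j])
      bs <- vapply(setdiff(unique(cl), own),
                   function(o) mean(d[j, cl == o]), numeric(1))
      b <- min(bs)
      if (is.nan(a)) 0 else (b - a) / max(a, b)
    }, numeric(1))
    data.frame(k = k, mean_silhouette = mean(sil))
  })
  do.call(rbind, res)
}
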