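# Per-sample differential splicing against cohort statistics.

#' Cohort-level PSI statistics per event
#'
#' Mean and sample standard deviation (n-1 denominator) of PSI over covered
#' cells. Events with fewer than `min_cohort_n` covered samples or zero
#' variance are flagged non-evaluable (a zero-variance event would otherwise
#' yield infinite z-scores).
#'
#' @param pm A `psi_matrix`.
#' @param mode `"full"` (sample included in its own cohort statistics, the
#'   default) or `"loo"` (leave-one-out: per-sample mean/sd excluding that
#'   sample, derived from sufficient statistics).
#' @param min_cohort_n Minimum covered samples per event (default 10).
#' @return List of class `cohort_event_stats`: `mean`, `sd`, `n` (per-event
#'   vectors), `evaluable` (logical), `mode`, plus sufficient statistics
#'   `sum`/`sumsq` used by leave-one-out mode.
#' @export
cohort_event_stats <- function(pm, mode = c("full", "loo"), min_cohort_n = 10) {
  mode <- match.arg(mode)
  stopifnot(inherits(pm, "psi_matrix"), nrow(pm$psi) > 0)
  x <- pm$psi
  obs <- pm$covered & !is.na(x)
  x0 <- ifelse(obs, x, 0)
  n <- rowSums(obs)
  s1 <- rowSums(x0)
  s2 <- rowSums(x0^2)
  mu <- ifelse(n > 0, s1 / n, NA_real_)
  varr <- ifelse(n > 1, pmax(0, (s2 - n * mu^2) / (n - 1)), NA_real_)
  sdv <- sqrt(varr)
  evaluable <- n >= min_cohort_n & !is.na(sdv) & sdv > 0
  if (!any(evaluable)) warning("no evaluable events at min_cohort_n = ",
                               min_cohort_n)
  structure(list(event_key = rownames(x), mean = mu, sd = sdv, n = n,
                 sum = s1, sumsq = s2, evaluable = evaluable, mode = mode,
                 min_cohort_n = min_cohort_n),
            class = "cohort_event_stats")
}

# Leave-one-out mean/sd matrices from sufficient statistics.
.loo_stats <- function(stats, pm) {
  obs <- pm$covered & !is.na(pm$psi)
  x0 <- ifelse(obs, pm$psi, 0)
  n_i <- stats$n - obs                       # matrix via recycling by column
  s1_i <- stats$sum - x0
  s2_i <- stats$sumsq - x0^2
  mu_i <- ifelse(n_i > 0, s1_i / n_i, NA_real_)
  var_i <- ifelse(n_i > 1, pmax(0, (s2_i - n_i * mu_i^2) / (n_i - 1)),
                  NA_real_)
  list(mean = mu_i, sd = sqrt(var_i), n = n_i)
}

#' Call per-sample differential splice events
#'
#' A call is emitted iff the cell is covered, the event evaluable, and both
#' `|z| > z_thresh` and `|dpsi| > dpsi_thresh` hold (strict inequalities),
#' where `dpsi = psi - cohort mean` and `z = dpsi / cohort sd`. Direction is
#' `inclusion` for positive dpsi, `skipping` for negative.
#'
#' @param pm A `psi_matrix`.
#' @param stats From [cohort_event_stats()] on the same matrix.
#' @param z_thresh,dpsi_thresh Positive call thresholds (defaults 2.0 / 0.2).
#' @return `data.frame` with columns sample, event_key, psi, delta_psi, z,
#'   direction; one row per call, ordered by (event_key, sample).
#' @export
call_differential <- function(pm, stats, z_thresh = 2.0, dpsi_thresh = 0.2) {
  if (z_thresh <= 0 || dpsi_thresh <= 0) stop("thresholds must be positive")
  stopifnot(identical(stats$event_key, rownames(pm$psi)))
  obs <- pm$covered & !is.na(pm$psi)
  if (stats$mode == "loo") {
    loo <- .loo_stats(stats, pm)
    mu <- loo$mean; sdv <- loo$sd
    ev <- stats$evaluable & (loo$n >= stats$min_cohort_n) &
      !is.na(sdv) & sdv > 0
  } else {
    mu <- stats$mean; sdv <- stats$sd
    ev <- stats$evaluable
  }
  dpsi <- pm$psi - mu                        # recycles per-event vectors
  z <- dpsi / sdv
  hit <- obs & ev & abs(z) > z_thresh & abs(dpsi) > dpsi_thresh
  hit[is.na(hit)] <- FALSE
  idx <- which(hit, arr.ind = TRUE)
  calls <- data.frame(
    sample = pm$samples[idx[, 2]],
    event_key = rownames(pm$psi)[idx[, 1]],
    psi = pm$psi[idx],
    delta_psi = dpsi[idx],
    z = z[idx],
    stringsAsFactors = FALSE)
  calls$direction <- ifelse(calls$delta_psi > 0, "inclusion", "skipping")
  calls[order(calls$event_key, calls$sample), , drop = FALSE]
}

#' Summarize recurrent differential events
#'
#' @param calls From [call_differential()].
#' @param min_recurrence Minimum number of called samples (default 2).
#' @return `data.frame`: event_key, n_samples_called, n_inclusion,
#'   n_skipping, direction_class (`inclusion`/`skipping`/`mixed`),
#'   mean_abs_dpsi.
#' @export
recurrence <- function(calls, min_recurrence = 2) {
  if (nrow(calls) == 0) {
    return(data.frame(event_key = character(), n_samples_called = integer(),
                      n_inclusion = integer(), n_skipping = integer(),
                      direction_class = character(),
                      mean_abs_dpsi = numeric()))
  }
  dt <- data.table::as.data.table(calls)
  agg <- dt[, list(n_samples_called = .N,
                   n_inclusion = sum(direction == "inclusion"),
                   n_skipping = sum(direction == "skipping"),
                   mean_abs_dpsi = mean(abs(delta_psi))),
            by = "event_key"]
  agg <- agg[agg$n_samples_called >= min_recurrence, ]
  agg$direction_class <- ifelse(
    agg$n_skipping == 0, "inclusion",
    ifelse(agg$n_inclusion == 0, "skipping", "mixed"))
  data.table::setorder(agg, event_key)
  as.data.frame(agg[, c("event_key", "n_samples_called", "n_inclusion",
                        "n_skipping", "direction_class", "mean_abs_dpsi")])
}

#' Histology-specific recurrent events with per-patient normalization
#'
#' An event is specific to a histology iff all of its calls fall in samples
#' of that histology; events called across several histologies are reported
#' as shared.
#'
#' @param recurrent From [recurrence()].
#' @param calls From [call_differential()].
#' @param manifest `data.frame` with columns `sample` and `histology`.
#' @return List with `per_histology` (histology, n_patients,
#'   n_specific_events, events_per_patient) and `shared` (event keys called
#'   in more than one histology).
#' @export
histology_specific <- function(recurrent, calls, manifest) {
  stopifnot(all(c("sample", "histology") %in% names(manifest)))
  calls <- calls[calls$event_key %in% recurrent$event_key, , drop = FALSE]
  miss <- setdiff(unique(calls$sample), manifest$sample)
  if (length(miss)) {
    stop("samples missing from manifest: ", paste(miss, collapse = ", "))
  }
  hist_of <- manifest$histology[match(calls$sample, manifest$sample)]
  if (anyNA(hist_of)) {
    stop("samples with missing histology: ",
         paste(unique(calls$sample[is.na(hist_of)]), collapse = ", "))
  }
  n_hist <- tapply(hist_of, calls$event_key,
                   function(h) length(unique(h)))
  specific_events <- names(n_hist)[n_hist == 1]
  shared_events <- names(n_hist)[n_hist > 1]
  ev_hist <- tapply(hist_of, calls$event_key, function(h) h[1])
  spec_hist <- ev_hist[specific_events]
  pts <- table(manifest$histology)
  counts <- table(factor(spec_hist, levels = names(pts)))
  per <- data.frame(histology = names(pts),
                    n_patients = as.integer(pts),
                    n_specific_events = as.integer(counts),
                    stringsAsFactors = FALSE)
  per$events_per_patient <- per$n_specific_events / per$n_patients
  per <- per[order(-per$n_specific_events, per$histology), ]
  rownames(per) <- NULL
  list(per_histology = per, shared = sort(shared_events))
}
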