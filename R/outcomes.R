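# Proportional-hazards models, Kaplan-Meier stratification, and the
# age-trend (oncofetal) test.

#' Collapse rare factor levels
#'
#' Levels observed fewer than `min_n` times are merged into a single
#' `"Collapsed"` level so small histology groups can stay in a model.
#'
#' @param x Factor or character vector.
#' @param min_n Minimum group size to keep a level (default 3).
#' @param label Name of the merged level.
#' @return Factor with rare levels merged.
#' @export
collapse_small_levels <- function(x, min_n = 3, label = "Collapsed") {
  x <- as.character(x)
  tab <- table(x)
  rare <- names(tab)[tab < min_n]
  x[x %in% rare] <- label
  factor(x)
}

#' Fit a Cox proportional-hazards model
#'
#' Thin, validated wrapper over [survival::coxph()] with Efron tie handling
#' by default, returning a tidy per-term table of hazard ratios. Factor
#' covariates should carry their reference level (e.g., cluster 1, gross /
#' near-total resection) via `relevel()` before fitting; interactions are
#' written in the formula (e.g., `~ sbi * cluster`).
#'
#' @param data `data.frame` with a time column, a status column (0 =
#'   censored, 1 = event), and covariates.
#' @param formula Right-hand-side formula of covariates, e.g.
#'   `~ cluster + resection + age`.
#' @param time_col,status_col Column names (defaults `"time"`, `"status"`).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return List of class `cox_fit`: `terms` (`data.frame`: term, hr, ci_low,
#'   ci_high, p), `n`, `n_events`, `converged`, `fit` (the underlying
#'   `coxph` object).
#' @export
fit_cox <- function(data, formula, time_col = "time", status_col = "status",
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(all(c(time_col, status_col) %in% names(data)))
  if (any(data[[time_col]] <= 0)) stop("non-positive survival times")
  if (!any(data[[status_col]] == 1)) stop("no events in data")
  full <- stats::as.formula(sprintf(
    "survival::Surv(%s, %s) %s", time_col, status_col,
    paste(deparse(formula), collapse = "")))
  warns <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(full, data = data, ties = ties, model = TRUE,
                    x = FALSE),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  beta <- co[, "coef"]
  sep <- grep("may be infinite", warns, value = TRUE)
  if (length(sep) || any(!is.finite(beta))) {
    idx <- suppressWarnings(as.integer(gsub("\\D", "", sep)))
    idx <- idx[!is.na(idx) & idx >= 1 & idx <= nrow(co)]
    stop("apparent complete separation for term(s): ",
         paste(unique(c(rownames(co)[idx],
                        rownames(co)[!is.finite(beta)])), collapse = ", "))
  }
  converged <- !any(grepl("Ran out of iterations|did not converge", warns))
  for (w in setdiff(warns, sep)) warning(w, call. = FALSE)
  terms <- data.frame(
    term = rownames(co),
    hr = unname(ci[, "exp(coef)"]),
    ci_low = unname(ci[, "lower .95"]),
    ci_high = unname(ci[, "upper .95"]),
    p = unname(co[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE)
  structure(list(terms = terms, n = s$n, n_events = s$nevent,
                 converged = converged, ties = ties, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit: n = %d, events = %d, ties = %s%s\n", x$n,
              x$n_events, x$ties,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  t <- x$terms
  t$hr <- sprintf("%.3f", t$hr)
  t$ci <- sprintf("[%.3f, %.3f]", x$terms$ci_low, x$terms$ci_high)
  t$p <- format.pval(x$terms$p, digits = 3)
  print(t[, c("term", "hr", "ci", "p")], row.names = FALSE)
  invisible(x)
}

#' Kaplan-Meier stratification by a continuous score
#'
#' Splits samples into high/low strata at the median (or a supplied cut
#' point), estimates the Kaplan-Meier survival curve for each stratum, and
#' tests the difference with a two-sided log-rank test.
#'
#' @param data `data.frame` with time and status columns.
#' @param score Numeric vector aligned with `data` rows.
#' @param split `"median"` or a numeric cut point; strata are
#'   `score > cut` (high) vs `score <= cut` (low).
#' @param time_col,status_col Column names.
#' @return List of class `km_strata`: `curves` (`data.frame`: stratum,
#'   time, n_risk, n_event, surv), `logrank_p`, `strata_n`, `fit`.
#' @export
km_strata <- function(data, score, split = "median", time_col = "time",
                      status_col = "status") {
  cut <- if (identical(split, "median")) stats::median(score) else split
  stratum <- factor(ifelse(score > cut, "high", "low"),
                    levels = c("low", "high"))
  if (length(unique(stratum)) < 2) {
    stop("all samples fall on one side of the split")
  }
  d <- data.frame(time = data[[time_col]], status = data[[status_col]],
                  stratum = stratum)
  fit <- survival::survfit(survival::Surv(time, status) ~ stratum, data = d)
  sm <- summary(fit)
  curves <- data.frame(
    stratum = sub("^stratum=", "", as.character(sm$strata)),
    time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
    surv = sm$surv, stringsAsFactors = FALSE)
  lr <- survival::survdiff(survival::Surv(time, status) ~ stratum, data = d)
  p <- stats::pchisq(lr$chisq, df = length(lr$n) - 1, lower.tail = FALSE)
  structure(list(curves = curves, logrank_p = p,
                 strata_n = table(stratum), cut = cut, fit = fit),
            class = "km_strata")
}

#' @export
print.km_strata <- function(x, ...) {
  cat(sprintf("km_strata: low n = %d, high n = %d, log-rank p = %.3g\n",
              x$strata_n[["low"]], x$strata_n[["high"]], x$logrank_p))
  invisible(x)
}

#' Age-trend test across ordered age groups
#'
#' For a quantity measured per sample (e.g., exon-inclusion PSI), tests for
#' a monotone trend across ordered age groups: two-sided Wilcoxon rank-sum
#' tests for each adjacent pair of groups (BH-adjusted), and a Spearman
#' correlation between the values and the group rank as the trend
#' statistic. A declining trend (oncofetal pattern: high early, low late)
#' gives a negative trend statistic.
#'
#' @param values Numeric vector.
#' @param groups Ordered factor (or character coerced with the order given
#'   by `levels`) of age groups, aligned with `values`.
#' @param levels Optional explicit group order if `groups` is not an
#'   ordered factor.
#' @return List of class `age_trend`: `trend_rho`, `trend_p` (Spearman),
#'   `pairwise` (`data.frame`: group1, group2, p, adj_p).
#' @export
age_trend <- function(values, groups, levels = NULL) {
  if (is.null(levels)) {
    if (!is.factor(groups)) {
      stop("groups must be an ordered factor or explicit levels supplied")
    }
    levels <- base::levels(groups)
  }
  groups <- factor(as.character(groups), levels = levels)
  if (anyNA(groups)) stop("group labels outside the declared order")
  cnt <- table(groups)
  if (length(cnt) < 2 || any(cnt < 3)) {
    stop("need >= 2 groups with >= 3 values each")
  }
  rank_of <- as.integer(groups)
  ct <- suppressWarnings(stats::cor.test(values, rank_of,
                                         method = "spearman", exact = FALSE))
  pair <- lapply(seq_len(length(levels) - 1), function(i) {
    a <- values[groups == levels[i]]
    b <- values[groups == levels[i + 1]]
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    data.frame(group1 = levels[i], group2 = levels[i + 1], p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  pair <- do.call(rbind, pair)
  pair$adj_p <- stats::p.adjust(pair$p, method = "BH")
  structure(list(trend_rho = unname(ct$estimate), trend_p = ct$p.value,
                 pairwise = pair),
            class = "age_trend")
}

#' @export
print.age_trend <- function(x, ...) {
  cat(sprintf("age_trend: Spearman rho = %.3f (p = %.3g)\n", x$trend_rho,
              x$trend_p))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
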