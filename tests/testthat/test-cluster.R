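# Variable-event selection, clustering, enrichment, cell-type scores, and
# variance partitioning.

test_that("top_variable_events ranks by variance with deterministic ties", {
  set.seed(4)
  m <- rbind(rep(0.5, 20),                        # constant
             rbeta(20, 2, 2),                     # high variance
             rbeta(20, 50, 50))                   # low variance
  pm <- psi_matrix_from(m)
  sel <- top_variable_events(pm, k = 2)
  expect_equal(sel[1], "ev002")
  expect_false("ev001" %in% sel)
  # clamp with warning when k exceeds the eligible count
  expect_warning(all3 <- top_variable_events(pm, k = 10), "3 events")
  expect_length(all3, 3)
  # exact variance ties -> ordered by event key, stable
  m2 <- rbind(a = c(0.2, 0.8, 0.2, 0.8), b = c(0.8, 0.2, 0.8, 0.2))
  rownames(m2) <- c("zzz", "aaa")
  pm2 <- psi_matrix_from(m2)
  expect_equal(suppressWarnings(top_variable_events(pm2, k = 2)),
               c("aaa", "zzz"))
  # coverage filter removes sparsely covered events
  cov <- matrix(TRUE, 3, 20); cov[2, 1:10] <- FALSE
  pm3 <- psi_matrix_from(m, cov)
  expect_false("ev002" %in%
                 suppressWarnings(top_variable_events(pm3, k = 3,
                                                      min_coverage_frac = 0.75)))
})

test_that("clustering recovers planted blocks and ignores sample order", {
  set.seed(12)
  n_per <- 15
  block <- function(mu) matrix(pmin(pmax(rnorm(40 * n_per, mu, 0.05), 0), 1),
                               40, n_per)
  m <- cbind(block(0.25), block(0.75))
  truth <- rep(1:2, each = n_per)
  colnames(m) <- sprintf("S%03d", 1:(2 * n_per))
  pm <- psi_matrix_from(m)
  cl <- cluster_samples(pm, k = 2)
  expect_equal(adjusted_rand(cl$cluster, truth), 1)
  expect_true(all(sort(unique(cl$cluster)) == 1:2))
  # permutation of samples -> identical partition
  perm <- sample(ncol(m))
  pm2 <- psi_matrix_from(m[, perm])
  cl2 <- cluster_samples(pm2, k = 2)
  expect_equal(cl2$cluster[names(cl$cluster)], cl$cluster)
  # a duplicated sample joins its twin's cluster
  m3 <- cbind(m, DUP = m[, 1])
  cl3 <- cluster_samples(psi_matrix_from(m3), k = 2)
  expect_equal(unname(cl3$cluster["DUP"]), unname(cl3$cluster["S001"]))
  expect_error(cluster_samples(pm, k = 1), "k must be")
})

test_that("cluster recovery holds across seeds at the planted separation", {
  for (seed in 1:3) {
    cfg <- sim_config(n_samples = 80, n_events = c(SE = 600),
                      n_clusters = 4, cluster_dpsi = 0.3,
                      concentration = 100, seed = seed)
    co <- simulate_cohort(cfg)
    pm <- assemble_psi_matrix(co$tables)
    sel <- top_variable_events(pm, k = 200)
    cl <- cluster_samples(pm, k = 4, subset_events = sel)
    expect_gte(adjusted_rand(cl$cluster, co$truth$cluster[names(cl$cluster)]),
               0.9)
  }
})

test_that("Fisher enrichment matches hypergeometric enumeration with Haldane OR", {
  # brute-force two-sided Fisher p by hypergeometric enumeration
  fisher_enum <- function(a, b, c_, d) {
    m <- a + b; n <- c_ + d; k <- a + c_
    lo <- max(0, k - n); hi <- min(k, m)
    probs <- vapply(lo:hi, function(x) {
      exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
    }, numeric(1))
    p_obs <- probs[a - lo + 1]
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  set.seed(8)
  for (i in 1:60) {
    n <- sample(4:30, 1)
    cl <- sample(1:2, n, replace = TRUE)
    lb <- sample(c("x", "y"), n, replace = TRUE)
    names(cl) <- names(lb) <- sprintf("S%02d", seq_len(n))
    enr <- cluster_enrichment(cl, lb)
    for (j in seq_len(nrow(enr))) {
      row <- enr[j, ]
      expect_equal(row$p, fisher_enum(row$a, row$b, row$c, row$d),
                   tolerance = 1e-9)
      if (row$a * row$d > 0 && row$b * row$c > 0) {
        expect_equal(row$odds_ratio, (row$a * row$d) / (row$b * row$c))
      } else {
        expect_equal(row$odds_ratio,
                     ((row$a + 0.5) * (row$d + 0.5)) /
                       ((row$b + 0.5) * (row$c + 0.5)))
      }
    }
  }
})

test_that("enrichment odds ratios behave at the extremes", {
  cl <- setNames(rep(1:2, each = 10), sprintf("S%02d", 1:20))
  # label coincides with cluster 1 -> corrected OR maximal, infinite flagged
  lb <- setNames(rep(c("A", "B"), each = 10), names(cl))
  enr <- cluster_enrichment(cl, lb)
  r <- enr[enr$cluster == 1 & enr$label == "A", ]
  expect_true(r$or_infinite)
  expect_equal(r$odds_ratio, (10.5 * 10.5) / (0.5 * 0.5))
  expect_lt(r$adj_p, 0.01)
  # proportional label -> OR 1, p 1
  lb2 <- setNames(rep(c("A", "B"), 10), names(cl))
  enr2 <- cluster_enrichment(cl, lb2)
  r2 <- enr2[enr2$cluster == 1 & enr2$label == "A", ]
  expect_equal(r2$odds_ratio, 1)
  expect_equal(r2$p, 1)
})

test_that("cell-type scores reduce to z-scores and track planted fractions", {
  set.seed(5)
  tpm <- matrix(2^runif(60, 1, 8), 3, 20,
                dimnames = list(c("g1", "g2", "g3"),
                                sprintf("S%02d", 1:20)))
  sc <- celltype_scores(tpm, list(t1 = "g1"))
  expect_equal(sc[, "t1"],
               as.vector(scale(log2(tpm["g1", ] + 1))),
               ignore_attr = TRUE)
  # absent / zero-variance markers
  expect_warning(celltype_scores(tpm, list(t1 = c("g1", "nope"))), "absent")
  tpm0 <- rbind(tpm, flat = 5)
  expect_error(suppressWarnings(celltype_scores(tpm0, list(t1 = "flat"))),
               "no usable marker")
  # planted mixture: score correlates with the true fraction
  co <- ref_cohort()
  sc2 <- celltype_scores(co$tpm, co$marker_sets)
  fr <- co$truth$celltype_fractions
  for (ct in colnames(fr)) {
    expect_gte(cor(sc2[rownames(fr), ct], fr[, ct]), 0.9)
  }
})

test_that("variance partitioning matches a normal-equations oracle", {
  set.seed(14)
  r2_oracle <- function(y, X) {
    Xi <- cbind(1, X)
    beta <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
    rss <- sum((y - Xi %*% beta)^2)
    1 - rss / sum((y - mean(y))^2)
  }
  for (i in 1:100) {
    n <- sample(12:40, 1)
    p <- sample(2:4, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("S%03d", 1:n),
                                paste0("t", 1:p)))
    y <- rnorm(n)
    pm <- psi_matrix_from(matrix(y, 1, n,
                                 dimnames = list("e1", rownames(X))))
    got <- psi_variance_explained(pm, X)
    expect_equal(got$r_squared, r2_oracle(y, X), tolerance = 1e-8)
  }
})

test_that("variance partitioning handles perfect fits, nulls, and degenerate events", {
  set.seed(15)
  n <- 200
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(sprintf("S%03d", 1:n), paste0("t", 1:6)))
  # exact linear function of one score -> R^2 = 1
  y1 <- 0.5 + 0.1 * X[, 1]
  # independent noise -> mean R^2 ~ p/(n-1)
  null_m <- matrix(rnorm(60 * n), 60, n, dimnames = list(NULL, rownames(X)))
  m <- rbind(y1, null_m, const = 0.5)
  rownames(m) <- c("lin", sprintf("null%02d", 1:60), "const")
  pm <- psi_matrix_from(m)
  got <- psi_variance_explained(pm, X)
  expect_equal(got$r_squared[got$event_key == "lin"], 1)
  expect_false("const" %in% got$event_key)       # zero TSS skipped
  null_r2 <- got$r_squared[grepl("^null", got$event_key)]
  expect_lt(abs(mean(null_r2) - 6 / (n - 1)), 2 * sd(null_r2) / sqrt(60))
  expect_true(all(got$bin[grepl("^null", got$event_key)] == "<30%"))
  # bin edges: left-closed middle bin
  expect_equal(r_squared_bin(c(0.29, 0.30, 0.50, 0.51)),
               c("<30%", "30-50%", "30-50%", ">50%"))
})
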