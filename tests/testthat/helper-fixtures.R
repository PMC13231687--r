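# Shared fixtures and independent brute-force oracles. Oracles are written
# as directly as possible against the definitions (set operations, all-pairs
# counts) so they stay independent of the package implementation paths.

random_profiling_matrix <- function(n_cpd, n_assay, rate = 0.3,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vals <- matrix(rbinom(n_cpd * n_assay, 1, rate), nrow = n_cpd,
                 dimnames = list(sprintf("c%02d", seq_len(n_cpd)),
                                 sprintf("a%02d", seq_len(n_assay))))
  profiling_matrix(vals)
}

# brute-force set Tanimoto from raw 0/1 columns
brute_tanimoto <- function(col_a, col_b, restriction) {
  A <- restriction[col_a[restriction] == 1]
  B <- restriction[col_b[restriction] == 1]
  u <- union(A, B)
  if (!length(u)) return(0)
  length(intersect(A, B)) / length(u)
}

brute_ba <- function(truth, pred) {
  sens <- sum(truth == 1 & pred == 1) / sum(truth == 1)
  spec <- sum(truth == 0 & pred == 0) / sum(truth == 0)
  (sens + spec) / 2
}

brute_mcc <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1); tn <- sum(truth == 0 & pred == 0)
  fp <- sum(truth == 0 & pred == 1); fn <- sum(truth == 1 & pred == 0)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

# all positive-negative pairs with half credit for ties
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# Holm step-down executed literally
brute_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  run <- 0
  for (k in seq_len(m)) {
    run <- max(run, (m - k + 1) * p[ord[k]])
    adj[ord[k]] <- min(1, run)
  }
  adj
}

# random MMS table + labels with every series label-mixed
random_split_fixture <- function(seed, n_series = NULL) {
  set.seed(seed)
  n_series <- if (is.null(n_series)) sample(8:15, 1) else n_series
  sizes <- sample(2:6, n_series, replace = TRUE)
  cpd <- sprintf("m%03d", seq_len(sum(sizes)))
  mms <- data.frame(series_id = rep(sprintf("S%03d", seq_len(n_series)),
                                    sizes),
                    core_key = rep(sprintf("core%03d", seq_len(n_series)),
                                   sizes),
                    compound_id = cpd,
                    substituent = "*C", stringsAsFactors = FALSE)
  labels <- setNames(integer(length(cpd)), cpd)
  start <- cumsum(c(1, sizes))
  for (s in seq_len(n_series)) {
    mem <- cpd[start[s]:(start[s] + sizes[s] - 1)]
    k <- sample(length(mem) - 1, 1)
    labels[sample(mem, k)] <- 1L
  }
  list(mms = mms, labels = labels, sizes = sizes)
}

# one-row hyperparameter grids keep unit tests fast; the full default grids
# are exercised where grid search itself is under test
default_single_grid <- function(algo) {
  switch(algo,
         RF = data.frame(ntree = 100, max_depth = 0),
         XGB = data.frame(nrounds = 60, max_depth = 4, eta = 0.3),
         SVM = data.frame(cost = 1, gamma = NA_real_))
}

tiny_synthetic <- function(seed = 101, n_series = 12, n_assays = 20,
                           n_test = 3, n_planted = 2) {
  cfg <- synthetic_config(n_series = n_series,
                          analogs_per_series = c(3, 5),
                          n_assays = n_assays, n_test_assays = n_test,
                          n_planted = n_planted, ac_fraction = 0.7,
                          seed = seed)
  lib <- generate_library(cfg)
  gm <- generate_matrix(cfg, lib)
  list(cfg = cfg, lib = lib, gm = gm)
}
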