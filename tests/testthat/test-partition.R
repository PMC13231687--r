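# Leakage-controlled splits and class weights.

test_that("intra-series split keeps per-series label purity", {
  fx <- random_split_fixture(1, n_series = 10)
  sp <- intra_series_split(fx$mms, fx$labels, seed = 99)
  expect_length(intersect(sp$train$compound_id, sp$test$compound_id), 0)
  for (sid in unique(fx$mms$series_id)) {
    mem <- unique(fx$mms$compound_id[fx$mms$series_id == sid])
    tr_lab <- unique(sp$train$label[sp$train$compound_id %in% mem])
    te_lab <- unique(sp$test$label[sp$test$compound_id %in% mem])
    expect_lte(length(tr_lab), 1)
    expect_lte(length(te_lab), 1)
    if (length(tr_lab) && length(te_lab)) expect_true(tr_lab != te_lab)
  }
  # union of partitions covers all members of AC-forming series
  expect_setequal(c(sp$train$compound_id, sp$test$compound_id),
                  unique(fx$mms$compound_id))
})

test_that("a single AC pair splits one compound per partition", {
  mms <- data.frame(series_id = "S1", core_key = "k",
                    compound_id = c("a", "i"), substituent = "*C")
  sp <- intra_series_split(mms, c(a = 1, i = 0), seed = 4)
  expect_equal(nrow(sp$train), 1)
  expect_equal(nrow(sp$test), 1)
})

test_that("series without both labels are excluded and counted", {
  mms <- rbind(
    data.frame(series_id = "S1", core_key = "k1",
               compound_id = c("a", "b"), substituent = "*C"),
    data.frame(series_id = "S2", core_key = "k2",
               compound_id = c("c", "d"), substituent = "*C"))
  labels <- c(a = 1, b = 0, c = 1, d = 1)  # S2 homogeneous
  sp <- intra_series_split(mms, labels, seed = 1)
  expect_equal(sp$dropped$no_ac, 1)
  expect_false(any(c("c", "d") %in%
                     c(sp$train$compound_id, sp$test$compound_id)))
})

test_that("compounds shared between series are never duplicated across partitions", {
  # 'x' sits in both series; whatever the orientations draw, partitions
  # stay disjoint and dropped conflicts are counted
  mms <- rbind(
    data.frame(series_id = "S1", core_key = "k1",
               compound_id = c("x", "p", "q"), substituent = "*C"),
    data.frame(series_id = "S2", core_key = "k2",
               compound_id = c("x", "r", "s"), substituent = "*C"))
  labels <- c(x = 1, p = 0, q = 0, r = 0, s = 1)
  for (seed in 1:50) {
    sp <- intra_series_split(mms, labels, seed = seed)
    both <- intersect(sp$train$compound_id, sp$test$compound_id)
    expect_length(both, 0)
  }
})

test_that("split invariants hold across seeded random fixtures", {
  for (seed in 1:200) {
    fx <- random_split_fixture(seed)
    sp <- intra_series_split(fx$mms, fx$labels, seed = seed + 1000)
    expect_length(intersect(sp$train$compound_id, sp$test$compound_id), 0)

    su <- series_unit_split(fx$mms, fx$labels, seed = seed + 2000)
    expect_length(intersect(su$train$compound_id, su$test$compound_id), 0)
    for (sid in unique(fx$mms$series_id)) {
      mem <- unique(fx$mms$compound_id[fx$mms$series_id == sid])
      in_train <- mem %in% su$train$compound_id
      expect_true(all(in_train) || !any(in_train))
    }
  }
})

test_that("intra-series orientations are balanced over seeds", {
  mms <- data.frame(series_id = "S1", core_key = "k",
                    compound_id = c("a1", "a2", "i1"), substituent = "*C")
  labels <- c(a1 = 1, a2 = 1, i1 = 0)
  actives_in_train <- vapply(1:400, function(seed) {
    sp <- intra_series_split(mms, labels, seed = seed)
    "a1" %in% sp$train$compound_id
  }, TRUE)
  # 95% binomial band around 0.5 for n = 400
  expect_gt(mean(actives_in_train), 0.5 - 1.96 * 0.5 / 20)
  expect_lt(mean(actives_in_train), 0.5 + 1.96 * 0.5 / 20)
})

test_that("series-unit split hits the achievable 80:20 compound ratio", {
  # 5 equal series: exactly 4 train / 1 test
  mms5 <- data.frame(series_id = rep(sprintf("S%d", 1:5), each = 4),
                     core_key = rep(sprintf("k%d", 1:5), each = 4),
                     compound_id = sprintf("c%02d", 1:20),
                     substituent = "*C")
  labels5 <- setNames(rep(c(1, 0), 10), mms5$compound_id)
  sp <- series_unit_split(mms5, labels5, seed = 7)
  expect_equal(nrow(sp$train), 16)
  expect_equal(nrow(sp$test), 4)

  # sizes 8 and 2: the 8-compound series must train
  mms2 <- data.frame(series_id = rep(c("S1", "S2"), c(8, 2)),
                     core_key = rep(c("k1", "k2"), c(8, 2)),
                     compound_id = sprintf("c%02d", 1:10),
                     substituent = "*C")
  labels2 <- setNames(rep(c(1, 0), 5), mms2$compound_id)
  for (seed in 1:20) {
    sp2 <- series_unit_split(mms2, labels2, seed = seed)
    expect_setequal(sp2$train$compound_id, sprintf("c%02d", 1:8))
  }

  expect_error(series_unit_split(mms2[1:8, ], labels2[1:8], seed = 1),
               "at least 2")
})

test_that("class weights follow the inverse-frequency rule", {
  expect_equal(class_weights(rep(c(0, 1), 25)), c("0" = 1, "1" = 1))
  w <- class_weights(c(rep(1, 10), rep(0, 30)))
  expect_equal(w[["1"]], 2.0)
  expect_equal(w[["0"]], 2 / 3)
  # permutation symmetry
  w_flip <- class_weights(c(rep(0, 10), rep(1, 30)))
  expect_equal(unname(w_flip[c("1", "0")]), unname(w[c("0", "1")]))
  expect_error(class_weights(rep(1, 5)), "both labels")
})

test_that("profile-silent compounds trigger series exclusion under both readings", {
  fx <- random_split_fixture(11, n_series = 4)
  cpds <- names(fx$labels)
  prof <- matrix(rbinom(length(cpds) * 3, 1, 0.6), ncol = 3,
                 dimnames = list(cpds, c("p1", "p2", "p3")))
  silent <- unique(fx$mms$compound_id[fx$mms$series_id == "S002"])[1]
  prof[silent, ] <- 0L
  prof[cpds[1], 1] <- 1L  # ensure the matrix keeps at least c1 active
  m <- profiling_matrix(prof)

  kept <- exclude_silent_series(fx$mms, m, c("p1", "p2", "p3"))
  expect_false("S002" %in% kept$series_id)
  expect_equal(attr(kept, "n_series_dropped"), 1)

  kept2 <- exclude_silent_series(fx$mms, m, c("p1", "p2", "p3"),
                                 drop = "compounds")
  expect_false(silent %in% kept2$compound_id)
  # series survives if at least two members remain
  remaining <- length(unique(
    fx$mms$compound_id[fx$mms$series_id == "S002"])) - 1
  expect_equal("S002" %in% kept2$series_id, remaining >= 2)

  expect_error(exclude_silent_series(fx$mms, m, character()), "empty")
})
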