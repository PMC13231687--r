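# Profiling matrix container, preprocessing, assay similarity, leakage
# instrumentation.

test_that("matrix validation reports bad cells and duplicate ids", {
  vals <- matrix(c(1, 0, 0, 1, 0, 1), nrow = 3,
                 dimnames = list(c("c1", "c2", "c3"), c("a1", "a2")))
  m <- profiling_matrix(vals)
  expect_equal(dim(m), c(3, 2))

  bad <- vals; bad[2, 1] <- NA
  expect_error(profiling_matrix(bad), "c2.*a1")
  bad2 <- vals; bad2[1, 2] <- 2
  expect_error(profiling_matrix(bad2), "non-binary")
  dup <- vals; rownames(dup) <- c("c1", "c1", "c3")
  expect_error(profiling_matrix(dup), "duplicate compound_id")
})

test_that("matrix TSV round-trips and blank/non-binary cells error", {
  m <- random_profiling_matrix(6, 4, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, path)
  m2 <- load_matrix(path)
  expect_identical(m2$values, m$values)

  lines <- readLines(path)
  lines[3] <- sub("\t\\d", "\t", lines[3])  # blank out one cell
  broken <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, broken)
  expect_error(load_matrix(broken), "blank|missing")

  lines2 <- readLines(path)
  lines2[2] <- sub("\t(\\d)$", "\t7", lines2[2])
  broken2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines2, broken2)
  expect_error(load_matrix(broken2), "non-binary")
})

test_that("all-inactive rows are dropped idempotently, order preserved", {
  vals <- matrix(c(0, 1, 0, 0, 0, 1), nrow = 3,
                 dimnames = list(c("c1", "c2", "c3"), c("a1", "a2")))
  m <- drop_all_inactive_compounds(profiling_matrix(vals))
  expect_equal(m$compound_ids, c("c2", "c3"))
  expect_equal(m$assay_ids, c("a1", "a2"))
  m_again <- drop_all_inactive_compounds(m)
  expect_identical(m_again$values, m$values)

  all_active <- profiling_matrix(matrix(1, 2, 2,
    dimnames = list(c("x", "y"), c("a", "b"))))
  expect_identical(drop_all_inactive_compounds(all_active)$values,
                   all_active$values)
})

test_that("active sets respect the compound restriction", {
  vals <- matrix(c(1, 0, 1), ncol = 1,
                 dimnames = list(c("c1", "c2", "c3"), "a1"))
  m <- profiling_matrix(vals)
  expect_setequal(active_set(m, "a1", c("c1", "c2")), "c1")
  expect_equal(active_set(m, "a1", character()), character())
  expect_setequal(active_set(m, "a1"), c("c1", "c3"))
  expect_error(active_set(m, "nope"), "unknown assay")
})

test_that("assay Tanimoto matches set arithmetic, incl. degenerate cases", {
  # A = {c1,c2,c3}, B = {c2,c3,c4} -> 2/4
  vals <- matrix(0L, 5, 2, dimnames = list(sprintf("c%d", 1:5),
                                           c("a", "b")))
  vals[1:3, "a"] <- 1L
  vals[2:4, "b"] <- 1L
  m <- profiling_matrix(vals)
  expect_equal(assay_tanimoto(m, "a", "b"), 0.5)
  expect_equal(assay_tanimoto(m, "a", "a"), 1.0)
  expect_equal(assay_tanimoto(m, "b", "a"), assay_tanimoto(m, "a", "b"))
  # disjoint and empty active sets
  expect_equal(assay_tanimoto(m, "a", "b", restriction = c("c1", "c4")), 0)
  expect_equal(assay_tanimoto(m, "a", "b", restriction = "c5"), 0)
})

test_that("assay Tanimoto equals brute force on random matrices", {
  for (seed in 1:100) {
    m <- random_profiling_matrix(20, 10, rate = 0.25, seed = seed)
    restriction <- sample(m$compound_ids, sample(5:20, 1))
    pick <- sample(m$assay_ids, 2)
    got <- assay_tanimoto(m, pick[1], pick[2], restriction)
    want <- brute_tanimoto(m$values[, pick[1]], m$values[, pick[2]],
                           restriction)
    expect_equal(got, want)
    expect_gte(got, 0); expect_lte(got, 1)
    expect_equal(got, assay_tanimoto(m, pick[2], pick[1], restriction))
  }
})

test_that("profile assay ranking is ordered, complete and tie-stable", {
  # planted duplicate ranks first at 1.0
  m <- random_profiling_matrix(15, 5, rate = 0.4, seed = 3)
  vals <- m$values
  vals <- cbind(vals, dup = vals[, "a01"])
  m2 <- profiling_matrix(vals)
  rk <- rank_profile_assays(m2, "a01", setdiff(colnames(vals), "a01"),
                            m2$compound_ids)
  expect_equal(rk$profile_assay[1], "dup")
  expect_equal(rk$tanimoto[1], 1.0)
  expect_equal(nrow(rk), 5)

  # all-zero on train: similarity 0 everywhere, ranked by assay id
  zeros <- matrix(0L, 4, 4, dimnames = list(sprintf("c%d", 1:4),
                                            c("t", "p3", "p1", "p2")))
  zeros[, "t"] <- c(1L, 0L, 0L, 0L)
  mz <- profiling_matrix(zeros)
  rkz <- rank_profile_assays(mz, "t", c("p3", "p1", "p2"),
                             train_compounds = c("c2", "c3"))
  expect_equal(rkz$profile_assay, c("p1", "p2", "p3"))
  expect_equal(rkz$tanimoto, c(0, 0, 0))

  # ties 0.5 / 0.2 / 0.5 -> the two 0.5 assays first, by assay id
  v <- matrix(0L, 10, 4, dimnames = list(sprintf("c%d", 1:10),
                                         c("t", "pB", "pA", "pC")))
  v[1:4, "t"] <- 1L
  v[c(1, 2, 3, 5), "pB"] <- 1L   # |int|=3, |uni|=5 -> 0.6? no: 3/5
  v[c(1, 2, 3, 5), "pA"] <- 1L
  v[c(1, 9, 10), "pC"] <- 1L     # 1/6
  mv <- profiling_matrix(v)
  rkv <- rank_profile_assays(mv, "t", c("pB", "pA", "pC"), rownames(v))
  expect_equal(rkv$profile_assay, c("pA", "pB", "pC"))
  expect_equal(rkv$tanimoto[1], rkv$tanimoto[2])

  expect_error(rank_profile_assays(mv, "t", c("t", "pA"), rownames(v)),
               "must not")
})

test_that("similarity restricted to training compounds never reads test cells", {
  m <- instrumented_matrix(random_profiling_matrix(20, 6, seed = 8))
  train <- m$compound_ids[1:12]
  test <- m$compound_ids[13:20]
  invisible(access_log(m, clear = TRUE))
  rk <- rank_profile_assays(m, "a01", paste0("a0", 2:6), train)
  expect_false(accessed_cells(m, test, m$assay_ids))
  expect_true(accessed_cells(m, train, "a01"))
})

test_that("sparsity summaries are percentages over assays", {
  vals <- matrix(0L, 100, 2, dimnames = list(sprintf("c%03d", 1:100),
                                             c("a", "b")))
  vals[1, "a"] <- 1L
  vals[1:3, "b"] <- 1L
  m <- profiling_matrix(vals)
  s <- summarize_sparsity(m)
  expect_equal(s$median, 2)
  expect_equal(s$mean, 2)
  expect_equal(s$sd, sd(c(1, 3)))

  uniform <- profiling_matrix(matrix(c(1L, 0L), 2, 3,
    dimnames = list(c("x", "y"), c("a", "b", "c"))))
  expect_equal(summarize_sparsity(uniform)$sd, 0)
})
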