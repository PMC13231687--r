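# Fragmentation, matching molecular series assembly and activity cliff
# enumeration.

test_that("toluene yields the single methyl fragmentation", {
  fr <- fragment_molecule("Cc1ccccc1", "toluene")
  expect_equal(nrow(fr), 1)
  expect_equal(fr$substituent, "*C")
  expect_equal(fr$core_key, "*c1ccccc1")
  expect_equal(fr$n_sub, 1)
  expect_equal(fr$n_att, 1)
})

test_that("molecules above the heavy-atom cap return no fragmentations", {
  big <- paste(rep("C", 61), collapse = "")
  expect_equal(nrow(fragment_molecule(big, "c61")), 0)
  just_ok <- paste(rep("C", 60), collapse = "")
  expect_gt(nrow(fragment_molecule(just_ok, "c60")), 0)
})

test_that("the fragment-to-size ratio filter is inclusive at the boundary", {
  # decane: substituents of 1-3 carbons pass (ratio up to 0.2), larger fail
  fr <- fragment_molecule(paste(rep("C", 10), collapse = ""), "decane")
  expect_setequal(fr$n_sub, c(1, 2, 3))
  expect_true(all((fr$n_sub - fr$n_att) / 10 <= 0.2))
  # tighter threshold can only lose fragmentations (monotone filter)
  for (mol in c("CCc1ccc(F)cc1", "COc1ccncc1", "CCCCCCCCCC")) {
    counts <- vapply(c(0.1, 0.2, 0.3), function(th) {
      nrow(fragment_molecule(mol, "m", ratio_threshold = th))
    }, 1L)
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("equal-size fragmentations emit both passing orientations", {
  fr <- fragment_molecule("CO", "methanol")
  expect_equal(nrow(fr), 2)
  expect_setequal(fr$core_key, c("*C", "*O"))
})

test_that("double cuts produce two-attachment linker substituents", {
  fr <- fragment_molecule("c1ccccc1CCc1ccccc1", "bibenzyl", cuts = 2)
  two <- fr[fr$n_att == 2, ]
  expect_gt(nrow(two), 0)
  expect_true(all(two$n_sub >= 1))
  expect_true(all((two$n_sub - 2) / 14 <= 0.2))
  # the ethylene linker between the two phenyls is one of them
  expect_true(any(two$n_sub == 2))
})

test_that("bad structures raise input errors naming the compound", {
  expect_error(fragment_molecule("C1CC", "broken"), "broken")
  expect_error(fragment_molecule("CC.CC", "salt"), "disconnected|salt")
  expect_error(molecule_library(c("C", "C1CC"), c("ok", "bad")), "bad")
})

test_that("compounds sharing a core form one MMS; singleton cores none", {
  lib <- molecule_library(c("Cc1ccc(F)cc1", "CCc1ccc(F)cc1", "CCCCO"),
                          c("tolF", "etbF", "butanol"))
  mms <- build_mms(fragment_library(lib))
  # fluoro-phenyl core carries both analogues
  core <- mms[mms$core_key == "*c1ccc(cc1)F", ]
  expect_setequal(core$compound_id, c("tolF", "etbF"))
  expect_equal(length(unique(core$series_id)), 1)
  # butanol shares no core with anything
  expect_false("butanol" %in% mms$compound_id)
  # every series has >= 2 distinct compounds
  n_per_series <- tapply(mms$compound_id, mms$series_id,
                         function(x) length(unique(x)))
  expect_true(all(n_per_series >= 2))
})

test_that("overlapping series membership is allowed and deterministic", {
  lib <- molecule_library(c("CCc1ccc(F)cc1", "CCCc1ccc(F)cc1"), c("a", "b"))
  mms1 <- build_mms(fragment_library(lib))
  # a and b share two cores pairwise -> two series, both containing a and b
  expect_equal(length(unique(mms1$series_id)), 2)
  for (sid in unique(mms1$series_id)) {
    expect_setequal(mms1$compound_id[mms1$series_id == sid], c("a", "b"))
  }
  # series ids are ranks of sorted core keys: rerun is identical
  mms2 <- build_mms(fragment_library(lib))
  expect_identical(mms1, mms2)
  expect_equal(mms1$series_id[1], "S0001")
})

test_that("identical cores from different parents are byte-identical", {
  fr1 <- fragment_molecule("Cc1ccc(Cl)cc1", "p1")
  fr2 <- fragment_molecule("CCc1ccc(Cl)cc1", "p2")
  shared <- intersect(fr1$core_key, fr2$core_key)
  expect_true("*c1ccc(cc1)Cl" %in% shared)
})

test_that("activity cliffs are every active x inactive pair of a series", {
  series <- data.frame(series_id = "S1", core_key = "k",
                       compound_id = c("a1", "a2", "i1", "i2", "i3"),
                       substituent = "*C", stringsAsFactors = FALSE)
  labels <- c(a1 = 1, a2 = 1, i1 = 0, i2 = 0, i3 = 0)
  acs <- extract_acs(series, labels, "assayX")
  expect_equal(nrow(acs), 6)  # 2 actives x 3 inactives
  expect_setequal(unique(acs$active_id), c("a1", "a2"))
  expect_setequal(unique(acs$inactive_id), c("i1", "i2", "i3"))

  all_active <- setNames(rep(1, 5), series$compound_id)
  expect_equal(nrow(extract_acs(series, all_active, "assayX")), 0)

  small <- series[1:3, ]
  acs2 <- extract_acs(small, c(a1 = 1, a2 = 1, i1 = 0), "assayX")
  expect_setequal(paste(acs2$active_id, acs2$inactive_id),
                  c("a1 i1", "a2 i1"))

  expect_error(extract_acs(series, labels[-1], "assayX"), "complete")
})

test_that("AC counts equal n_active x n_inactive on random fixtures", {
  for (seed in 1:50) {
    fx <- random_split_fixture(seed)
    for (sid in unique(fx$mms$series_id)) {
      series <- fx$mms[fx$mms$series_id == sid, ]
      acs <- extract_acs(series, fx$labels, "t")
      lab <- fx$labels[unique(series$compound_id)]
      expect_equal(nrow(acs), sum(lab == 1) * sum(lab == 0))
    }
  }
})

test_that("unique AC compounds per assay match a brute-force union", {
  fx <- random_split_fixture(7)
  cpds <- names(fx$labels)
  vals <- cbind(t1 = fx$labels,
                homog = rep(0L, length(cpds)),
                t2 = rbinom(length(cpds), 1, 0.5))
  rownames(vals) <- cpds
  m <- profiling_matrix(vals)
  got <- ac_compounds_per_assay(fx$mms, m)
  expect_equal(got$homog, character())
  for (a in c("t1", "t2")) {
    expected <- character()
    for (sid in unique(fx$mms$series_id)) {
      series <- fx$mms[fx$mms$series_id == sid, ]
      acs <- extract_acs(series, setNames(vals[, a], cpds), a)
      expected <- union(expected, c(acs$active_id, acs$inactive_id))
    }
    expect_setequal(got[[a]], expected)
  }
})

test_that("synthetic analog series round-trip through fragmentation", {
  cfg <- synthetic_config(n_series = 6, analogs_per_series = c(3, 4),
                          n_assays = 10, n_test_assays = 2, seed = 31)
  lib <- generate_library(cfg)
  mms <- build_mms(fragment_library(lib$library))
  expect_equal(series_recovery(mms, lib$series_truth), 1.0)
})
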