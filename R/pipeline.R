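# End-to-end experiment orchestration: data assembly, test-assay selection,
# per-assay leakage-controlled splits, representation construction, model
# training, the 1-NN baseline, metrics, performance grouping and paired
# statistics. One master seed fans out deterministically to every cell so
# reruns reproduce all tables; failing cells are logged and yield NA metrics
# instead of aborting a sweep.

#' Select hold-out test assays by activity cliff richness
#'
#' Assays qualify when they hold at least `min_ac_compounds` unique activity
#' cliff compounds; `n` eligible assays are sampled without replacement
#' under the seed and all remaining assays (eligible or not) form the
#' bioactivity profile.
#'
#' @param m a [profiling_matrix()].
#' @param mms MMS table from [build_mms()].
#' @param min_ac_compounds eligibility threshold (default 500, the
#'   full-scale setting).
#' @param n number of test assays to sample (default 50).
#' @param seed sampling seed.
#' @return list with `test_assays`, `profile_assays` and the per-assay
#'   `ac_counts`.
#' @export
select_test_assays <- function(m, mms, min_ac_compounds = 500, n = 50,
                               seed = 1) {
  counts <- lengths(ac_compounds_per_assay(mms, m))
  eligible <- names(counts)[counts >= min_ac_compounds]
  if (length(eligible) < n) {
    stop_input(paste0("only %d of %d assays have >= %d unique AC compounds ",
                      "(max observed %d); cannot sample %d test assays"),
               length(eligible), length(counts), min_ac_compounds,
               max(counts), n)
  }
  test_assays <- sort(with_seed(seed, sample(eligible, n)))
  list(test_assays = test_assays,
       profile_assays = setdiff(m$assay_ids, test_assays),
       ac_counts = counts)
}

#' Configure an end-to-end experiment
#'
#' @param matrix a [profiling_matrix()] or path to a matrix TSV; ignored
#'   when `synthetic` is given.
#' @param library a compound library table ([molecule_library()]) or path to
#'   a `SMILES<TAB>compound_id` file; ignored when `synthetic` is given.
#' @param synthetic optional [synthetic_config()]; when set, library and
#'   matrix are generated.
#' @param n_test_assays number of hold-out assays (ignored when
#'   `test_assays` is given).
#' @param min_ac_compounds test-assay eligibility threshold.
#' @param test_assays explicit test assay ids (skips eligibility sampling).
#' @param schemes any of `"intra_series"`, `"series_unit"`.
#' @param representations any of `"profile_all"`, `"profile_top50"`,
#'   `"profile_top10"`, `"profile_rand50"`, `"profile_rand10"`, `"ecfp4"`,
#'   `"combined"`.
#' @param algos any of `"RF"`, `"XGB"`, `"SVM"`.
#' @param include_one_nn run the 1-NN assay transfer baseline per test
#'   assay.
#' @param random_draws independent draws of each random profile reduction
#'   (`profile_rand50`, `profile_rand10`) per assay; metrics are averaged
#'   over draws (default 3, which tightens the control estimate without
#'   biasing it).
#' @param grids optional named list (per algo) of hyperparameter grids
#'   overriding the [model_spec()] defaults.
#' @param cv_folds cross-validation folds.
#' @param train_ratio series-unit training compound fraction.
#' @param exclude_silent drop series containing compounds with all-zero
#'   profiles over the profile assays.
#' @param seed master seed; all cell seeds derive from it via
#'   [fan_out_seed()].
#' @param output_dir optional directory for TSV outputs and a manifest.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(matrix = NULL, library = NULL, synthetic = NULL,
                              n_test_assays = 50, min_ac_compounds = 500,
                              test_assays = NULL,
                              schemes = c("intra_series", "series_unit"),
                              representations = c("profile_all", "ecfp4",
                                                  "combined"),
                              algos = c("RF", "XGB", "SVM"),
                              include_one_nn = TRUE, random_draws = 3,
                              grids = NULL,
                              cv_folds = 5, train_ratio = 0.8,
                              exclude_silent = TRUE, seed = 1,
                              output_dir = NULL) {
  schemes <- match.arg(schemes, c("intra_series", "series_unit"),
                       several.ok = TRUE)
  representations <- match.arg(
    representations,
    c("profile_all", "profile_top50", "profile_top10", "profile_rand50",
      "profile_rand10", "ecfp4", "combined"), several.ok = TRUE)
  algos <- match.arg(algos, c("RF", "XGB", "SVM"), several.ok = TRUE)
  if (is.null(synthetic) && (is.null(matrix) || is.null(library))) {
    stop_input("provide either a synthetic config or both matrix and library")
  }
  structure(list(matrix = matrix, library = library, synthetic = synthetic,
                 n_test_assays = n_test_assays,
                 min_ac_compounds = min_ac_compounds,
                 test_assays = test_assays, schemes = schemes,
                 representations = representations, algos = algos,
                 include_one_nn = include_one_nn,
                 random_draws = as.integer(random_draws), grids = grids,
                 cv_folds = cv_folds, train_ratio = train_ratio,
                 exclude_silent = exclude_silent, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "experiment_config")
}

#' Run an end-to-end activity cliff prediction experiment
#'
#' For every (test assay x scheme x representation x algorithm) cell:
#' leakage-controlled split, assay similarity ranking on training compounds,
#' representation construction, grid-search cross-validated training,
#' test-set scoring and BA / ROC-AUC / MCC computation; plus the 1-NN assay
#' transfer baseline per test assay and MDI feature importances for every
#' random forest trained on the full bioactivity profile. Results are
#' grouped into positive / interquartile / negative performance tiers by
#' MCC quartiles per cell, and representations are compared by paired
#' Wilcoxon tests with Holm adjustment.
#'
#' @param cfg an [experiment_config()].
#' @return list with data frames `results`, `predictions`, `importances`,
#'   `statistics`, `splits`, plus `mms`, `test_assays`, `profile_assays`,
#'   `failures` and (for synthetic runs) `truth`. When `cfg$output_dir` is
#'   set, all tables are also written as TSV together with a JSON manifest
#'   of file checksums, the configuration and the seed.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  seed <- cfg$seed
  truth <- NULL
  if (!is.null(cfg$synthetic)) {
    lib <- generate_library(cfg$synthetic)
    gen <- generate_matrix(cfg$synthetic, lib)
    library <- lib$library
    matrix <- gen$matrix
    truth <- c(gen$truth, list(series_truth = lib$series_truth))
  } else {
    matrix <- if (is.character(cfg$matrix)) load_matrix(cfg$matrix) else cfg$matrix
    library <- if (is.character(cfg$library)) read_smiles(cfg$library) else cfg$library
  }
  frags <- fragment_library(library)
  mms <- build_mms(frags)
  m <- drop_all_inactive_compounds(matrix)
  mms <- restrict_mms(mms, m$compound_ids)
  if (!nrow(mms)) stop_input("no matching molecular series left after preprocessing")

  if (is.null(cfg$test_assays)) {
    sel <- select_test_assays(m, mms, cfg$min_ac_compounds,
                              cfg$n_test_assays,
                              fan_out_seed(seed, "select_test_assays"))
    test_assays <- sel$test_assays
  } else {
    test_assays <- cfg$test_assays
  }
  profile_assays <- setdiff(m$assay_ids, test_assays)
  mms_used <- if (cfg$exclude_silent) {
    exclude_silent_series(mms, m, profile_assays)
  } else mms
  if (!nrow(mms_used)) stop_input("every series was profile-silent")

  needs_fp <- any(cfg$representations %in% c("ecfp4", "combined"))
  fp <- NULL
  if (needs_fp) {
    cpds <- sort(unique(mms_used$compound_id))
    smi <- library$smiles[match(cpds, library$compound_id)]
    fp <- ecfp4_vectors(smi, ids = cpds)
  }

  results <- list(); predictions <- list(); importances <- list()
  splits_out <- list(); failures <- list()
  note_failure <- function(cell, msg) {
    failures[[length(failures) + 1L]] <<- data.frame(
      cell = cell, error = conditionMessage(msg), stringsAsFactors = FALSE)
    message(sprintf("[acprofiles] cell %s failed: %s", cell,
                    conditionMessage(msg)))
  }

  for (ta in test_assays) {
    labels <- setNames(pm_cells(m, assays = ta)[, 1], m$compound_ids)
    for (scheme in cfg$schemes) {
      split_seed <- fan_out_seed(seed, ta, scheme, "split")
      split <- tryCatch({
        if (scheme == "intra_series") {
          intra_series_split(mms_used, labels, split_seed, test_assay = ta)
        } else {
          series_unit_split(mms_used, labels, ratio = cfg$train_ratio,
                            seed = split_seed, test_assay = ta)
        }
      }, error = function(e) {
        note_failure(paste(ta, scheme, "split", sep = "/"), e); NULL
      })
      if (is.null(split)) next
      if (length(unique(split$train$label)) < 2 &&
          scheme == "series_unit") {
        note_failure(paste(ta, scheme, "split", sep = "/"),
                     simpleError("single-class training partition"))
        next
      }
      splits_out[[length(splits_out) + 1L]] <- split_table(split, ta)
      train_ids <- split$train$compound_id
      test_ids <- split$test$compound_id
      y_train <- split$train$label
      y_test <- split$test$label
      ranking <- rank_profile_assays(m, ta, profile_assays, train_ids)

      if (cfg$include_one_nn) {
        row <- tryCatch({
          pred <- one_nn_transfer(m, ta, profile_assays, train_ids, test_ids)
          predictions[[length(predictions) + 1L]] <- data.frame(
            test_assay = ta, scheme = scheme, representation = "profile_all",
            algo = "1NN", compound_id = test_ids, true_label = y_test,
            score = as.numeric(pred), predicted_label = as.integer(pred),
            stringsAsFactors = FALSE)
          metric_row(ta, scheme, "profile_all", "1NN", y_test, pred,
                     scores = pred, n_train = length(train_ids))
        }, error = function(e) {
          note_failure(paste(ta, scheme, "1NN", sep = "/"), e)
          metric_row(ta, scheme, "profile_all", "1NN", NULL, NULL, NULL,
                     n_train = length(train_ids))
        })
        results[[length(results) + 1L]] <- row
      }

      k50 <- floor(length(profile_assays) / 2)
      for (rep_kind in cfg$representations) {
        n_draws <- if (rep_kind %in% c("profile_rand50", "profile_rand10")) {
          max(1L, cfg$random_draws)
        } else 1L
        for (algo in cfg$algos) {
          cell <- paste(ta, scheme, rep_kind, algo, sep = "/")
          draw_rows <- list()
          for (draw in seq_len(n_draws)) {
            row <- tryCatch({
              feats <- representation_features(
                rep_kind, ranking, profile_assays, k50,
                fan_out_seed(seed, ta, scheme, rep_kind, draw))
              Xtr <- build_features(m, fp, train_ids, feats, rep_kind, ta)
              Xte <- build_features(m, fp, test_ids, feats, rep_kind, ta)
              spec <- model_spec(algo, grid = cfg$grids[[algo]],
                                 cv_folds = cfg$cv_folds,
                                 seed = fan_out_seed(seed, ta, scheme,
                                                     rep_kind, algo))
              model <- train_model(spec, Xtr, y_train,
                                   weights = class_weights(y_train))
              scores <- predict_scores(model, Xte)
              pred <- score_to_label(algo, scores)
              if (algo == "RF" && rep_kind == "profile_all") {
                imp <- mdi_importance(model)
                importances[[length(importances) + 1L]] <- data.frame(
                  test_assay = ta, scheme = scheme,
                  feature_id = names(imp), mdi = unname(imp),
                  stringsAsFactors = FALSE)
              }
              if (draw == 1L) {
                predictions[[length(predictions) + 1L]] <- data.frame(
                  test_assay = ta, scheme = scheme,
                  representation = rep_kind, algo = algo,
                  compound_id = test_ids, true_label = y_test,
                  score = unname(scores), predicted_label = unname(pred),
                  stringsAsFactors = FALSE)
              }
              metric_row(ta, scheme, rep_kind, algo, y_test, pred, scores,
                         n_train = length(train_ids))
            }, error = function(e) {
              note_failure(cell, e)
              metric_row(ta, scheme, rep_kind, algo, NULL, NULL, NULL,
                         n_train = length(train_ids))
            })
            draw_rows[[draw]] <- row
          }
          row <- draw_rows[[1L]]
          if (n_draws > 1L) {
            for (col in c("ba", "roc_auc", "mcc")) {
              vals <- vapply(draw_rows, `[[`, 1, col)
              row[[col]] <- if (all(is.na(vals))) NA_real_ else
                mean(vals, na.rm = TRUE)
            }
          }
          results[[length(results) + 1L]] <- row
        }
      }
    }
  }

  results <- do.call(rbind, results)
  results <- add_groups(results)
  stats <- representation_statistics(results)
  out <- list(results = results,
              predictions = do.call(rbind, predictions),
              importances = do.call(rbind, importances),
              statistics = stats,
              splits = do.call(rbind, splits_out),
              mms = mms_used,
              test_assays = test_assays,
              profile_assays = profile_assays,
              failures = do.call(rbind, failures),
              truth = truth,
              seed = seed)
  if (!is.null(cfg$output_dir)) write_experiment(out, cfg)
  out
}

restrict_mms <- function(mms, compound_ids) {
  mms <- mms[mms$compound_id %in% compound_ids, , drop = FALSE]
  sizes <- tapply(mms$compound_id, mms$series_id,
                  function(x) length(unique(x)))
  keep <- names(sizes)[sizes >= 2]
  mms[mms$series_id %in% keep, , drop = FALSE]
}

metric_row <- function(ta, scheme, rep_kind, algo, y_test, pred, scores,
                       n_train) {
  if (is.null(y_test)) {
    return(data.frame(test_assay = ta, scheme = scheme,
                      representation = rep_kind, algo = algo,
                      n_train = n_train, n_test = NA_integer_,
                      ba = NA_real_, roc_auc = NA_real_, mcc = NA_real_,
                      stringsAsFactors = FALSE))
  }
  cc <- confusion_counts(y_test, pred)
  ba <- tryCatch(balanced_accuracy(cc), error = function(e) NA_real_)
  auc <- tryCatch(roc_auc(scores, y_test), error = function(e) NA_real_)
  data.frame(test_assay = ta, scheme = scheme, representation = rep_kind,
             algo = algo, n_train = n_train, n_test = length(y_test),
             ba = ba, roc_auc = auc, mcc = mcc_score(cc),
             stringsAsFactors = FALSE)
}

representation_features <- function(rep_kind, ranking, profile_assays, k50,
                                    seed) {
  switch(rep_kind,
    profile_all = list(assays = profile_assays),
    profile_top50 = list(assays = reduce_profile(ranking, "top_k", k50)),
    profile_top10 = list(assays = reduce_profile(ranking, "top_k", 10)),
    profile_rand50 = list(assays = reduce_profile(ranking, "random_k", k50,
                                                  seed = seed)),
    profile_rand10 = list(assays = reduce_profile(ranking, "random_k", 10,
                                                  seed = seed)),
    ecfp4 = list(assays = NULL),
    combined = list(assays = profile_assays))
}

build_features <- function(m, fp, compounds, feats, rep_kind, test_assay) {
  prof <- if (!is.null(feats$assays)) {
    profile_vectors(m, compounds, feats$assays, test_assay = test_assay)
  } else NULL
  if (rep_kind == "ecfp4") {
    fp[compounds, , drop = FALSE]
  } else if (rep_kind == "combined") {
    combined_vectors(prof, fp[compounds, , drop = FALSE])
  } else {
    prof
  }
}

split_table <- function(split, ta) {
  all <- rbind(cbind(split$train, partition = "train"),
               cbind(split$test, partition = "test"))
  sids <- vapply(all$compound_id, function(c) {
    paste(sort(unique(split$series_map[[c]])), collapse = ";")
  }, "")
  data.frame(test_assay = ta, scheme = split$scheme, seed = split$seed,
             compound_id = all$compound_id, series_id = unname(sids),
             partition = all$partition, label = all$label,
             stringsAsFactors = FALSE)
}

add_groups <- function(results) {
  if (is.null(results) || !nrow(results)) return(results)
  results$group <- NA_character_
  cells <- unique(results[, c("scheme", "representation", "algo")])
  for (i in seq_len(nrow(cells))) {
    idx <- which(results$scheme == cells$scheme[i] &
                   results$representation == cells$representation[i] &
                   results$algo == cells$algo[i] & !is.na(results$mcc))
    if (length(idx) >= 4) {
      grouped <- group_by_mcc(results[idx, , drop = FALSE])
      results$group[idx] <- as.character(grouped$group)
    }
  }
  results
}

representation_statistics <- function(results, metric = "ba") {
  if (is.null(results) || !nrow(results)) return(NULL)
  out <- list()
  cells <- unique(results[, c("scheme", "algo")])
  for (i in seq_len(nrow(cells))) {
    sub <- results[results$scheme == cells$scheme[i] &
                     results$algo == cells$algo[i] &
                     !is.na(results[[metric]]), , drop = FALSE]
    reps <- unique(sub$representation)
    if (length(reps) < 2) next
    # keep assays covered by every representation
    tabs <- lapply(reps, function(r) {
      v <- sub[[metric]][sub$representation == r]
      names(v) <- sub$test_assay[sub$representation == r]
      v
    })
    names(tabs) <- reps
    common <- Reduce(intersect, lapply(tabs, names))
    if (length(common) < 5) next
    tabs <- lapply(tabs, `[`, common)
    st <- paired_wilcoxon_holm(tabs)
    st <- cbind(scheme = cells$scheme[i], algo = cells$algo[i],
                metric = metric, st)
    out[[length(out) + 1L]] <- st
  }
  if (length(out)) do.call(rbind, out) else NULL
}

write_experiment <- function(out, cfg) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wr <- function(df, name) {
    if (is.null(df) || !nrow(df)) return(invisible())
    p <- file.path(cfg$output_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, p)
  }
  wr(out$results, "results.tsv")
  wr(out$predictions, "predictions.tsv")
  wr(out$importances, "importances.tsv")
  wr(out$statistics, "statistics.tsv")
  wr(out$splits, "splits.tsv")
  wr(out$mms, "mms.tsv")
  wr(out$failures, "failures.tsv")
  manifest <- list(
    package = "acprofiles",
    version = as.character(utils::packageVersion("acprofiles")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = out$seed,
    config = cfg[setdiff(names(cfg), c("matrix", "library", "grids"))],
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(out)
}
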