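# Leakage-controlled train/test partitioning over matching molecular
# series. Both schemes guarantee disjoint compound partitions; the
# intra-series split additionally guarantees per-series label purity (all
# training members of a series carry one label, all test members the
# opposite), while the series-unit split never places one series on both
# sides of the boundary.

new_split <- function(scheme, train, test, series_map, seed, dropped,
                      test_assay = NA_character_) {
  structure(list(test_assay = test_assay, scheme = scheme,
                 train = train, test = test,
                 series_map = series_map, seed = seed, dropped = dropped),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("%s split (seed %d): %d train / %d test compounds, %d series",
              x$scheme, x$seed, nrow(x$train), nrow(x$test),
              length(unique(unlist(x$series_map)))),
      sprintf("; dropped: %d without both labels, %d conflicting\n",
              x$dropped$no_ac, x$dropped$conflict))
  invisible(x)
}

# AC-forming series only: members with both labels present
ac_series <- function(mms, labels) {
  members <- unique(mms$compound_id)
  missing <- setdiff(members, names(labels))
  if (length(missing)) {
    stop_input("no assay label for series member '%s'", missing[1])
  }
  by_series <- split(mms$compound_id, mms$series_id)
  by_series <- lapply(by_series, unique)
  keep <- vapply(by_series, function(mem) {
    lab <- labels[mem]
    any(lab == 1) && any(lab == 0)
  }, TRUE)
  list(series = by_series[keep], n_dropped = sum(!keep))
}

#' Intra-series train/test split
#'
#' For every activity-cliff-forming series, all active members go to one
#' partition and all inactive members to the other; the orientation
#' (actives to train, or the reverse) is drawn per series with probability
#' 0.5 under the seed. Compounds belonging to several series keep their
#' first assignment (series are processed in seeded shuffled order); a later
#' series whose label purity would be violated by an already-pinned compound
#' is dropped and counted.
#'
#' @param mms MMS table from [build_mms()] (AC-forming series need at least
#'   one active and one inactive member; others are excluded and counted).
#' @param labels named 0/1 vector: test-assay activity label per compound.
#' @param seed integer seed controlling series order and orientations.
#' @param test_assay optional assay id stored in the result.
#' @return a `split_assignment`: `train` and `test` data frames
#'   (`compound_id`, `label`), `series_map`, `seed` and dropped-series
#'   counts.
#' @export
intra_series_split <- function(mms, labels, seed, test_assay = NA_character_) {
  acs <- ac_series(mms, labels)
  if (!length(acs$series)) stop_input("no series with both labels present")
  assign_part <- character()   # compound -> "train"/"test"
  conflict <- 0L
  used_series <- list()
  with_seed(seed, {
    ord <- sample(names(acs$series))
    for (sid in ord) {
      mem <- acs$series[[sid]]
      lab <- labels[mem]
      actives_to_train <- runif(1) < 0.5
      part <- ifelse((lab == 1) == actives_to_train, "train", "test")
      names(part) <- mem
      pinned <- intersect(mem, names(assign_part))
      if (any(part[pinned] != assign_part[pinned])) {
        conflict <- conflict + 1L
        next
      }
      new <- setdiff(mem, pinned)
      assign_part[new] <- part[new]
      used_series[[sid]] <- mem
    }
  })
  if (!any(assign_part == "train") || !any(assign_part == "test")) {
    stop_input("intra-series split produced an empty partition")
  }
  cpds <- names(assign_part)
  df <- data.frame(compound_id = cpds, label = unname(labels[cpds]),
                   stringsAsFactors = FALSE)
  series_map <- split(rep(names(used_series), lengths(used_series)),
                      unlist(used_series))
  new_split("intra_series",
            df[assign_part == "train", , drop = FALSE],
            df[assign_part == "test", , drop = FALSE],
            series_map, seed,
            list(no_ac = acs$n_dropped, conflict = conflict), test_assay)
}

#' Series-unit train/test split
#'
#' Assigns entire series (never splitting one series across the boundary) so
#' that the training partition holds as close as achievable to `ratio` of
#' the compounds. Series sharing compounds are merged into clusters first,
#' which removes assignment conflicts by construction; clusters are shuffled
#' under the seed, assigned greedily against the target and then locally
#' repaired (single-cluster moves) towards the closest achievable compound
#' ratio.
#'
#' @inheritParams intra_series_split
#' @param ratio target fraction of compounds in the training partition
#'   (default 0.8).
#' @return a `split_assignment` (see [intra_series_split()]).
#' @export
series_unit_split <- function(mms, labels, ratio = 0.8, seed,
                              test_assay = NA_character_) {
  stopifnot(ratio > 0, ratio < 1)
  acs <- ac_series(mms, labels)
  if (length(acs$series) < 2) {
    stop_input("series-unit split needs at least 2 activity-cliff series")
  }
  # merge series sharing compounds into clusters (union-find)
  sids <- names(acs$series)
  parent <- setNames(seq_along(sids), sids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  by_compound <- split(rep(sids, lengths(acs$series)), unlist(acs$series))
  for (ss in by_compound) {
    if (length(ss) > 1) {
      roots <- vapply(ss, function(s) find(which(sids == s)), 1L)
      parent[roots] <- roots[1]
    }
  }
  root <- vapply(seq_along(sids), find, 1L)
  clusters <- split(sids, root)
  cl_members <- lapply(clusters, function(ss) {
    unique(unlist(acs$series[ss]))
  })
  if (length(clusters) < 2) {
    stop_input("all series overlap into a single cluster; cannot form both partitions")
  }
  sizes <- lengths(cl_members)
  target <- ratio * sum(sizes)
  in_train <- with_seed(seed, {
    ord <- sample(length(clusters))
    tr <- logical(length(clusters))
    cur <- 0
    for (i in ord) {
      if (abs(cur + sizes[i] - target) <= abs(cur - target)) {
        tr[i] <- TRUE
        cur <- cur + sizes[i]
      }
    }
    # guarantee non-empty partitions
    if (!any(tr)) tr[ord[1]] <- TRUE
    if (all(tr)) tr[ord[length(ord)]] <- FALSE
    # local repair: single-cluster moves, then pairwise swaps, while that
    # tightens the compound ratio towards the closest achievable split
    repeat {
      cur <- sum(sizes[tr])
      dev <- abs(cur - target)
      improved <- FALSE
      for (i in seq_along(tr)) {
        if (tr[i] && sum(tr) == 1) next
        if (!tr[i] && sum(!tr) == 1) next
        nd <- abs(cur + (if (tr[i]) -sizes[i] else sizes[i]) - target)
        if (nd < dev - 1e-9) {
          tr[i] <- !tr[i]
          improved <- TRUE
          break
        }
      }
      if (improved) next
      ti <- which(tr); te <- which(!tr)
      for (i in ti) {
        for (j in te) {
          nd <- abs(cur - sizes[i] + sizes[j] - target)
          if (nd < dev - 1e-9) {
            tr[i] <- FALSE; tr[j] <- TRUE
            improved <- TRUE
            break
          }
        }
        if (improved) break
      }
      if (!improved) break
    }
    # exact fallback: if local repair missed the closest achievable train
    # size (rare 2-for-1 exchanges), reconstruct one by subset-sum DP over
    # the shuffled cluster order
    total <- sum(sizes)
    reach <- matrix(FALSE, length(ord) + 1L, total + 1L)
    reach[1, 1] <- TRUE
    for (k in seq_along(ord)) {
      s <- sizes[ord[k]]
      reach[k + 1L, ] <- reach[k, ]
      reach[k + 1L, (s + 1L):(total + 1L)] <-
        reach[k + 1L, (s + 1L):(total + 1L)] | reach[k, 1:(total - s + 1L)]
    }
    cand <- which(reach[length(ord) + 1L, ]) - 1L
    cand <- cand[cand > 0 & cand < total]
    best_sum <- cand[which.min(abs(cand - target))]
    if (abs(sum(sizes[tr]) - target) > abs(best_sum - target) + 1e-9) {
      tr <- logical(length(sizes))
      s <- best_sum
      for (k in rev(seq_along(ord))) {
        if (!reach[k, s + 1L]) {   # not achievable without this cluster
          tr[ord[k]] <- TRUE
          s <- s - sizes[ord[k]]
        }
      }
    }
    tr
  })
  part <- character()
  for (i in seq_along(clusters)) {
    part[cl_members[[i]]] <- if (in_train[i]) "train" else "test"
  }
  cpds <- names(part)
  df <- data.frame(compound_id = cpds, label = unname(labels[cpds]),
                   stringsAsFactors = FALSE)
  series_map <- split(rep(sids, lengths(acs$series)), unlist(acs$series))
  new_split("series_unit",
            df[part == "train", , drop = FALSE],
            df[part == "test", , drop = FALSE],
            series_map, seed,
            list(no_ac = acs$n_dropped, conflict = 0L), test_assay)
}

#' Inverse-frequency class weights
#'
#' `weight(label) = n_total / (2 * n_label)`: minority-class samples receive
#' higher relative weight; a balanced input yields unit weights.
#'
#' @param labels 0/1 vector (both classes must be present).
#' @return named numeric vector with elements `"0"` and `"1"`.
#' @export
#' @examples
#' class_weights(c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, rep(0, 30)))
class_weights <- function(labels) {
  tab <- table(factor(labels, levels = c(0, 1)))
  if (any(tab == 0)) stop_input("class weights need both labels present")
  w <- length(labels) / (2 * as.numeric(tab))
  setNames(w, names(tab))
}

#' Exclude series with profile-silent compounds
#'
#' Removes matching molecular series containing compounds whose annotations
#' are consistently inactive across the profile assays (their bioactivity
#' profile carries no information). The default drops the whole series as
#' soon as one member is silent; `drop = "compounds"` instead removes only
#' the silent members and keeps the series when at least two members remain.
#'
#' @param mms MMS table from [build_mms()].
#' @param m a [profiling_matrix()].
#' @param profile_assays non-empty set of profile assay ids.
#' @param drop `"series"` (default) or `"compounds"`.
#' @return the filtered MMS table; attributes `n_series_dropped` and
#'   `n_compounds_dropped` record the removals.
#' @export
exclude_silent_series <- function(mms, m, profile_assays,
                                  drop = c("series", "compounds")) {
  drop <- match.arg(drop)
  if (!length(profile_assays)) stop_input("empty profile assay set")
  members <- unique(mms$compound_id)
  prof <- pm_cells(m, members, profile_assays)
  silent <- members[rowSums(prof) == 0]
  if (drop == "series") {
    bad <- unique(mms$series_id[mms$compound_id %in% silent])
    out <- mms[!(mms$series_id %in% bad), , drop = FALSE]
    n_cpd <- length(setdiff(unique(mms$compound_id), unique(out$compound_id)))
    attr(out, "n_series_dropped") <- length(bad)
    attr(out, "n_compounds_dropped") <- n_cpd
  } else {
    out <- mms[!(mms$compound_id %in% silent), , drop = FALSE]
    sz <- table(out$series_id)[as.character(unique(out$series_id))]
    keep <- names(sz)[vapply(names(sz), function(s) {
      length(unique(out$compound_id[out$series_id == s])) >= 2
    }, TRUE)]
    dropped_series <- length(unique(mms$series_id)) - length(keep)
    out <- out[out$series_id %in% keep, , drop = FALSE]
    attr(out, "n_series_dropped") <- dropped_series
    attr(out, "n_compounds_dropped") <-
      length(setdiff(unique(mms$compound_id), unique(out$compound_id)))
  }
  out
}
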