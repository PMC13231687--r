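# Matching molecular series: systematic fragmentation of compounds into
# core + substituent at acyclic single bonds, and grouping of compounds that
# share an identical (canonical) core.

#' Fragment a molecule into core/substituent pairs
#'
#' Enumerates systematic fragmentations of a molecule by severing acyclic
#' single bonds between heavy atoms. For a single cut the smaller fragment is
#' the substituent and the larger the core (on a size tie, every orientation
#' passing the size filter is emitted); with `cuts = 2` two bonds are severed
#' and the inner linker fragment becomes a two-attachment substituent.
#' Fragmentations are kept only when the substituent passes the
#' fragment-to-size ratio filter `(n_sub - n_att) / n_mol <= ratio_threshold`,
#' where `n_sub` counts substituent heavy atoms (attachment points excluded),
#' `n_att` is the number of attachment points and `n_mol` the heavy-atom
#' count of the parent. Cores and substituents are serialized as canonical
#' SMILES with `*` attachment placeholders, so identical cores reached from
#' different parents compare equal byte-for-byte.
#'
#' @param smiles SMILES of the parent molecule (single connected structure).
#' @param compound_id identifier recorded in the output.
#' @param max_heavy molecules with more heavy atoms return zero
#'   fragmentations (default 60).
#' @param ratio_threshold upper bound for `(n_sub - n_att) / n_mol`
#'   (default 0.2).
#' @param cuts maximum number of simultaneous bond cuts (1, the matched
#'   molecular series convention, or 2).
#' @return a `data.frame` with columns `parent_id`, `core_key`,
#'   `substituent`, `n_sub`, `n_att`; zero rows when no fragmentation is
#'   eligible.
#' @export
#' @examples
#' fragment_molecule("Cc1ccccc1", "toluene")
fragment_molecule <- function(smiles, compound_id = "mol", max_heavy = 60,
                              ratio_threshold = 0.2, cuts = 1) {
  stopifnot(ratio_threshold > 0, ratio_threshold < 1, cuts %in% c(1, 2))
  graph <- parse_mols(smiles, compound_id)[[1]]
  fragment_graph(graph, compound_id, max_heavy, ratio_threshold, cuts)
}

#' Fragment every molecule of a compound library
#'
#' @param library a compound library as returned by [molecule_library()] or
#'   [read_smiles()] (columns `compound_id`, `smiles`).
#' @inheritParams fragment_molecule
#' @return pooled fragmentation table over all compounds (see
#'   [fragment_molecule()]).
#' @export
fragment_library <- function(library, max_heavy = 60, ratio_threshold = 0.2,
                             cuts = 1) {
  stopifnot(all(c("compound_id", "smiles") %in% names(library)))
  graphs <- parse_mols(library$smiles, library$compound_id)
  out <- lapply(seq_along(graphs), function(i) {
    fragment_graph(graphs[[i]], library$compound_id[i], max_heavy,
                   ratio_threshold, cuts)
  })
  do.call(rbind, out)
}

empty_frags <- function() {
  data.frame(parent_id = character(), core_key = character(),
             substituent = character(), n_sub = integer(),
             n_att = integer(), stringsAsFactors = FALSE)
}

# core of the fragmentation algorithm, operating on a parsed graph
fragment_graph <- function(graph, compound_id, max_heavy, ratio_threshold,
                           cuts) {
  n_mol <- length(graph$atoms)
  if (n_mol > max_heavy) return(empty_frags())
  bonds <- graph$bonds
  adj <- adjacency_list(n_mol, bonds)
  cuttable <- which(bonds[, "order"] == 1 &
                      apply(bonds, 1, function(b) {
                        is_bridge(adj, b[["a1"]], b[["a2"]])
                      }))
  if (!length(cuttable)) return(empty_frags())

  pieces <- list()   # fragments awaiting canonicalization
  rows <- list()     # (core piece idx, sub piece idx, n_sub, n_att)
  add_piece <- function(atom_idx, attach) {
    pieces[[length(pieces) + 1L]] <<- list(atoms = atom_idx, attach = attach)
    length(pieces)
  }

  # single cuts
  for (bi in cuttable) {
    u <- bonds[bi, "a1"]; v <- bonds[bi, "a2"]
    side_u <- reachable(adj, u, exclude = c(u, v), from_edge = bi, bonds)
    side_v <- setdiff(seq_len(n_mol), side_u)
    cands <- if (length(side_u) < length(side_v)) {
      list(list(sub = side_u, core = side_v, su = u, cv = v))
    } else if (length(side_v) < length(side_u)) {
      list(list(sub = side_v, core = side_u, su = v, cv = u))
    } else {
      list(list(sub = side_u, core = side_v, su = u, cv = v),
           list(sub = side_v, core = side_u, su = v, cv = u))
    }
    for (cand in cands) {
      n_sub <- length(cand$sub)
      if ((n_sub - 1) / n_mol <= ratio_threshold) {
        ci <- add_piece(cand$core, list(cand$cv))
        si <- add_piece(cand$sub, list(cand$su))
        rows[[length(rows) + 1L]] <- list(core = ci, sub = si,
                                          n_sub = n_sub, n_att = 1L)
      }
    }
  }

  # double cuts: sever two bridges; the middle fragment is the substituent
  if (cuts >= 2 && length(cuttable) >= 2) {
    pairs <- combn(cuttable, 2)
    for (k in seq_len(ncol(pairs))) {
      b1 <- pairs[1, k]; b2 <- pairs[2, k]
      comp <- components_without(adj, n_mol, bonds, c(b1, b2))
      ends1 <- comp[c(bonds[b1, "a1"], bonds[b1, "a2"])]
      ends2 <- comp[c(bonds[b2, "a1"], bonds[b2, "a2"])]
      mid <- intersect(ends1, ends2)
      if (length(mid) != 1) next
      mid_atoms <- which(comp == mid)
      n_sub <- length(mid_atoms)
      if ((n_sub - 2) / n_mol > ratio_threshold) next
      # attachment atoms on the middle piece and the two outer pieces
      att_mid <- c(
        if (comp[bonds[b1, "a1"]] == mid) bonds[b1, "a1"] else bonds[b1, "a2"],
        if (comp[bonds[b2, "a1"]] == mid) bonds[b2, "a1"] else bonds[b2, "a2"])
      att_out <- c(
        if (comp[bonds[b1, "a1"]] == mid) bonds[b1, "a2"] else bonds[b1, "a1"],
        if (comp[bonds[b2, "a1"]] == mid) bonds[b2, "a2"] else bonds[b2, "a1"])
      outer_atoms <- which(comp != mid)
      ci <- add_piece(outer_atoms, as.list(att_out))
      si <- add_piece(mid_atoms, as.list(att_mid))
      rows[[length(rows) + 1L]] <- list(core = ci, sub = si,
                                        n_sub = n_sub, n_att = 2L)
    }
  }
  if (!length(rows)) return(empty_frags())

  blocks <- vapply(seq_along(pieces), function(i) {
    fragment_molblock(graph, pieces[[i]]$atoms, pieces[[i]]$attach,
                      title = paste0("p", i))
  }, "")
  canon <- canonical_from_molblocks(blocks, paste0("p", seq_along(pieces)))
  out <- data.frame(
    parent_id = compound_id,
    core_key = canon[vapply(rows, `[[`, 1L, "core")],
    substituent = canon[vapply(rows, `[[`, 1L, "sub")],
    n_sub = vapply(rows, `[[`, 1L, "n_sub"),
    n_att = vapply(rows, `[[`, 1L, "n_att"),
    stringsAsFactors = FALSE
  )
  unique(out)
}

adjacency_list <- function(n, bonds) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(bonds))) {
    a <- bonds[i, 1]; b <- bonds[i, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, i))
    adj[[b]] <- rbind(adj[[b]], c(a, i))
  }
  adj
}

# is the u-v bond a bridge? BFS from u avoiding the direct edge
is_bridge <- function(adj, u, v) {
  seen <- logical(length(adj))
  seen[u] <- TRUE
  queue <- u
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    nb <- adj[[x]]
    if (is.null(nb)) next
    for (j in seq_len(nrow(nb))) {
      y <- nb[j, 1]
      if (x == u && y == v) next  # skip the candidate edge itself
      if (!seen[y]) {
        if (y == v) return(FALSE)
        seen[y] <- TRUE
        queue <- c(queue, y)
      }
    }
  }
  TRUE
}

# atoms reachable from `start` when edge `from_edge` is removed
reachable <- function(adj, start, exclude, from_edge, bonds) {
  seen <- logical(length(adj))
  seen[start] <- TRUE
  queue <- start
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    nb <- adj[[x]]
    if (is.null(nb)) next
    for (j in seq_len(nrow(nb))) {
      if (nb[j, 2] == from_edge) next
      y <- nb[j, 1]
      if (!seen[y]) {
        seen[y] <- TRUE
        queue <- c(queue, y)
      }
    }
  }
  which(seen)
}

# connected component id per atom after removing the given bond indices
components_without <- function(adj, n, bonds, drop_edges) {
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    comp[s] <- cid
    queue <- s
    while (length(queue)) {
      x <- queue[1]; queue <- queue[-1]
      nb <- adj[[x]]
      if (is.null(nb)) next
      for (j in seq_len(nrow(nb))) {
        if (nb[j, 2] %in% drop_edges) next
        y <- nb[j, 1]
        if (comp[y] == 0L) {
          comp[y] <- cid
          queue <- c(queue, y)
        }
      }
    }
  }
  comp
}

#' Assemble matching molecular series from pooled fragmentations
#'
#' Groups all compounds sharing an identical canonical core into one matching
#' molecular series (MMS). Cores carried by a single compound yield no
#' series. Series identifiers are `"S"` plus the zero-padded rank of the core
#' in lexicographic core order, so the assignment is deterministic.
#'
#' @param frags pooled fragmentation table from [fragment_library()].
#' @return a `data.frame` (one row per series member) with columns
#'   `series_id`, `core_key`, `compound_id`, `substituent`.
#' @export
build_mms <- function(frags) {
  empty <- data.frame(series_id = character(), core_key = character(),
                      compound_id = character(), substituent = character(),
                      stringsAsFactors = FALSE)
  if (is.null(frags) || nrow(frags) == 0) return(empty)
  n_cpd <- tapply(frags$parent_id, frags$core_key,
                  function(x) length(unique(x)))
  keep_cores <- sort(names(n_cpd)[n_cpd >= 2])
  if (!length(keep_cores)) return(empty)
  sid <- setNames(sprintf(paste0("S%0", max(4, nchar(length(keep_cores))), "d"),
                          seq_along(keep_cores)), keep_cores)
  sub <- frags[frags$core_key %in% keep_cores,
               c("core_key", "parent_id", "substituent")]
  out <- data.frame(series_id = unname(sid[sub$core_key]),
                    core_key = sub$core_key,
                    compound_id = sub$parent_id,
                    substituent = sub$substituent,
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out[order(out$series_id, out$compound_id, out$substituent), , drop = FALSE]
}

#' Enumerate activity cliffs within one series for one assay
#'
#' An activity cliff (AC) is a pair of compounds from the same matching
#' molecular series in which one compound is active and the other inactive in
#' the assay under consideration; every active/inactive combination is an AC,
#' so a series with `n_a` actives and `n_i` inactives yields `n_a * n_i`
#' cliffs.
#'
#' @param series rows of an MMS table ([build_mms()]) for a single series.
#' @param assay_labels named 0/1 vector: activity label per compound in the
#'   assay; must cover every series member (the profiling matrix is
#'   complete).
#' @param assay_id assay identifier recorded in the output.
#' @return a `data.frame` with columns `assay_id`, `series_id`, `active_id`,
#'   `inactive_id`.
#' @export
extract_acs <- function(series, assay_labels, assay_id) {
  stopifnot(length(unique(series$series_id)) <= 1)
  members <- unique(series$compound_id)
  missing <- setdiff(members, names(assay_labels))
  if (length(missing)) {
    stop_input("assay '%s': no label for series member '%s' (matrix must be complete)",
               assay_id, missing[1])
  }
  lab <- assay_labels[members]
  act <- members[lab == 1]
  ina <- members[lab == 0]
  if (!length(act) || !length(ina)) {
    return(data.frame(assay_id = character(), series_id = character(),
                      active_id = character(), inactive_id = character(),
                      stringsAsFactors = FALSE))
  }
  grid <- expand.grid(active_id = act, inactive_id = ina,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(assay_id = assay_id, series_id = series$series_id[1],
             active_id = grid$active_id, inactive_id = grid$inactive_id,
             stringsAsFactors = FALSE)
}

#' Unique activity cliff compounds per assay
#'
#' For every assay of a profiling matrix, collects the set of distinct
#' compounds that participate in at least one activity cliff in that assay
#' (used for test-assay eligibility).
#'
#' @param mms MMS table from [build_mms()].
#' @param matrix a [profiling_matrix()] covering all series members.
#' @return named list: assay id -> character vector of compound ids.
#' @export
ac_compounds_per_assay <- function(mms, matrix) {
  assays <- matrix$assay_ids
  members <- unique(mms$compound_id)
  missing <- setdiff(members, matrix$compound_ids)
  if (length(missing)) {
    stop_input("matrix lacks series member '%s'", missing[1])
  }
  vals <- pm_cells(matrix, members, assays)
  by_series <- split(seq_len(nrow(mms)), mms$series_id)
  out <- lapply(assays, function(a) {
    col <- vals[, a]
    res <- character()
    for (idx in by_series) {
      mem <- unique(mms$compound_id[idx])
      lab <- col[mem]
      if (any(lab == 1) && any(lab == 0)) res <- c(res, mem)
    }
    sort(unique(res))
  })
  names(out) <- assays
  out
}
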