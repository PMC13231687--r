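# Compound representations: binary bioactivity profiles over the profile
# assays, a 2048-bit folded circular fingerprint (ECFP4, radius 2), and
# their concatenation. Reduced profiles are derived from an assay
# similarity ranking (top-k) or by random sampling (control).

#' Bioactivity profile vectors
#'
#' Extracts the binary profile of one or more compounds over the profile
#' assays, in fixed column order. Passing the held-out test assay as part of
#' the profile is a leakage error.
#'
#' @param m a [profiling_matrix()].
#' @param compounds compound ids (rows of the result).
#' @param profile_assays ordered feature assays.
#' @param test_assay optional assay id that must not appear among
#'   `profile_assays`.
#' @return integer matrix, one row per compound, one column per profile
#'   assay.
#' @export
profile_vectors <- function(m, compounds, profile_assays, test_assay = NULL) {
  if (!is.null(test_assay) && test_assay %in% profile_assays) {
    stop_input("leakage: test assay '%s' present in the profile assays",
               test_assay)
  }
  pm_cells(m, compounds, profile_assays)
}

#' ECFP4 fingerprints (2048-bit folded circular fingerprint)
#'
#' Computes an extended-connectivity fingerprint with bond diameter 4
#' (radius 2) folded to a constant length. Initial atom identifiers combine
#' element, heavy degree, bond-order sum and ring membership; identifiers
#' are then iteratively rehashed over bond-ordered neighbor identifiers, and
#' every identifier from radius 0 to 2 sets one (hashed) bit. The
#' fingerprint is deterministic; bit collisions from folding are accepted,
#' as is standard.
#'
#' @param smiles character vector of SMILES.
#' @param ids optional row names for the result (default: the SMILES).
#' @param nbits fingerprint length (default 2048).
#' @param radius neighborhood radius (default 2 = ECFP4).
#' @return binary integer matrix, one row per molecule, `nbits` columns.
#' @export
#' @examples
#' fp <- ecfp4_vectors(c("C", "CC"))
#' sum(fp[1, ] != fp[2, ]) > 0
ecfp4_vectors <- function(smiles, ids = smiles, nbits = 2048, radius = 2) {
  graphs <- parse_mols(smiles, ids)
  out <- matrix(0L, nrow = length(graphs), ncol = nbits,
                dimnames = list(ids, paste0("fp", seq_len(nbits) - 1L)))
  for (i in seq_along(graphs)) {
    out[i, morgan_bits(graphs[[i]], nbits, radius) + 1L] <- 1L
  }
  out
}

# polynomial hash of an integer vector into [0, 2^31)
hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + x) %% 2147483629
  h
}

# set-bit positions (0-based) of the circular fingerprint of one molecule
morgan_bits <- function(graph, nbits, radius) {
  n <- length(graph$atoms)
  bonds <- graph$bonds
  adj <- adjacency_list(n, bonds)
  ring <- ring_bond_flags(graph)
  elem_no <- atomic_numbers(graph$atoms)
  deg <- integer(n)
  bosum <- integer(n)
  for (i in seq_len(nrow(bonds))) {
    a <- bonds[i, 1]; b <- bonds[i, 2]; o <- bonds[i, 3]
    deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
    bosum[a] <- bosum[a] + o; bosum[b] <- bosum[b] + o
  }
  in_ring_atom <- logical(n)
  if (nrow(bonds)) {
    ra <- bonds[ring, 1:2]
    in_ring_atom[unique(as.vector(ra))] <- TRUE
  }
  ids <- vapply(seq_len(n), function(a) {
    hash_ints(c(elem_no[a], deg[a], bosum[a], as.integer(in_ring_atom[a])))
  }, 1)
  bits <- ids
  for (r in seq_len(radius)) {
    new_ids <- vapply(seq_len(n), function(a) {
      nb <- adj[[a]]
      env <- c(r, ids[a])
      if (!is.null(nb)) {
        pairs <- cbind(bonds[nb[, 2], "order"], ids[nb[, 1]])
        pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
        env <- c(env, as.vector(t(pairs)))
      }
      hash_ints(env)
    }, 1)
    ids <- new_ids
    bits <- c(bits, ids)
  }
  unique(as.integer(bits %% nbits))
}

ring_bond_flags <- function(graph) {
  bonds <- graph$bonds
  if (!nrow(bonds)) return(logical())
  adj <- adjacency_list(length(graph$atoms), bonds)
  !vapply(seq_len(nrow(bonds)), function(i) {
    is_bridge(adj, bonds[i, 1], bonds[i, 2])
  }, TRUE)
}

atomic_numbers <- function(symbols) {
  tab <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
           S = 16, Cl = 17, Br = 35, I = 53, Se = 34, As = 33)
  out <- tab[symbols]
  out[is.na(out)] <- 113  # rare elements share one bucket
  unname(out)
}

#' Concatenate profile and fingerprint blocks
#'
#' Combined representation: profile features first, fingerprint bits second.
#'
#' @param profile profile matrix from [profile_vectors()].
#' @param fp fingerprint matrix from [ecfp4_vectors()] with identical rows.
#' @return the column-bound matrix.
#' @export
combined_vectors <- function(profile, fp) {
  if (nrow(profile) != nrow(fp)) {
    stop_input("profile and fingerprint row counts differ (%d vs %d)",
               nrow(profile), nrow(fp))
  }
  if (!is.null(rownames(profile)) && !is.null(rownames(fp)) &&
      !identical(rownames(profile), rownames(fp))) {
    stop_input("profile and fingerprint rows are for different compounds")
  }
  cbind(profile, fp)
}

#' Reduce a bioactivity profile by assay similarity
#'
#' `top_k` keeps the `k` assays most similar to the test assay (per the
#' ranking); `random_k` samples `k` assays uniformly without replacement
#' from all profile assays (the control).
#'
#' @param ranking an assay similarity ranking from
#'   [rank_profile_assays()].
#' @param mode `"top_k"` or `"random_k"`.
#' @param k number of assays to keep (e.g. 60 = "top 50%" of 121 assays, or
#'   10).
#' @param seed required for `random_k`.
#' @return character vector of `k` assay ids.
#' @export
reduce_profile <- function(ranking, mode = c("top_k", "random_k"), k,
                           seed = NULL) {
  mode <- match.arg(mode)
  if (k > nrow(ranking)) {
    stop_input("k = %d exceeds the %d available profile assays",
               k, nrow(ranking))
  }
  if (mode == "top_k") {
    ranking$profile_assay[seq_len(k)]
  } else {
    if (is.null(seed)) stop_input("random_k reduction needs a seed")
    with_seed(seed, sample(sort(ranking$profile_assay), k))
  }
}
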