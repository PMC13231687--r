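# Molecular graph plumbing on top of ChemmineR/OpenBabel.
#
# Molecules are held as plain R lists: a vector of heavy-atom element
# symbols and a bond table (atom1, atom2, order). Hydrogens are implicit
# throughout; explicit [H] atoms are stripped on parsing. Formal charges are
# not carried through fragmentation (see package vignette), which restricts
# the chemistry layer to neutral molecules.

#' Read a SMILES library file
#'
#' Reads a tab-separated SMILES file with one record per line,
#' `SMILES<TAB>compound_id`, validates every structure and returns a compound
#' library table.
#'
#' @param path path to the SMILES file.
#' @return a `data.frame` with columns `compound_id`, `smiles` and `n_heavy`
#'   (heavy-atom count of the parent molecule).
#' @export
read_smiles <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    stop_input("line %d of '%s' is not 'SMILES<TAB>compound_id'", bad[1], path)
  }
  molecule_library(
    smiles = vapply(parts, `[[`, "", 1L),
    compound_id = vapply(parts, `[[`, "", 2L)
  )
}

#' Assemble and validate a compound library
#'
#' @param smiles character vector of SMILES strings; each must parse to a
#'   single connected molecule.
#' @param compound_id unique compound identifiers.
#' @return a `data.frame` with columns `compound_id`, `smiles`, `n_heavy`.
#' @export
#' @examples
#' molecule_library(c("Cc1ccccc1", "CCc1ccccc1"), c("tol", "etb"))
molecule_library <- function(smiles, compound_id) {
  stopifnot(length(smiles) == length(compound_id))
  compound_id <- as.character(compound_id)
  if (anyDuplicated(compound_id)) {
    stop_input("duplicate compound_id: %s",
               compound_id[duplicated(compound_id)][1])
  }
  graphs <- parse_mols(smiles, compound_id)
  data.frame(
    compound_id = compound_id,
    smiles = as.character(smiles),
    n_heavy = vapply(graphs, function(g) length(g$atoms), 1L),
    stringsAsFactors = FALSE
  )
}

# Parse SMILES into molecular graphs.
# Returns a list (one per molecule) of list(atoms = element symbols,
# bonds = matrix [a1, a2, order]). Errors name the offending compound_id.
parse_mols <- function(smiles, ids = as.character(seq_along(smiles))) {
  disc <- grepl(".", smiles, fixed = TRUE)
  if (any(disc)) {
    stop_input("compound '%s': disconnected structure (multi-fragment SMILES)",
               ids[which(disc)[1]])
  }
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(as.character(smiles))),
    error = function(e) NULL
  )
  if (!is.null(sdfset) && length(sdfset) != length(smiles)) {
    sdfset <- NULL  # invalid records were silently dropped; diagnose below
  }
  if (is.null(sdfset)) {
    # fall back to per-molecule parsing to identify the culprit
    for (i in seq_along(smiles)) {
      ok <- tryCatch({
        s <- suppressWarnings(ChemmineR::smiles2sdf(smiles[i]))
        nrow(ChemmineR::atomblock(s[[1]])) > 0
      }, error = function(e) FALSE)
      if (!ok) stop_input("compound '%s': unparsable SMILES '%s'",
                          ids[i], smiles[i])
    }
    stop_input("SMILES parsing failed for an undetermined input")
  }
  lapply(seq_along(smiles), function(i) {
    sdf <- sdfset[[i]]
    ab <- ChemmineR::atomblock(sdf)
    if (nrow(ab) == 0) {
      stop_input("compound '%s': unparsable SMILES '%s'", ids[i], smiles[i])
    }
    atoms <- sub("_\\d+$", "", rownames(ab))
    bb <- ChemmineR::bondblock(sdf)
    bonds <- if (is.null(dim(bb)) || nrow(bb) == 0 || ncol(bb) < 3) {
      matrix(integer(), ncol = 3, dimnames = list(NULL, c("a1", "a2", "order")))
    } else {
      m <- unname(as.matrix(bb[, 1:3, drop = FALSE]))
      storage.mode(m) <- "integer"
      colnames(m) <- c("a1", "a2", "order")
      m
    }
    # strip explicit hydrogens
    hyd <- which(atoms == "H")
    if (length(hyd)) {
      keep <- setdiff(seq_along(atoms), hyd)
      remap <- integer(length(atoms))
      remap[keep] <- seq_along(keep)
      bonds <- bonds[!(bonds[, 1] %in% hyd | bonds[, 2] %in% hyd), ,
                     drop = FALSE]
      bonds[, 1] <- remap[bonds[, 1]]
      bonds[, 2] <- remap[bonds[, 2]]
      atoms <- atoms[keep]
    }
    if (length(atoms) == 0) {
      stop_input("compound '%s': no heavy atoms", ids[i])
    }
    list(atoms = atoms, bonds = bonds)
  })
}

# Serialize a fragment (subset of atoms plus attachment points) as a V2000
# molblock. `attach` is a list of atom indices (into `atom_idx`) that carry
# one dummy '*' neighbor each; duplicated indices give multiple attachments.
fragment_molblock <- function(graph, atom_idx, attach, title = "frag") {
  remap <- integer(length(graph$atoms))
  remap[atom_idx] <- seq_along(atom_idx)
  syms <- c(graph$atoms[atom_idx], rep("*", length(attach)))
  b <- graph$bonds
  keep <- b[, 1] %in% atom_idx & b[, 2] %in% atom_idx
  bonds <- b[keep, , drop = FALSE]
  bonds[, 1] <- remap[bonds[, 1]]
  bonds[, 2] <- remap[bonds[, 2]]
  if (length(attach)) {
    star <- length(atom_idx) + seq_along(attach)
    bonds <- rbind(bonds, cbind(remap[unlist(attach)], star,
                                rep(1L, length(attach))))
  }
  atom_lines <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    0, 0, 0, syms)
  bond_lines <- sprintf("%3d%3d%3d  0  0  0  0",
                        bonds[, 1], bonds[, 2], bonds[, 3])
  paste(c(title, "  acprofiles", "",
          sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                  length(syms), nrow(bonds)),
          atom_lines, bond_lines, "M  END", "$$$$"),
        collapse = "\n")
}

# Canonicalize a batch of molblocks via OpenBabel; returns canonical SMILES
# in input order. Titles must be unique within the batch.
canonical_from_molblocks <- function(blocks, titles) {
  out <- ChemmineOB::convertFormat(
    "SDF", "CAN", paste0(paste(blocks, collapse = "\n"), "\n"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smi <- vapply(parts, `[[`, "", 1L)
  ttl <- vapply(parts, function(p) if (length(p) > 1) p[[2]] else "", "")
  smi[match(titles, ttl)]
}

# Canonical SMILES of plain molecules (batch).
canonical_smiles <- function(smiles) {
  inp <- paste0(paste(smiles, seq_along(smiles), sep = "\t"), collapse = "\n")
  out <- ChemmineOB::convertFormat("SMI", "CAN", paste0(inp, "\n"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smi <- vapply(parts, `[[`, "", 1L)
  idx <- as.integer(vapply(parts, function(p) if (length(p) > 1) p[[2]] else NA_character_, ""))
  res <- rep(NA_character_, length(smiles))
  res[idx] <- smi
  res
}
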