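# The complete binary compound-profiling matrix: rows are compound
# "bioactivity profiles", columns are assay "activity vectors". All cell
# access inside the package goes through pm_cells() so that an instrumented
# wrapper can audit exactly which cells an operation reads (leakage audit).

#' Construct a binary profiling matrix
#'
#' @param values a numeric/integer matrix with compound ids as row names and
#'   assay ids as column names; every cell must be 0 or 1 and no cell may be
#'   missing (the matrix is "complete").
#' @return an object of class `profiling_matrix` with fields `values`,
#'   `compound_ids`, `assay_ids`.
#' @export
#' @examples
#' m <- profiling_matrix(matrix(c(1, 0, 0, 1, 0, 1), nrow = 3,
#'   dimnames = list(c("c1", "c2", "c3"), c("a1", "a2"))))
profiling_matrix <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_input("profiling matrix needs compound row names and assay column names")
  }
  if (anyDuplicated(rownames(values))) {
    stop_input("duplicate compound_id: %s",
               rownames(values)[duplicated(rownames(values))][1])
  }
  if (anyDuplicated(colnames(values))) {
    stop_input("duplicate assay_id: %s",
               colnames(values)[duplicated(colnames(values))][1])
  }
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop_input("missing cell at compound '%s', assay '%s'",
               rownames(values)[idx[1]], colnames(values)[idx[2]])
  }
  if (!all(values %in% c(0, 1))) {
    idx <- which(!(values %in% c(0, 1)))[1]
    rc <- arrayInd(idx, dim(values))
    stop_input("non-binary cell '%s' at compound '%s', assay '%s'",
               format(values[idx]), rownames(values)[rc[1]],
               colnames(values)[rc[2]])
  }
  storage.mode(values) <- "integer"
  structure(list(values = values,
                 compound_ids = rownames(values),
                 assay_ids = colnames(values)),
            class = "profiling_matrix")
}

#' @export
print.profiling_matrix <- function(x, ...) {
  cat(sprintf("profiling_matrix: %d compounds x %d assays, %.2f%% active cells\n",
              length(x$compound_ids), length(x$assay_ids),
              100 * mean(x$values)))
  invisible(x)
}

#' @export
dim.profiling_matrix <- function(x) dim(x$values)

#' Load a profiling matrix from TSV
#'
#' Expects a header of assay ids, a first column of compound ids and binary
#' cells; the file must be complete (no empty cells).
#'
#' @param path TSV file path.
#' @return a [profiling_matrix()].
#' @export
load_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop_input("matrix file '%s' has no assay columns", path)
  ids <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  blank <- which(vals == "" | is.na(vals))
  if (length(blank)) {
    rc <- arrayInd(blank[1], dim(vals))
    stop_input("blank cell at compound '%s', assay '%s'",
               ids[rc[1]], colnames(vals)[rc[2]])
  }
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(ids, colnames(vals))))
  profiling_matrix(num)
}

#' Write a profiling matrix as TSV
#'
#' @param m a [profiling_matrix()].
#' @param path output file.
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(compound_id = m$compound_ids, m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cells of a profiling matrix
#'
#' The single point of cell access used by all package internals. The
#' instrumented subclass created by [instrumented_matrix()] records every
#' access, which lets tests assert that leakage-controlled operations never
#' touch forbidden cells.
#'
#' @param m a [profiling_matrix()].
#' @param compounds,assays ids to read (default: all).
#' @return the integer submatrix (dimensions preserved).
#' @export
pm_cells <- function(m, compounds = NULL, assays = NULL) {
  UseMethod("pm_cells")
}

#' @export
pm_cells.profiling_matrix <- function(m, compounds = NULL, assays = NULL) {
  compounds <- compounds %||% m$compound_ids
  assays <- assays %||% m$assay_ids
  unknown_c <- setdiff(compounds, m$compound_ids)
  if (length(unknown_c)) stop_input("unknown compound_id '%s'", unknown_c[1])
  unknown_a <- setdiff(assays, m$assay_ids)
  if (length(unknown_a)) stop_input("unknown assay_id '%s'", unknown_a[1])
  m$values[compounds, assays, drop = FALSE]
}

#' Wrap a profiling matrix with access instrumentation
#'
#' Returns a matrix whose cell reads through [pm_cells()] are logged
#' (compound block x assay block per call). Used to audit that similarity
#' computations and representations restricted to training compounds never
#' read test-compound cells of the test assay.
#'
#' @param m a [profiling_matrix()].
#' @return an `instrumented_matrix` (usable wherever a `profiling_matrix`
#'   is).
#' @seealso [access_log()]
#' @export
instrumented_matrix <- function(m) {
  stopifnot(inherits(m, "profiling_matrix"))
  m$log <- new.env(parent = emptyenv())
  m$log$accesses <- list()
  class(m) <- c("instrumented_matrix", class(m))
  m
}

#' @export
pm_cells.instrumented_matrix <- function(m, compounds = NULL, assays = NULL) {
  rec <- list(compounds = compounds %||% m$compound_ids,
              assays = assays %||% m$assay_ids)
  m$log$accesses[[length(m$log$accesses) + 1L]] <- rec
  NextMethod()
}

#' Retrieve (and optionally clear) the access log of an instrumented matrix
#'
#' @param m an [instrumented_matrix()].
#' @param clear reset the log after reading it.
#' @return list of accesses, each a list with `compounds` and `assays`.
#' @export
access_log <- function(m, clear = FALSE) {
  stopifnot(inherits(m, "instrumented_matrix"))
  out <- m$log$accesses
  if (clear) m$log$accesses <- list()
  out
}

#' Was a given cell block ever read?
#'
#' Convenience predicate over [access_log()]: did any logged access touch at
#' least one (compound, assay) pair from the given sets?
#'
#' @param m an [instrumented_matrix()].
#' @param compounds,assays cell block to test.
#' @return `TRUE` if any logged access intersects the block.
#' @export
accessed_cells <- function(m, compounds, assays) {
  for (rec in access_log(m)) {
    if (length(intersect(rec$compounds, compounds)) &&
        length(intersect(rec$assays, assays))) {
      return(TRUE)
    }
  }
  FALSE
}

#' Remove compounds inactive in every assay
#'
#' Consistently inactive compounds carry no profile information; dropping
#' them is idempotent, preserves row order and leaves the assay set
#' unchanged.
#'
#' @param m a [profiling_matrix()].
#' @return the filtered matrix.
#' @export
drop_all_inactive_compounds <- function(m) {
  vals <- pm_cells(m)
  keep <- rowSums(vals) > 0
  profiling_matrix(vals[keep, , drop = FALSE])
}

#' Active compounds of an assay under a compound restriction
#'
#' @param m a [profiling_matrix()].
#' @param assay_id assay to read.
#' @param restriction compound ids to consider (e.g. training compounds
#'   only); defaults to all compounds.
#' @return character vector of compounds with value 1.
#' @export
active_set <- function(m, assay_id, restriction = NULL) {
  restriction <- restriction %||% m$compound_ids
  if (!length(restriction)) return(character())
  col <- pm_cells(m, restriction, assay_id)
  restriction[col[, 1] == 1]
}

#' Tanimoto similarity of two assays
#'
#' `T(a, b) = |A n B| / |A u B|` where `A` and `B` are the active compound
#' sets of the two assays under the given restriction. When both active sets
#' are empty the similarity is defined as 0 (no shared evidence).
#'
#' @param m a [profiling_matrix()].
#' @param a,b assay ids.
#' @param restriction compound ids over which active sets are formed
#'   (defaults to all compounds).
#' @return similarity in `[0, 1]`.
#' @export
assay_tanimoto <- function(m, a, b, restriction = NULL) {
  A <- active_set(m, a, restriction)
  B <- active_set(m, b, restriction)
  uni <- length(union(A, B))
  if (uni == 0) return(0)
  length(intersect(A, B)) / uni
}

#' Rank profile assays by similarity to a test assay
#'
#' Computes the Tanimoto similarity (over training compounds only, to avoid
#' leakage) between the test assay and every profile assay, and returns the
#' full descending ranking. Ties are broken by ascending assay id so the
#' ranking is deterministic.
#'
#' @param m a [profiling_matrix()].
#' @param test_assay the held-out assay.
#' @param profile_assays candidate assays (must not contain `test_assay`).
#' @param train_compounds restriction used for the active sets.
#' @return a `data.frame` with columns `rank`, `profile_assay`, `tanimoto`,
#'   ordered by descending similarity; attributes `test_assay` and
#'   `n_train`.
#' @export
rank_profile_assays <- function(m, test_assay, profile_assays,
                                train_compounds) {
  if (test_assay %in% profile_assays) {
    stop_input("test assay '%s' must not be part of the profile assays",
               test_assay)
  }
  if (!length(train_compounds)) stop_input("empty training compound set")
  test_col <- pm_cells(m, train_compounds, test_assay)[, 1]
  prof <- pm_cells(m, train_compounds, profile_assays)
  inter <- as.vector(crossprod(prof, test_col))
  uni <- colSums(prof) + sum(test_col) - inter
  tan <- ifelse(uni == 0, 0, inter / uni)
  ord <- order(-tan, profile_assays)
  out <- data.frame(rank = seq_along(profile_assays),
                    profile_assay = profile_assays[ord],
                    tanimoto = tan[ord],
                    stringsAsFactors = FALSE)
  attr(out, "test_assay") <- test_assay
  attr(out, "n_train") <- length(train_compounds)
  out
}

#' Summarize per-assay activity sparsity
#'
#' @param m a [profiling_matrix()].
#' @return list with `median`, `mean` and `sd` (sample standard deviation)
#'   of the per-assay active-compound percentage.
#' @export
summarize_sparsity <- function(m) {
  pct <- 100 * colMeans(pm_cells(m))
  list(median = median(pct), mean = mean(pct), sd = sd(pct))
}
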