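#' Derive a reproducible child seed from a master seed and labels
#'
#' Deterministically fans a single master seed out to per-task seeds (one per
#' test assay, scheme, algorithm, ...) so that experiment cells are mutually
#' independent but individually reproducible. The labels are hashed with a
#' small polynomial string hash; the result is always a valid 32-bit R seed.
#'
#' @param seed integer master seed.
#' @param ... character or numeric labels identifying the task.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' fan_out_seed(1, "assay_003", "intra_series", "RF")
fan_out_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "\r")
  h <- 0
  for (code in utf8ToInt(labels)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# run expr under a local RNG state seeded with `seed`, restoring global state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
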