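# Synthetic benchmark data: analog-series compound libraries (one scaffold
# per series, single-site substituent variation) and complete binary
# profiling matrices with planted statistical structure -- sparse background
# activity, activity-cliff-rich test assays, and "planted nearest neighbor"
# profile assays that copy a test assay's activity vector with a controlled
# label-flip rate. The generator emits the same SMILES and TSV dialects the
# real pipeline reads, so every stage is testable without external data.

#' Configuration of the synthetic benchmark
#'
#' Defaults emulate the structure of a large screening profile collection
#' at desk scale: 121 profile assays as in the full setting, ~1% background
#' active sparsity, and a subset of test assays with one highly similar
#' ("planted") profile assay each at flip rate 0.1.
#'
#' @param n_series number of analog series (default 60).
#' @param analogs_per_series inclusive integer range of series sizes
#'   (default `c(4, 8)`).
#' @param n_assays total number of assays (default 133 = 12 test + 121
#'   profile).
#' @param n_test_assays number of designated test assays (default 12).
#' @param base_active_rate background Bernoulli activity rate
#'   (default 0.01).
#' @param n_planted number of test assays that receive a planted
#'   nearest-neighbor profile assay (default half of the test assays).
#' @param flip_rate label-flip probability of planted columns
#'   (default 0.1).
#' @param ac_fraction fraction of series given mixed labels (at least one
#'   active and one inactive member) in each test assay (default 0.6).
#' @param seed integer seed; the same configuration and seed reproduce the
#'   library and matrix exactly.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_series = 60, analogs_per_series = c(4, 8),
                             n_assays = 133, n_test_assays = 12,
                             base_active_rate = 0.01,
                             n_planted = ceiling(n_test_assays / 2),
                             flip_rate = 0.1, ac_fraction = 0.6, seed = 1) {
  stopifnot(n_test_assays < n_assays,
            base_active_rate > 0, base_active_rate < 1,
            flip_rate >= 0, flip_rate <= 0.5,
            ac_fraction > 0, ac_fraction <= 1,
            length(analogs_per_series) == 2,
            analogs_per_series[1] >= 2,
            n_planted <= n_test_assays)
  structure(list(n_series = n_series,
                 analogs_per_series = as.integer(analogs_per_series),
                 n_assays = n_assays, n_test_assays = n_test_assays,
                 base_active_rate = base_active_rate,
                 n_planted = n_planted, flip_rate = flip_rate,
                 ac_fraction = ac_fraction, seed = as.integer(seed)),
            class = "synthetic_config")
}

# scaffold templates: an "R" marks the substitution site; decorations make
# cores distinct across series while keeping them small ring systems
scaffold_pool <- function() {
  bases <- c("c1ccc(R)cc1", "c1cccc(R)c1", "c1ccnc(R)c1", "c1ccc(R)cn1",
             "C1CCC(R)CC1", "C1CCN(R)CC1", "c1ccc2cc(R)ccc2c1",
             "c1ccc2nc(R)ccc2c1", "c1cnc(R)cn1", "C1CCC(R)C1",
             "C1CCC(R)OC1", "C1CN(R)CCN1C", "c1ccc2c(c1)CCC2R",
             "c1ccc2c(c1)OC(R)C2", "C1CC2CCC1C(R)C2", "c1cc2ccccc2c(R)c1")
  decos <- c("", "F", "Cl", "Br", "C", "CO", "N#C", "CC", "O", "OC",
             "CN", "FC", "CCO", "ClC")
  as.vector(outer(decos, bases, paste0))
}

substituent_pool <- function() {
  c("C", "CC", "O", "OC", "N", "NC", "F", "Cl", "Br", "C=O", "C#N",
    "CO", "CN", "S", "SC", "I", "CF", "OCC", "CCC", "NCC")
}

heavy_count <- function(smiles) {
  # heavy atoms = element tokens (two-letter organic subset first)
  vapply(smiles, function(s) {
    s <- gsub("R", "", s, fixed = TRUE)
    length(gregexpr("Cl|Br|Si|Se|As|[BCNOPSFIbcnops]", s)[[1]])
  }, 1L, USE.NAMES = FALSE)
}

#' Generate a synthetic analog-series compound library
#'
#' Each series combines one scaffold (a small, optionally decorated ring
#' system, unique per series) with distinct small substituents at a single
#' site; all emitted SMILES are valid, connected, and well under 60 heavy
#' atoms. Substituent choices that would collide with another compound's
#' canonical structure are replaced, so compound structures are unique
#' library-wide.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `library` (a [molecule_library()] table) and
#'   `series_truth`, a `data.frame` (`compound_id`, `series`) recording
#'   which compounds share a scaffold.
#' @export
generate_library <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  scaffolds <- scaffold_pool()
  subs <- substituent_pool()
  if (cfg$n_series > length(scaffolds)) {
    stop_input("scaffold pool exhausted: %d series requested, %d scaffolds available",
               cfg$n_series, length(scaffolds))
  }
  if (cfg$analogs_per_series[2] > length(subs)) {
    stop_input("substituent pool exhausted: series size up to %d, %d substituents available",
               cfg$analogs_per_series[2], length(subs))
  }
  n_scaf <- heavy_count(scaffolds)
  n_sub <- heavy_count(subs)
  with_seed(cfg$seed, {
    cores <- sample(scaffolds, cfg$n_series)
    core_n <- n_scaf[match(cores, scaffolds)]
    size_range <- seq(cfg$analogs_per_series[1], cfg$analogs_per_series[2])
    sizes <- size_range[sample.int(length(size_range), cfg$n_series,
                                   replace = TRUE)]
    rows <- list()
    seen <- character()
    for (s in seq_len(cfg$n_series)) {
      # only substituents that pass the fragment-to-size ratio filter on
      # this scaffold, so the series is recoverable by construction
      ok <- subs[(n_sub - 1) / (core_n[s] + n_sub) <= 0.2]
      if (length(ok) < cfg$analogs_per_series[1]) {
        stop_input("substituent pool exhausted for scaffold '%s'", cores[s])
      }
      chosen <- sample(ok, min(sizes[s], length(ok)))
      spare <- setdiff(sample(ok), chosen)
      kept <- character()
      for (sb in chosen) {
        repeat {
          smi <- sub("R", sb, cores[s], fixed = TRUE)
          can <- canonical_smiles(smi)
          if (!is.na(can) && !(can %in% seen)) {
            seen <- c(seen, can)
            kept <- c(kept, smi)
            break
          }
          if (!length(spare)) break
          sb <- spare[1]
          spare <- spare[-1]
        }
      }
      rows[[s]] <- data.frame(
        series = sprintf("G%03d", s),
        smiles = kept,
        stringsAsFactors = FALSE)
    }
    lib <- do.call(rbind, rows)
    lib$compound_id <- sprintf("CPD%04d", seq_len(nrow(lib)))
    list(library = molecule_library(lib$smiles, lib$compound_id),
         series_truth = lib[, c("compound_id", "series")])
  })
}

#' Generate a complete binary profiling matrix with planted structure
#'
#' Background cells are i.i.d. Bernoulli at the configured base rate. In
#' every designated test assay, a fraction of the series receive mixed
#' labels -- the number of actives is drawn uniformly from 1 to size-1 --
#' so those series form activity cliffs. For each planted test assay one
#' profile assay is overwritten with a copy of the test assay's activity
#' vector whose every label is flipped independently with probability
#' `flip_rate`; its Tanimoto similarity to the test assay is therefore
#' high but noisy (measured, not asserted). Rows that end up all-inactive
#' are retained so that matrix preprocessing can be exercised.
#'
#' @param cfg a [synthetic_config()].
#' @param lib a [generate_library()] result.
#' @return list with `matrix` (a [profiling_matrix()]) and `truth`:
#'   `test_assays`, `profile_assays`, `planted` (`data.frame` of
#'   `test_assay`, `profile_assay`, `flip_rate`), and `mixed_series`
#'   (per-test-assay list of ground-truth series with mixed labels).
#' @export
generate_matrix <- function(cfg, lib) {
  stopifnot(inherits(cfg, "synthetic_config"))
  truth <- lib$series_truth
  sizes <- table(truth$series)
  if (cfg$ac_fraction > 0 && any(sizes < 2)) {
    stop_input("mixed labels need series of size >= 2 (found a 1-member series)")
  }
  compounds <- lib$library$compound_id
  n_cpd <- length(compounds)
  assays <- sprintf("assay_%03d", seq_len(cfg$n_assays))
  with_seed(cfg$seed + 1L, {
    test_assays <- sort(sample(assays, cfg$n_test_assays))
    profile_assays <- setdiff(assays, test_assays)
    vals <- matrix(rbinom(n_cpd * cfg$n_assays, 1, cfg$base_active_rate),
                   nrow = n_cpd, dimnames = list(compounds, assays))
    series_ids <- sort(unique(truth$series))
    n_mixed <- max(1L, round(cfg$ac_fraction * length(series_ids)))
    mixed_series <- list()
    for (ta in test_assays) {
      mixed <- sort(sample(series_ids, n_mixed))
      mixed_series[[ta]] <- mixed
      for (g in mixed) {
        mem <- truth$compound_id[truth$series == g]
        k_active <- sample(length(mem) - 1L, 1L)
        act <- sample(mem, k_active)
        vals[mem, ta] <- 0L
        vals[act, ta] <- 1L
      }
    }
    planted <- data.frame(test_assay = character(),
                          profile_assay = character(),
                          flip_rate = numeric(), stringsAsFactors = FALSE)
    if (cfg$n_planted > 0) {
      planted_tests <- test_assays[seq_len(cfg$n_planted)]
      planted_profiles <- sample(profile_assays, cfg$n_planted)
      for (i in seq_along(planted_tests)) {
        src <- vals[, planted_tests[i]]
        flips <- rbinom(n_cpd, 1, cfg$flip_rate)
        vals[, planted_profiles[i]] <- as.integer(xor(src, flips))
      }
      planted <- data.frame(test_assay = planted_tests,
                            profile_assay = planted_profiles,
                            flip_rate = cfg$flip_rate,
                            stringsAsFactors = FALSE)
    }
    list(matrix = profiling_matrix(vals),
         truth = list(test_assays = test_assays,
                      profile_assays = profile_assays,
                      planted = planted,
                      mixed_series = mixed_series))
  })
}

#' Fraction of ground-truth series recovered as matching molecular series
#'
#' A ground-truth series counts as recovered when a single extracted MMS
#' contains all of its members (the MMS may contain additional compounds
#' that legitimately share the core).
#'
#' @param mms MMS table from [build_mms()].
#' @param series_truth the `series_truth` table of [generate_library()].
#' @return fraction in `[0, 1]`.
#' @export
series_recovery <- function(mms, series_truth) {
  by_mms <- lapply(split(mms$compound_id, mms$series_id), unique)
  truth <- split(series_truth$compound_id, series_truth$series)
  hits <- vapply(truth, function(mem) {
    any(vapply(by_mms, function(got) all(mem %in% got), TRUE))
  }, TRUE)
  mean(hits)
}
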