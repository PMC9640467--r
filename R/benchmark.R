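# Benchmark harness: per-pair scorer rank-agreement against experimental
# affinities, and threshold summaries over a dataset of pairs.

#' A benchmark pair of complexes with known affinities
#'
#' The strong member must have the lower (tighter) affinity in nM; both score
#' vectors must cover the same scorer set and be oriented (lower = better).
#' Affinity types (Kd vs IC50) are only ever compared within a pair.
#'
#' @param id_strong,id_weak complex identifiers.
#' @param affinity_strong,affinity_weak affinities in nM.
#' @param scores_strong,scores_weak oriented [score_vector()]s.
#' @return object of class `benchmark_pair`.
#' @export
benchmark_pair <- function(id_strong, id_weak, affinity_strong, affinity_weak,
                           scores_strong, scores_weak) {
  if (!(affinity_strong < affinity_weak))
    pd_error(sprintf("pair %s/%s: the strong member must have the lower affinity",
                     id_strong, id_weak), "pepmc_data_error")
  sym <- union(setdiff(names(scores_strong), names(scores_weak)),
               setdiff(names(scores_weak), names(scores_strong)))
  if (length(sym))
    pd_error(sprintf("pair %s/%s: scorer present on one side only: %s",
                     id_strong, id_weak, paste(sym, collapse = ", ")),
             "pepmc_data_error")
  structure(list(id_strong = id_strong, id_weak = id_weak,
                 affinity_strong = affinity_strong,
                 affinity_weak = affinity_weak,
                 scores_strong = unclass(scores_strong),
                 scores_weak = unclass(scores_weak)),
            class = "benchmark_pair")
}

#' Count scorers ranking a pair correctly
#'
#' Scorer i matches when its oriented score for the strong binder is strictly
#' lower than for the weak binder — the sign of the score difference agrees
#' with the experimental activity difference.  Ties do not match.
#'
#' @param pair a [benchmark_pair()].
#' @return object of class `pair_result`: list with `matches` (count),
#'   `per_scorer` (named logical), `n_scorers`.
#' @export
pair_matches <- function(pair) {
  stopifnot(inherits(pair, "benchmark_pair"))
  ok <- pair$scores_strong[names(pair$scores_weak)] < pair$scores_weak
  structure(list(id_strong = pair$id_strong, id_weak = pair$id_weak,
                 matches = sum(ok), per_scorer = ok,
                 n_scorers = length(ok)),
            class = "pair_result")
}

#' Count pairs passing a consensus threshold
#'
#' @param results list of `pair_result`s, a list of `benchmark_pair`s, or a
#'   bare integer vector of per-pair match counts (published match counts are
#'   valid inputs).
#' @param threshold minimum number of agreeing scorers (>= 1).
#' @return number of pairs with `matches >= threshold`.
#' @export
dataset_summary <- function(results, threshold = 4) {
  if (threshold < 1) pd_error("threshold must be >= 1", "pepmc_config_error")
  counts <- if (is.numeric(results)) as.integer(results)
    else vapply(results, function(r) {
      if (inherits(r, "benchmark_pair")) r <- pair_matches(r)
      stopifnot(inherits(r, "pair_result"))
      r$matches
    }, integer(1))
  sum(counts >= threshold)
}

#' Per-scorer error rate over a dataset
#'
#' Fraction of pairs where the scorer's oriented ordering is wrong or tied.
#'
#' @param pairs list of [benchmark_pair()]s.
#' @param scorer scorer name (must be present in every pair).
#' @return fraction in [0, 1].
#' @export
scorer_error_rate <- function(pairs, scorer) {
  ok <- vapply(pairs, function(p) {
    stopifnot(inherits(p, "benchmark_pair"))
    if (!scorer %in% names(p$scores_strong))
      pd_error(sprintf("scorer '%s' missing from pair %s/%s", scorer,
                       p$id_strong, p$id_weak), "pepmc_data_error")
    p$scores_strong[[scorer]] < p$scores_weak[[scorer]]
  }, logical(1))
  mean(!ok)
}

#' Read / write benchmark pairs in long CSV format
#'
#' Columns: `pair_id,complex_id,affinity_nM,role,scorer,score` with
#' `role` in `strong`/`weak`.  Scores in the file are raw; orientation
#' (including any negation) is applied at load through the registry.
#'
#' @param path CSV file.
#' @param registry named list of [scorer_spec()]s used to orient raw scores
#'   (scorers absent from the registry are assumed lower-is-better).
#' @return list of `benchmark_pair`s.
#' @export
read_benchmark_pairs <- function(path, registry = default_scorer_registry()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "complex_id", "affinity_nM", "role", "scorer", "score")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    pd_error(sprintf("pairs file missing column(s): %s",
                     paste(missing_cols, collapse = ", ")), "pepmc_schema_error")
  orient1 <- function(scorer, raw) {
    sp <- registry[[scorer]]
    if (is.null(sp)) sp <- scorer_spec(scorer, "lower_is_better")
    orient(raw, sp)
  }
  lapply(split(df, df$pair_id), function(d) {
    side <- function(role) {
      dd <- d[d$role == role, ]
      if (!nrow(dd))
        pd_error(sprintf("pair %s has no '%s' member", d$pair_id[1], role),
                 "pepmc_data_error")
      list(id = dd$complex_id[1], affinity = dd$affinity_nM[1],
           scores = score_vector(stats::setNames(
             mapply(orient1, dd$scorer, dd$score), dd$scorer)))
    }
    s <- side("strong"); w <- side("weak")
    benchmark_pair(s$id, w$id, s$affinity, w$affinity, s$scores, w$scores)
  })
}

#' @rdname read_benchmark_pairs
#' @param pairs list of `benchmark_pair`s (oriented scores; written as-is with
#'   every scorer treated as lower-is-better on re-load).
#' @export
write_benchmark_pairs <- function(pairs, path) {
  rows <- do.call(rbind, lapply(seq_along(pairs), function(k) {
    p <- pairs[[k]]
    rbind(
      data.frame(pair_id = sprintf("pair%02d", k), complex_id = p$id_strong,
                 affinity_nM = p$affinity_strong, role = "strong",
                 scorer = names(p$scores_strong),
                 score = unname(p$scores_strong)),
      data.frame(pair_id = sprintf("pair%02d", k), complex_id = p$id_weak,
                 affinity_nM = p$affinity_weak, role = "weak",
                 scorer = names(p$scores_weak),
                 score = unname(p$scores_weak)))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Published per-pair match counts bundled with the package
#'
#' The two benchmark datasets' per-pair agreement counts (six 100-fold pairs;
#' nine harder, lower-fold pairs), as shipped in
#' `inst/extdata/benchmark_matches.csv`.  The raw per-scorer scores behind
#' these counts are not redistributable, so the counts are inputs here, not
#' recomputable outputs.
#'
#' @return data.frame with columns `dataset`, `complex_strong`,
#'   `affinity_strong_nM`, `complex_weak`, `affinity_weak_nM`, `matches`.
#' @export
published_match_counts <- function() {
  utils::read.csv(system.file("extdata", "benchmark_matches.csv",
                              package = "pepmc"),
                  stringsAsFactors = FALSE)
}
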