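# Synthetic planted additive landscapes and noisy scorer ensembles.  These
# stand in for the true binding free-energy surface that structure-based
# scoring functions approximate, and make the design loop, consensus
# statistics and benchmark harness testable end-to-end with no external tools.

#' Generate a planted additive landscape
#'
#' The energy of a sequence is the sum of independent per-position
#' contributions (lower = better).  At every position the best code beats the
#' runner-up by at least `gap`, so the global optimum is the unique
#' per-position argmin.
#'
#' @param length peptide length.
#' @param alphabet character vector of monomer codes (>= 2).
#' @param gap minimum per-position energy gap between best and runner-up.
#' @param seed integer seed; the landscape is reproducible from it.
#' @param spread standard deviation of the raw per-(position, code) energies.
#' @return object of class `planted_landscape`: list with `energy_table`
#'   (length x alphabet matrix), `alphabet`, `length`, `optimum` (a
#'   `peptide_sequence`), `gap`, `seed`.
#' @export
generate_landscape <- function(length, alphabet, gap, seed, spread = 1) {
  alphabet <- unique(normalize_code(alphabet))
  if (length(alphabet) < 2) pd_error("alphabet needs >= 2 codes", "pepmc_config_error")
  if (gap <= 0) pd_error("gap must be > 0", "pepmc_config_error")
  st <- rng_streams(seed, 1)[[1]]
  E <- with_stream(st, matrix(stats::rnorm(length * base::length(alphabet),
                                           sd = spread),
                              nrow = length,
                              dimnames = list(NULL, alphabet)))
  for (p in seq_len(length)) {
    ord <- order(E[p, ])
    best <- ord[1]; runner <- ord[2]
    if (E[p, runner] - E[p, best] < gap)
      E[p, best] <- E[p, runner] - gap
  }
  planted_landscape(E, gap = gap, seed = seed)
}

#' Construct a planted landscape from an energy table
#'
#' Lower-level constructor (used by [generate_landscape()] and for degenerate
#' cases such as a flat, zero-signal landscape).
#'
#' @param energy_table length x alphabet numeric matrix with code column
#'   names.
#' @param gap the minimum per-position gap, if known (informational).
#' @param seed generator seed, if any.
#' @return a `planted_landscape`.
#' @export
planted_landscape <- function(energy_table, gap = NA_real_, seed = NA_integer_) {
  stopifnot(is.matrix(energy_table), !is.null(colnames(energy_table)))
  opt <- colnames(energy_table)[apply(energy_table, 1, which.min)]
  structure(list(energy_table = energy_table,
                 alphabet = colnames(energy_table),
                 length = nrow(energy_table),
                 optimum = peptide_sequence(opt),
                 gap = gap, seed = seed),
            class = "planted_landscape")
}

#' True (noise-free) energy of a sequence on a planted landscape
#'
#' @param landscape a `planted_landscape`.
#' @param seq a `peptide_sequence` (or character vector of codes).
#' @return numeric energy (lower = better).
#' @export
landscape_energy <- function(landscape, seq) {
  stopifnot(inherits(landscape, "planted_landscape"))
  codes <- if (inherits(seq, "peptide_sequence")) unclass(seq)
           else normalize_code(seq)
  if (length(codes) != landscape$length)
    pd_error(sprintf("sequence length %d does not match landscape length %d",
                     length(codes), landscape$length), "pepmc_config_error")
  bad <- setdiff(codes, landscape$alphabet)
  if (length(bad))
    pd_error(sprintf("code(s) outside the landscape alphabet: %s",
                     paste(bad, collapse = ", ")), "pepmc_config_error")
  sum(landscape$energy_table[cbind(seq_along(codes),
                                   match(codes, landscape$alphabet))])
}

#' Build a noisy scorer ensemble over a planted landscape
#'
#' Each synthetic scorer returns `E(seq) + bias_i + eps_i` with
#' `eps_i ~ Normal(0, noise_sd_i)`, independent across scorers and across
#' calls (every evaluation of a sampled frame is noised independently, for the
#' reference as well as the candidate).  All synthetic scorers are
#' lower-is-better, so their outputs are already oriented.
#'
#' @param landscape a `planted_landscape`.
#' @param n_scorers number of scorers.
#' @param noise_sd scalar or length-`n_scorers` standard deviations.
#' @param bias scalar or per-scorer constant offsets.
#' @param seed integer seed for the ensemble's private noise stream.
#' @param names scorer names (default `synthetic1..n`).
#' @return object of class `scorer_ensemble`.
#' @export
make_ensemble <- function(landscape, n_scorers, noise_sd, bias = 0, seed = 1,
                          names = paste0("synthetic", seq_len(n_scorers))) {
  stopifnot(inherits(landscape, "planted_landscape"), n_scorers >= 1)
  noise_sd <- rep_len(noise_sd, n_scorers)
  bias <- rep_len(bias, n_scorers)
  if (any(noise_sd < 0)) pd_error("noise_sd must be >= 0", "pepmc_config_error")
  structure(list(landscape = landscape, n_scorers = as.integer(n_scorers),
                 noise_sd = noise_sd, bias = bias, names = names,
                 stream = rng_streams(seed, 1)[[1]]),
            class = "scorer_ensemble")
}

#' Evaluate an ensemble on a sequence
#'
#' @param ensemble a [make_ensemble()] result.
#' @param seq a `peptide_sequence`.
#' @return oriented [score_vector()] of length `n_scorers`.
#' @export
evaluate_ensemble <- function(ensemble, seq) {
  stopifnot(inherits(ensemble, "scorer_ensemble"))
  e <- landscape_energy(ensemble$landscape, seq)
  eps <- if (all(ensemble$noise_sd == 0)) rep(0, ensemble$n_scorers)
         else with_stream(ensemble$stream,
                          stats::rnorm(ensemble$n_scorers, sd = ensemble$noise_sd))
  score_vector(stats::setNames(e + ensemble$bias + eps, ensemble$names))
}

#' Generate synthetic benchmark pairs from a planted landscape
#'
#' Draws pairs of random sequences, labels the lower-true-energy member as the
#' strong binder, maps energies to nanomolar affinities through a fixed
#' exponential (`affinity_nM = exp(beta * (E - E_opt))`, default one energy
#' unit = 10-fold), and scores both members with the ensemble.  Pairs are
#' redrawn until the affinity fold-difference reaches `affinity_gap`.
#'
#' @param landscape a `planted_landscape`.
#' @param ensemble a [make_ensemble()] result (supplies the score vectors).
#' @param n_pairs number of pairs.
#' @param affinity_gap minimum fold-difference between the pair's affinities.
#' @param seed integer seed for the sequence draws.
#' @param beta energy-to-log-affinity slope (default `log(10)`).
#' @return list of `benchmark_pair` objects (see [benchmark_pair()]).
#' @export
generate_benchmark_pairs <- function(landscape, ensemble, n_pairs,
                                     affinity_gap = 1, seed = 1,
                                     beta = log(10)) {
  stopifnot(inherits(landscape, "planted_landscape"), n_pairs >= 1)
  st <- rng_streams(seed, 1)[[1]]
  e_opt <- landscape_energy(landscape, landscape$optimum)
  rand_seq <- function() peptide_sequence(
    with_stream(st, sample(landscape$alphabet, landscape$length, replace = TRUE)))
  out <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    for (try in 1:1000) {
      s1 <- rand_seq(); s2 <- rand_seq()
      e1 <- landscape_energy(landscape, s1)
      e2 <- landscape_energy(landscape, s2)
      if (e1 == e2) next
      fold <- exp(beta * abs(e1 - e2))
      if (fold >= affinity_gap) break
      if (try == 1000)
        pd_error("could not draw a pair with the requested affinity gap",
                 "pepmc_config_error")
    }
    if (e2 < e1) { tmp <- s1; s1 <- s2; s2 <- tmp; tmp <- e1; e1 <- e2; e2 <- tmp }
    out[[k]] <- benchmark_pair(
      id_strong = sprintf("synth%02da", k), id_weak = sprintf("synth%02db", k),
      affinity_strong = exp(beta * (e1 - e_opt)),
      affinity_weak = exp(beta * (e2 - e_opt)),
      scores_strong = evaluate_ensemble(ensemble, s1),
      scores_weak = evaluate_ensemble(ensemble, s2))
  }
  out
}

#' Write synthetic fixtures to a directory
#'
#' Emits a landscape JSON, a scorer-registry YAML describing the synthetic
#' ensemble, and a benchmark pairs CSV (long format; see
#' [write_benchmark_pairs()]).
#'
#' @param dir output directory (created if needed).
#' @param seed integer root seed.
#' @param length,alphabet,gap,n_scorers,noise_sd,n_pairs generator settings.
#' @return invisibly, the paths written.
#' @export
write_fixtures <- function(dir, seed, length = 9,
                           alphabet = natural_amino_acids()$code, gap = 1,
                           n_scorers = 6, noise_sd = 0.25, n_pairs = 6) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ls <- generate_landscape(length, alphabet, gap, seed)
  en <- make_ensemble(ls, n_scorers, noise_sd, seed = seed + 1L)
  pairs <- generate_benchmark_pairs(ls, en, n_pairs, affinity_gap = 100,
                                    seed = seed + 2L)
  p1 <- file.path(dir, "landscape.json")
  jsonlite::write_json(list(alphabet = ls$alphabet, gap = ls$gap,
                            seed = ls$seed,
                            optimum = format_sequence(ls$optimum),
                            energy_table = as.data.frame(ls$energy_table)),
                       p1, digits = NA, auto_unbox = TRUE)
  p2 <- file.path(dir, "scorers.yaml")
  yaml::write_yaml(stats::setNames(
    lapply(en$names, function(n) list(orientation = "lower_is_better",
                                      command = "synthetic")), en$names), p2)
  p3 <- file.path(dir, "benchmark_pairs.csv")
  write_benchmark_pairs(pairs, p3)
  invisible(c(p1, p2, p3))
}

#' Read a landscape written by [write_fixtures()]
#'
#' @param path landscape JSON path.
#' @return a `planted_landscape`.
#' @export
read_landscape <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  E <- as.matrix(x$energy_table)
  colnames(E) <- x$alphabet
  planted_landscape(E, gap = x$gap, seed = x$seed)
}
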