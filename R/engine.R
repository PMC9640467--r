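# The design engine: propose -> sample -> score -> decide -> log, for a fixed
# attempt budget.

#' Design run configuration
#'
#' @param mutable_positions 1-based indices the proposal may touch.
#' @param alphabet character vector of monomer codes (or a data.frame with a
#'   `code` column, e.g. from [subset_alphabet()]).
#' @param acceptance list: either `list(mode = "consensus", n_required = 4)`
#'   or `list(mode = "metropolis", temperature = ..., scorer = <name>)`
#'   (Metropolis uses exactly one scoring function).
#' @param attempts number of proposals (the budget counts proposals, not
#'   acceptances; default 100).
#' @param seed root RNG seed, split into independent streams for proposals,
#'   Metropolis draws and synthetic scorer noise, so adding scorers does not
#'   perturb the proposal sequence.
#' @param sampling a [sampling_config()].
#' @param backend `"mock"` or `"rosetta"`.
#' @param allow_identity allow proposing the current residue's own code?
#' @param rescore_reference re-score the reference frame on every attempt
#'   (makes attempts statistically independent under a noisy scorer); default
#'   `FALSE`: the reference frame and its scores are reused until an
#'   acceptance replaces them, which avoids score drift of the reference.
#' @param ties_favorable treat zero deltas as favorable in the consensus?
#' @return object of class `design_config`.
#' @export
design_config <- function(mutable_positions, alphabet,
                          acceptance = list(mode = "consensus", n_required = 4),
                          attempts = 100, seed = 1,
                          sampling = sampling_config(),
                          backend = c("mock", "rosetta"),
                          allow_identity = FALSE,
                          rescore_reference = FALSE,
                          ties_favorable = FALSE) {
  backend <- match.arg(backend)
  if (attempts < 1) pd_error("attempts must be >= 1", "pepmc_config_error")
  if (is.data.frame(alphabet)) alphabet <- alphabet$code
  alphabet <- unique(normalize_code(alphabet))
  if (!acceptance$mode %in% c("consensus", "metropolis"))
    pd_error("acceptance mode must be 'consensus' or 'metropolis'",
             "pepmc_config_error")
  structure(list(mutable_positions = as.integer(mutable_positions),
                 alphabet = alphabet, acceptance = acceptance,
                 attempts = as.integer(attempts), seed = as.integer(seed),
                 sampling = sampling, backend = backend,
                 allow_identity = isTRUE(allow_identity),
                 rescore_reference = isTRUE(rescore_reference),
                 ties_favorable = isTRUE(ties_favorable)),
            class = "design_config")
}

# one oriented score vector for a state, from either scorer form
.score_state <- function(scorers, state) {
  if (inherits(scorers, "scorer_ensemble"))
    return(unclass(evaluate_ensemble(scorers, state$sequence)))
  vals <- vapply(scorers, function(f) f(state), numeric(1))
  if (is.null(names(vals))) names(vals) <- paste0("scorer", seq_along(vals))
  vals
}

# an ensemble re-seeded from the design seed, so identical (config, seed)
# yield identical runs regardless of how the ensemble was used before
.reseed_ensemble <- function(ensemble, stream) {
  e <- ensemble
  e$stream <- stream
  e
}

#' Run the iterative design
#'
#' For each of `attempts` proposals: draw a single-point mutation, sample the
#' mutated complex through the backend, score it, and accept or reject by the
#' configured rule.  On acceptance the candidate's frame and scores become the
#' reference; on rejection the reference is reused (see
#' `rescore_reference`).  The reference complex is scored from its own sampled
#' frame at initialization, so the first comparison is frame-to-frame.
#'
#' @param initial a prepared `complex_state` (see [prepare()]).
#' @param config a [design_config()].
#' @param scorers a [make_ensemble()] result (its noise stream is re-derived
#'   from `config$seed`), or a named list of functions `f(state) -> oriented
#'   score`.
#' @return object of class `design_result`: list with `records` (one row per
#'   attempt), `accepted` (the accepted chain), `start_sequence`,
#'   `final_sequence`, `initial_scores`, `candidate_pool` (accepted sequences
#'   ranked by consensus count, ties by summed z-scored deltas), `config`,
#'   `incomplete`.
#' @export
run_design <- function(initial, config, scorers) {
  stopifnot(inherits(initial, "complex_state"), inherits(config, "design_config"))
  streams <- rng_streams(config$seed, 3)  # proposal, metropolis, scorer noise
  if (inherits(scorers, "scorer_ensemble"))
    scorers <- .reseed_ensemble(scorers, streams[[3]])

  ref_state <- initial
  ref_scores <- .score_state(scorers, ref_state)
  scorer_names <- names(ref_scores)
  initial_scores <- ref_scores

  if (config$acceptance$mode == "metropolis") {
    mscorer <- config$acceptance$scorer
    if (is.null(mscorer)) {
      if (length(scorer_names) != 1)
        pd_error("Metropolis acceptance requires exactly one scorer (or acceptance$scorer naming it)",
                 "pepmc_config_error")
      mscorer <- scorer_names
    }
    if (!mscorer %in% scorer_names)
      pd_error(sprintf("acceptance$scorer '%s' is not among the scorers", mscorer),
               "pepmc_config_error")
    mcfg <- metropolis_config(config$acceptance$temperature)
  }

  n <- config$attempts
  rec <- list(step = integer(n), mutation = character(n),
              sequence = character(n), accepted = logical(n),
              n_favorable = integer(n), acceptance_probability = rep(NA_real_, n))
  score_mat <- matrix(NA_real_, n, length(scorer_names),
                      dimnames = list(NULL, scorer_names))
  delta_mat <- score_mat
  incomplete <- FALSE; failure <- NULL

  for (t in seq_len(n)) {
    out <- tryCatch({
      mut <- with_stream(streams[[1]],
        propose_mutation(ref_state$sequence, config$mutable_positions,
                         config$alphabet,
                         allow_identity = config$allow_identity))
      cand <- mutate_and_sample(ref_state, mut, config$sampling,
                                backend = config$backend, seed = config$seed)
      cand_scores <- .score_state(scorers, cand$state)
      list(mut = mut, cand = cand, cand_scores = cand_scores)
    }, pepmc_backend_error = function(e) e)
    if (inherits(out, "error")) { incomplete <- TRUE; failure <- out; break }

    if (config$rescore_reference)
      ref_scores <- .score_state(scorers, ref_state)
    delta <- score_delta(score_vector(ref_scores),
                         score_vector(out$cand_scores))
    decision <- if (config$acceptance$mode == "consensus") {
      consensus_accept(delta, config$acceptance$n_required,
                       ties_favorable = config$ties_favorable)
    } else {
      with_stream(streams[[2]],
                  metropolis_accept(unclass(delta)[[mscorer]], mcfg))
    }

    rec$step[t] <- t
    rec$mutation[t] <- format_mutation(out$mut)
    rec$sequence[t] <- format_sequence(out$cand$state$sequence)
    rec$accepted[t] <- decision$accepted
    rec$n_favorable[t] <- decision$n_favorable
    if (!is.null(decision$acceptance_probability))
      rec$acceptance_probability[t] <- decision$acceptance_probability
    score_mat[t, ] <- out$cand_scores
    delta_mat[t, ] <- unclass(delta)

    if (decision$accepted) {
      ref_state <- out$cand$state
      ref_scores <- out$cand_scores
    }
  }

  done <- if (incomplete) t - 1L else n
  keep <- seq_len(done)
  records <- data.frame(step = rec$step[keep], mutation = rec$mutation[keep],
                        sequence = rec$sequence[keep],
                        accepted = rec$accepted[keep],
                        n_favorable = rec$n_favorable[keep],
                        acceptance_probability = rec$acceptance_probability[keep],
                        stringsAsFactors = FALSE)
  sc <- as.data.frame(score_mat[keep, , drop = FALSE])
  names(sc) <- paste0("score_", scorer_names)
  records <- cbind(records, sc)

  accepted <- records[records$accepted, , drop = FALSE]

  # candidate pool: rank accepted sequences by consensus count, then by the
  # sum of z-scored oriented deltas (more negative = stronger improvement)
  pool <- accepted
  if (nrow(pool)) {
    dz <- scale(delta_mat[keep, , drop = FALSE])
    dz[is.nan(dz)] <- 0
    pool$delta_z_sum <- rowSums(dz, na.rm = TRUE)[records$accepted]
    pool <- pool[order(-pool$n_favorable, pool$delta_z_sum), , drop = FALSE]
  } else pool$delta_z_sum <- numeric(0)

  res <- structure(list(records = records, accepted = accepted,
                        start_sequence = initial$sequence,
                        final_sequence = ref_state$sequence,
                        initial_scores = initial_scores,
                        candidate_pool = pool,
                        config = config,
                        incomplete = incomplete),
                   class = "design_result")
  if (incomplete) {
    pd_warn(sprintf("design aborted at attempt %d: %s (partial result returned)",
                    done + 1L, conditionMessage(failure)),
            "pepmc_incomplete_run")
  }
  res
}

#' Accepted-sequence table
#'
#' One row per accepted attempt: step index, mutation string, formatted
#' sequence — the layout of a published accepted-sequence design table.
#'
#' @param result a `design_result`.
#' @return data.frame with columns `step`, `mutation`, `sequence`.
#' @export
summarize_accepted <- function(result) {
  stopifnot(inherits(result, "design_result"))
  result$accepted[, c("step", "mutation", "sequence")]
}

#' Per-scorer accepted-score trajectory
#'
#' For each scorer, the oriented score at step 0 (the initial reference frame)
#' and at each accepted step; a series with k acceptances has k + 1 points.  A
#' scorer's series may be non-monotone even when every step was consensus-
#' accepted: the consensus can move through a single function's local minima.
#'
#' @param result a consensus-mode `design_result`.
#' @return long data.frame: `scorer`, `point` (0..k), `step`, `score`.
#' @export
score_trajectory <- function(result) {
  stopifnot(inherits(result, "design_result"))
  scorer_names <- names(result$initial_scores)
  acc <- result$accepted
  do.call(rbind, lapply(scorer_names, function(nm) {
    scores <- c(result$initial_scores[[nm]], acc[[paste0("score_", nm)]])
    data.frame(scorer = nm, point = seq_along(scores) - 1L,
               step = c(0L, acc$step), score = scores,
               stringsAsFactors = FALSE)
  }))
}

#' Write a design run to a directory
#'
#' Emits `records.tsv` (all attempts), `accepted.tsv` (accepted-sequence
#' table), `trajectory.csv` (per-scorer accepted-score series),
#' `config-resolved.yaml` and `seed`.
#'
#' @param result a `design_result`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_design_run <- function(result, dir) {
  stopifnot(inherits(result, "design_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(records = file.path(dir, "records.tsv"),
             accepted = file.path(dir, "accepted.tsv"),
             trajectory = file.path(dir, "trajectory.csv"),
             config = file.path(dir, "config-resolved.yaml"),
             seed = file.path(dir, "seed"))
  utils::write.table(result$records, paths["records"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(summarize_accepted(result), paths["accepted"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(score_trajectory(result), paths["trajectory"],
                   row.names = FALSE, quote = FALSE)
  cfg <- result$config
  yaml::write_yaml(list(mutable_positions = cfg$mutable_positions,
                        alphabet = cfg$alphabet,
                        acceptance = cfg$acceptance,
                        attempts = cfg$attempts, seed = cfg$seed,
                        backend = cfg$backend,
                        sampling = unclass(cfg$sampling),
                        allow_identity = cfg$allow_identity,
                        rescore_reference = cfg$rescore_reference,
                        incomplete = result$incomplete),
                   paths["config"])
  writeLines(as.character(cfg$seed), paths["seed"])
  invisible(paths)
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("design_result: %d attempts, %d accepted%s\n",
              nrow(x$records), nrow(x$accepted),
              if (x$incomplete) " (INCOMPLETE)" else ""))
  cat(sprintf("  start: %s\n  final: %s\n",
              format_sequence(x$start_sequence),
              format_sequence(x$final_sequence)))
  invisible(x)
}
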