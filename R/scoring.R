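# Score orientation, per-scorer deltas, and the two acceptance rules
# (consensus of N scoring functions; Metropolis-Hastings).

#' Scorer specification
#'
#' Fixes a scorer's identity and orientation.  Oriented scores are always
#' lower-is-better: `higher_is_better` scorers are negated on orientation (as
#' done for neural-network affinity predictors whose raw output increases with
#' predicted affinity).
#'
#' @param name scorer identifier.
#' @param orientation `"lower_is_better"` or `"higher_is_better"`.
#' @return object of class `scorer_spec`.
#' @export
scorer_spec <- function(name, orientation = c("lower_is_better",
                                              "higher_is_better")) {
  orientation <- match.arg(orientation)
  structure(list(name = name, orientation = orientation), class = "scorer_spec")
}

#' Default scorer registry
#'
#' The six-function ensemble used by the protocol: DLigand2, Vina, Cyscore,
#' NNscore (negated), a Rosetta score configured for docking, and the internal
#' Rosetta score used during relaxation.
#'
#' @return named list of `scorer_spec`s.
#' @export
default_scorer_registry <- function() {
  list(
    dligand2         = scorer_spec("dligand2", "lower_is_better"),
    vina             = scorer_spec("vina", "lower_is_better"),
    cyscore          = scorer_spec("cyscore", "lower_is_better"),
    nnscore          = scorer_spec("nnscore", "higher_is_better"),
    rosetta_docking  = scorer_spec("rosetta_docking", "lower_is_better"),
    rosetta_internal = scorer_spec("rosetta_internal", "lower_is_better")
  )
}

#' Read a scorer registry from YAML
#'
#' Maps scorer name to orientation (and, for external plug-ins, a command
#' template invoked with a structure file path).
#'
#' @param path YAML file: `name: {orientation: ..., command: ...}` entries.
#' @return named list of `scorer_spec`s (command templates attached as the
#'   `command` attribute).
#' @export
read_scorer_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    sp <- scorer_spec(nm, raw[[nm]]$orientation)
    if (!is.null(raw[[nm]]$command)) attr(sp, "command") <- raw[[nm]]$command
    sp
  })
  stats::setNames(out, names(raw))
}

#' Orient a raw scorer output
#'
#' Lower-is-better scores pass through; higher-is-better scores are negated.
#' A non-finite raw score signals a scorer failure (warning of class
#' `pepmc_scorer_failure`) and yields `NA`; downstream, a failed scorer
#' abstains from the consensus.
#'
#' @param raw numeric raw score.
#' @param spec a [scorer_spec()].
#' @return oriented score (lower = better), or `NA` on failure.
#' @export
orient <- function(raw, spec) {
  stopifnot(inherits(spec, "scorer_spec"))
  if (!is.finite(raw)) {
    pd_warn(sprintf("scorer '%s' returned a non-finite value; abstaining",
                    spec$name), "pepmc_scorer_failure")
    return(NA_real_)
  }
  if (spec$orientation == "higher_is_better") -raw else raw
}

#' Oriented score vector
#'
#' @param values named numeric vector of oriented scores, one per scorer.
#' @return object of class `score_vector`.
#' @export
score_vector <- function(values) {
  if (is.null(names(values)) || any(!nzchar(names(values))))
    pd_error("score vector must be named by scorer", "pepmc_config_error")
  structure(values, class = "score_vector")
}

#' Per-scorer score differences (candidate minus reference)
#'
#' @param reference,candidate named oriented score vectors over the same
#'   scorer set.
#' @return named numeric vector of deltas (class `score_delta`); negative
#'   means the candidate improved that scorer.
#' @export
score_delta <- function(reference, candidate) {
  reference <- unclass(reference); candidate <- unclass(candidate)
  sym <- union(setdiff(names(reference), names(candidate)),
               setdiff(names(candidate), names(reference)))
  if (length(sym))
    pd_error(sprintf("scorer sets differ between reference and candidate: %s",
                     paste(sym, collapse = ", ")), "pepmc_config_error",
             scorers = sym)
  structure(candidate[names(reference)] - reference, class = "score_delta")
}

#' Consensus acceptance rule
#'
#' A mutation is accepted when at least `n_required` of the scoring functions
#' report a strictly negative oriented score difference.  A delta of exactly 0
#' is not favorable (so an identity mutation is never consensus-accepted);
#' `ties_favorable = TRUE` restores `<=`.  `NA` deltas (failed scorers)
#' abstain: they are not favorable and `n_required` is unchanged, so a failure
#' can only hinder acceptance.
#'
#' @param delta named numeric deltas (see [score_delta()]).
#' @param n_required number of agreeing scorers required (default 4).
#' @param ties_favorable count zero deltas as favorable?
#' @return an `acceptance_decision`: list with `accepted`, `n_favorable`,
#'   `n_scorers`, `n_abstained`, `rule`.
#' @export
consensus_accept <- function(delta, n_required = 4, ties_favorable = FALSE) {
  delta <- unclass(delta)
  n_scorers <- length(delta)
  if (n_required < 1 || n_required > n_scorers)
    pd_error(sprintf("n_required must be in 1..%d", n_scorers),
             "pepmc_config_error")
  fav <- if (ties_favorable) delta <= 0 else delta < 0
  n_favorable <- sum(fav, na.rm = TRUE)
  structure(list(accepted = n_favorable >= n_required,
                 n_favorable = n_favorable,
                 n_scorers = n_scorers,
                 n_abstained = sum(is.na(delta)),
                 rule = list(type = "consensus", n_required = n_required)),
            class = "acceptance_decision")
}

#' Metropolis configuration
#'
#' Effective temperature in oriented-score units.  The working range is 1
#' (strict) to 10 (relaxed); values outside it are allowed with a warning.
#'
#' @param temperature effective temperature, > 0.
#' @return object of class `metropolis_config`.
#' @export
metropolis_config <- function(temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0)
    pd_error("Metropolis temperature must be a single number > 0",
             "pepmc_config_error")
  if (temperature < 1 || temperature > 10)
    pd_warn(sprintf("effective temperature %.3g outside the usual 1..10 range",
                    temperature), "pepmc_temperature_range")
  structure(list(temperature = temperature), class = "metropolis_config")
}

#' Metropolis-Hastings acceptance rule
#'
#' An improving move (delta <= 0) is always accepted; a worsening move is
#' accepted with probability `exp(-delta / temperature)`.  Uses the session
#' RNG (seed or wrap in [with_stream()]).
#'
#' @param delta single oriented score difference (candidate - reference).
#' @param config a [metropolis_config()], or a bare temperature.
#' @return an `acceptance_decision` with `acceptance_probability` recorded.
#' @export
metropolis_accept <- function(delta, config) {
  if (!inherits(config, "metropolis_config"))
    config <- metropolis_config(config)
  if (!is.finite(delta))
    pd_error("Metropolis delta must be finite", "pepmc_config_error")
  p <- min(1, exp(-delta / config$temperature))
  accepted <- delta <= 0 || stats::runif(1) < p
  structure(list(accepted = accepted,
                 n_favorable = as.integer(delta < 0),
                 n_scorers = 1L,
                 n_abstained = 0L,
                 acceptance_probability = p,
                 rule = list(type = "metropolis",
                             temperature = config$temperature)),
            class = "acceptance_decision")
}

#' @export
print.acceptance_decision <- function(x, ...) {
  cat(sprintf("%s (%d/%d favorable, rule: %s)\n",
              if (x$accepted) "ACCEPTED" else "rejected",
              x$n_favorable, x$n_scorers, x$rule$type))
  invisible(x)
}
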