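# internal helpers: classed conditions and reproducible RNG streams

pd_error <- function(msg, class, call. = FALSE, ...) {
  stop(errorCondition(msg, ..., class = c(class, "pepmc_error")))
}

pd_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "pepmc_warning")))
}

#' Independent RNG streams from one root seed
#'
#' Splits a single integer seed into `n` independent L'Ecuyer-CMRG streams so
#' that, e.g., mutation proposals, Metropolis draws and scorer noise do not
#' perturb one another when a component is added or removed.
#'
#' @param seed integer root seed.
#' @param n number of streams.
#' @return list of stream objects (environments holding RNG state), usable
#'   with [with_stream()].
#' @export
rng_streams <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG")
  state <- get(".Random.seed", globalenv())
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    e <- new.env(parent = emptyenv())
    e$state <- state
    class(e) <- "pepmc_rng_stream"
    streams[[i]] <- e
    state <- parallel::nextRNGStream(state)
  }
  streams
}

#' Evaluate an expression under a saved RNG stream
#'
#' Swaps the stream's state into the session RNG, evaluates `expr`, saves the
#' advanced state back into the stream, and restores the caller's RNG.
#'
#' @param stream a stream from [rng_streams()].
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @export
with_stream <- function(stream, expr) {
  stopifnot(inherits(stream, "pepmc_rng_stream"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}
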