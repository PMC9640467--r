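# Peptide sequences with NNAAs: bracketed text notation, single-point
# mutations, log replay, and seeded mutation proposal.
#
# Notation: natural residues as one-letter codes, NNAAs as bracketed 3-letter
# PDB-style tokens, e.g. "PTSYA[ORN]DDS".  Positions are 1-based.

#' Construct a peptide sequence
#'
#' @param codes character vector of monomer codes (any mix of one-letter
#'   naturals and 3-letter tokens; normalized internally).
#' @return object of class `peptide_sequence` (a character vector of
#'   normalized codes).
#' @export
peptide_sequence <- function(codes) {
  if (length(codes) < 1)
    pd_error("a peptide needs at least one residue", "pepmc_parse_error")
  structure(normalize_code(codes), class = "peptide_sequence")
}

#' Parse the bracketed peptide notation
#'
#' One residue per uppercase letter outside brackets (standard one-letter
#' codes) and one per `[TOKEN]` group; tokens are whitespace-stripped, so
#' `"[41 H]"` and `"[41H]"` are the same monomer.
#'
#' @param text notation string, e.g. `"PTSYA[ORN]DDS"`.
#' @return a `peptide_sequence`.
#' @export
parse_sequence <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- trimws(text)
  if (!nzchar(text)) pd_error("empty sequence string", "pepmc_parse_error")
  chars <- strsplit(text, "")[[1]]
  codes <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      close <- which(chars == "]" & seq_along(chars) > i)
      if (!length(close))
        pd_error(sprintf("unbalanced '[' at position %d in '%s'", i, text),
                 "pepmc_parse_error", position = i)
      tok <- paste(chars[(i + 1):(close[1] - 1)], collapse = "")
      if (!nzchar(gsub("[[:space:]]", "", tok)))
        pd_error(sprintf("empty bracket token at position %d in '%s'", i, text),
                 "pepmc_parse_error", position = i)
      codes <- c(codes, tok)
      i <- close[1] + 1L
    } else if (ch == "]") {
      pd_error(sprintf("unbalanced ']' at position %d in '%s'", i, text),
               "pepmc_parse_error", position = i)
    } else if (grepl("[A-Za-z]", ch)) {
      up <- toupper(ch)
      if (!up %in% names(.nat_one_to_three))
        pd_error(sprintf("'%s' is not a natural amino-acid one-letter code (position %d)",
                         ch, i), "pepmc_unknown_residue_error", position = i)
      codes <- c(codes, up)
      i <- i + 1L
    } else if (grepl("[[:space:]]", ch)) {
      i <- i + 1L
    } else {
      pd_error(sprintf("unexpected character '%s' at position %d in '%s'",
                       ch, i, text), "pepmc_parse_error", position = i)
    }
  }
  peptide_sequence(codes)
}

#' Format a peptide sequence in bracketed notation
#'
#' Naturals print as one-letter codes, NNAAs as `[CODE]`;
#' `parse_sequence(format_sequence(s))` recovers `s`.
#'
#' @param seq a `peptide_sequence`.
#' @return notation string.
#' @export
format_sequence <- function(seq) {
  stopifnot(inherits(seq, "peptide_sequence"))
  codes <- unclass(seq)
  paste(ifelse(is_natural_code(codes), .nat_three_to_one[codes],
               paste0("[", codes, "]")), collapse = "")
}

#' @export
print.peptide_sequence <- function(x, ...) {
  cat(format_sequence(x), sprintf(" (%d residues)\n", length(x)))
  invisible(x)
}

#' Single-point mutation record
#'
#' @param old_code monomer code currently at `position`.
#' @param position 1-based residue index.
#' @param new_code replacement monomer code.
#' @return object of class `mutation`.
#' @export
mutation <- function(old_code, position, new_code) {
  position <- as.integer(position)
  if (is.na(position) || position < 1)
    pd_error("mutation position must be a positive integer", "pepmc_parse_error")
  structure(list(old_code = normalize_code(old_code), position = position,
                 new_code = normalize_code(new_code)), class = "mutation")
}

#' Parse / format the "[old]-position-[new]" mutation notation
#'
#' Naturals may appear unbracketed (one- or three-letter); bracket tokens are
#' whitespace-stripped.  Examples: `"G-6-[ORN]"`, `"[ORN]-6-[41 H]"`.
#'
#' @param text mutation string.
#' @return `parse_mutation` returns a `mutation`; `format_mutation` a string
#'   (naturals unbracketed one-letter, NNAAs bracketed).
#' @export
parse_mutation <- function(text) {
  m <- regmatches(text, regexec(
    "^\\s*(\\[[^]]+\\]|[A-Za-z0-9]+)-(\\d+)-(\\[[^]]+\\]|[A-Za-z0-9]+)\\s*$",
    text))[[1]]
  if (length(m) != 4)
    pd_error(sprintf("cannot parse mutation '%s' (expected [old]-position-[new])",
                     text), "pepmc_parse_error")
  strip <- function(x) gsub("^\\[|\\]$", "", x)
  mutation(strip(m[2]), as.integer(m[3]), strip(m[4]))
}

#' @rdname parse_mutation
#' @param mut a `mutation`.
#' @export
format_mutation <- function(mut) {
  stopifnot(inherits(mut, "mutation"))
  fmt <- function(code) if (is_natural_code(code)) .nat_three_to_one[[code]]
                        else paste0("[", code, "]")
  sprintf("%s-%d-%s", fmt(mut$old_code), mut$position, fmt(mut$new_code))
}

#' @export
print.mutation <- function(x, ...) {
  cat(format_mutation(x), "\n")
  invisible(x)
}

#' Apply a single-point mutation
#'
#' The mutation's `old_code` must match the residue currently at its position;
#' a mismatch raises a stale-mutation error, which guards against replaying a
#' log against the wrong sequence.  The input sequence is unchanged (value
#' semantics).
#'
#' @param seq a `peptide_sequence`.
#' @param mut a `mutation`.
#' @return the mutated `peptide_sequence`.
#' @export
apply_mutation <- function(seq, mut) {
  stopifnot(inherits(seq, "peptide_sequence"), inherits(mut, "mutation"))
  if (mut$position > length(seq))
    pd_error(sprintf("mutation position %d exceeds sequence length %d",
                     mut$position, length(seq)), "pepmc_stale_mutation_error")
  current <- unclass(seq)[mut$position]
  if (current != mut$old_code)
    pd_error(sprintf("stale mutation %s: residue at position %d is %s, not %s",
                     format_mutation(mut), mut$position, current, mut$old_code),
             "pepmc_stale_mutation_error")
  codes <- unclass(seq)
  codes[mut$position] <- mut$new_code
  structure(codes, class = "peptide_sequence")
}

#' Replay an ordered mutation log
#'
#' Folds [apply_mutation()] over the log; the first stale mutation aborts with
#' its step index.
#'
#' @param seq starting `peptide_sequence`.
#' @param log list of `mutation` objects, or a character vector of mutation
#'   strings.
#' @return final `peptide_sequence`.
#' @export
replay_mutations <- function(seq, log) {
  stopifnot(inherits(seq, "peptide_sequence"))
  if (is.character(log)) log <- lapply(log, parse_mutation)
  for (k in seq_along(log)) {
    seq <- tryCatch(apply_mutation(seq, log[[k]]),
      pepmc_stale_mutation_error = function(e)
        pd_error(sprintf("replay aborted at step %d: %s", k, conditionMessage(e)),
                 "pepmc_stale_mutation_error", step = k))
  }
  seq
}

#' Propose a random single-point mutation
#'
#' Samples a position uniformly over `mutable_positions` and a replacement
#' code uniformly over the alphabet; by default the residue currently at the
#' sampled position is excluded (an identity substitution wastes an attempt),
#' with `allow_identity = TRUE` restoring plain uniform sampling.  Uses the
#' session RNG; seed or wrap in [with_stream()] for reproducibility.
#'
#' @param seq a `peptide_sequence`.
#' @param mutable_positions integer vector of 1-based indices.
#' @param alphabet character vector of monomer codes (or a data.frame with a
#'   `code` column, as returned by [subset_alphabet()]).
#' @param allow_identity propose the current residue's own code?
#' @return a `mutation`.
#' @export
propose_mutation <- function(seq, mutable_positions, alphabet,
                             allow_identity = FALSE) {
  stopifnot(inherits(seq, "peptide_sequence"))
  if (is.data.frame(alphabet)) alphabet <- alphabet$code
  alphabet <- unique(normalize_code(alphabet))
  if (!length(mutable_positions) || !length(alphabet))
    pd_error("mutable_positions and alphabet must be non-empty", "pepmc_config_error")
  if (any(mutable_positions < 1 | mutable_positions > length(seq)))
    pd_error("mutable position outside the sequence", "pepmc_config_error")
  codes <- unclass(seq)
  choices <- function(pos) if (allow_identity) alphabet
                           else setdiff(alphabet, codes[pos])
  if (!allow_identity) {
    open <- mutable_positions[vapply(mutable_positions,
                                     function(p) length(choices(p)) > 0, logical(1))]
    if (!length(open))
      pd_error("alphabet exhausted: only the current residue is allowed at every mutable position",
               "pepmc_exhausted_alphabet_error")
  } else open <- mutable_positions
  pos <- if (length(open) == 1) open else sample(open, 1)
  cand <- choices(pos)
  new_code <- if (length(cand) == 1) cand else sample(cand, 1)
  mutation(codes[pos], pos, new_code)
}

#' Read / write a mutation log TSV
#'
#' Columns `step`, `mutation`, `sequence` (and optionally `accepted`), the
#' layout of an accepted-sequence design table.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_mutation_log <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
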