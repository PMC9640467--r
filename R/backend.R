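# Conformational-sampling backend contract: mutate -> relax -> sample ->
# score-ready structure.  Two backends: "mock" (deterministic, desk-scale,
# used throughout the tests) and "rosetta" (command-template adapter for a
# local Rosetta installation; never executed by the test suite).

#' Sampling configuration
#'
#' Defaults follow parameters tuned for protein-peptide complexes: 20,000
#' Backrub Monte Carlo trials at kT 1.2, with flexible-side-chain relaxation
#' after each mutation.
#'
#' @param backrub_trials number of Backrub trials (>= 1).
#' @param kT Monte Carlo temperature in Rosetta units (> 0).
#' @param relax_flexible_sidechains relax side chains after mutation?
#' @return object of class `sampling_config`.
#' @export
sampling_config <- function(backrub_trials = 20000, kT = 1.2,
                            relax_flexible_sidechains = TRUE) {
  if (backrub_trials < 1) pd_error("backrub_trials must be >= 1", "pepmc_config_error")
  if (kT <= 0) pd_error("kT must be > 0", "pepmc_config_error")
  structure(list(backrub_trials = as.integer(backrub_trials), kT = kT,
                 relax_flexible_sidechains = isTRUE(relax_flexible_sidechains)),
            class = "sampling_config")
}

#' Protein-peptide complex state
#'
#' @param structure PDB file path or a synthetic structure token.
#' @param peptide_chain chain identifier of the peptide.
#' @param sequence the peptide's `peptide_sequence`.
#' @param generation count of accepted mutations applied so far.
#' @param frame identifier of the last sampled frame.
#' @return object of class `complex_state`.
#' @export
complex_state <- function(structure, peptide_chain, sequence, generation = 0L,
                          frame = NULL) {
  stopifnot(inherits(sequence, "peptide_sequence"))
  if (is.null(frame))
    frame <- sprintf("frame:init:%s", format_sequence(sequence))
  structure(list(structure = structure, peptide_chain = peptide_chain,
                 sequence = sequence, generation = as.integer(generation),
                 frame = frame),
            class = "complex_state")
}

#' Prepare a complex for the design loop
#'
#' For a PDB file, reads the structure, checks the peptide chain is present,
#' and extracts its residue sequence (natural residues by 3-letter name, any
#' other residue kept as its PDB component code).  Protonation is delegated to
#' the sampling backend (the mock backend is a no-op).  For a synthetic token,
#' the declared `sequence` is used as-is.
#'
#' @param structure PDB path, or any token for a synthetic state.
#' @param peptide_chain chain identifier.
#' @param config a [sampling_config()].
#' @param sequence declared `peptide_sequence` (required for synthetic states;
#'   ignored for PDB input).
#' @return a `complex_state` ready for the first scoring pass.
#' @export
prepare <- function(structure, peptide_chain, config = sampling_config(),
                    sequence = NULL) {
  stopifnot(inherits(config, "sampling_config"))
  if (is.character(structure) && length(structure) == 1 &&
      grepl("\\.pdb$", structure, ignore.case = TRUE)) {
    if (!file.exists(structure))
      pd_error(sprintf("structure file not found: %s", structure), "pepmc_io_error")
    pdb <- bio3d::read.pdb(structure, verbose = FALSE)
    atoms <- pdb$atom[pdb$atom$type == "ATOM" | pdb$atom$type == "HETATM", ]
    chains <- unique(atoms$chain)
    if (!peptide_chain %in% chains)
      pd_error(sprintf("chain '%s' not found; available chains: %s",
                       peptide_chain, paste(chains, collapse = ", ")),
               "pepmc_input_error", chains = chains)
    ch <- atoms[atoms$chain == peptide_chain, ]
    resid <- ch$resid[!duplicated(ch$resno)]
    sequence <- peptide_sequence(resid)
  } else if (is.null(sequence)) {
    pd_error("a synthetic state needs a declared sequence", "pepmc_input_error")
  }
  complex_state(structure, peptide_chain, sequence)
}

#' Mutate the peptide and sample the new complex
#'
#' Contract: the returned structure is the last frame of the sampling
#' trajectory; the returned state carries the mutated sequence; the input
#' state is untouched.  The mock backend is a pure function of
#' `(state, mutation, seed)` — its frame token is deterministic — so design
#' runs are exactly reproducible.  The Rosetta backend shells out the
#' command templates of [rosetta_commands()] and requires a local
#' installation.
#'
#' @param state a `complex_state`.
#' @param mut a `mutation` valid against `state$sequence`.
#' @param config a [sampling_config()].
#' @param backend `"mock"` or `"rosetta"`.
#' @param seed integer folded into the mock frame token.
#' @param rosetta list of paths for the Rosetta adapter (see
#'   [rosetta_commands()]).
#' @return list with `state` (new `complex_state`) and `frame` (last-frame
#'   structure handle).
#' @export
mutate_and_sample <- function(state, mut, config = sampling_config(),
                              backend = c("mock", "rosetta"), seed = 0L,
                              rosetta = list()) {
  stopifnot(inherits(state, "complex_state"), inherits(mut, "mutation"))
  backend <- match.arg(backend)
  new_seq <- apply_mutation(state$sequence, mut)  # validates the mutation
  if (backend == "mock") {
    frame <- sprintf("frame:g%d:%s:%s:s%d", state$generation + 1L,
                     format_mutation(mut), format_sequence(new_seq),
                     as.integer(seed))
    new_state <- complex_state(state$structure, state$peptide_chain, new_seq,
                               generation = state$generation + 1L,
                               frame = frame)
    return(list(state = new_state, frame = frame))
  }
  cmds <- do.call(rosetta_commands,
                  c(list(state = state, mut = mut, config = config), rosetta))
  exe <- strsplit(cmds$commands[1], " ")[[1]][1]
  if (!nzchar(Sys.which(exe)))
    pd_error(sprintf("Rosetta backend: executable '%s' not found on PATH", exe),
             "pepmc_backend_error", commands = cmds$commands)
  for (cmd in cmds$commands) {
    status <- system(cmd)
    if (status != 0)
      pd_error(sprintf("Rosetta backend command failed (exit %d): %s",
                       status, cmd), "pepmc_backend_error", exit_status = status)
  }
  new_state <- complex_state(cmds$output_pdb, state$peptide_chain, new_seq,
                             generation = state$generation + 1L,
                             frame = cmds$output_pdb)
  list(state = new_state, frame = cmds$output_pdb)
}

#' Rosetta adapter command templates
#'
#' Builds the shell commands for one mutate-relax-sample cycle: fixed-backbone
#' design (`fixbb`) driven by a per-mutation resfile to introduce the single
#' substitution, flexible-side-chain relax, and Backrub sampling with the
#' configured number of trials and kT.  NNAA parameter files are located via
#' `extra_res_path`; generating those parameter files is out of scope.
#'
#' @param state a `complex_state` whose `structure` is a PDB path.
#' @param mut the `mutation` to introduce.
#' @param config a [sampling_config()].
#' @param fixbb_exe,relax_exe,backrub_exe executable names/paths.
#' @param extra_res_path directory of NNAA .params files (optional).
#' @param workdir scratch directory for intermediate files.
#' @return list with `commands` (character vector), `resfile` (lines),
#'   `resfile_path`, `output_pdb`.
#' @export
rosetta_commands <- function(state, mut, config = sampling_config(),
                             fixbb_exe = "fixbb.default.linuxgccrelease",
                             relax_exe = "relax.default.linuxgccrelease",
                             backrub_exe = "backrub.default.linuxgccrelease",
                             extra_res_path = NULL,
                             workdir = tempdir()) {
  stopifnot(inherits(state, "complex_state"), inherits(mut, "mutation"))
  resfile <- c("NATAA", "start",
               sprintf("%d %s PIKAA X[%s]", mut$position, state$peptide_chain,
                       mut$new_code))
  resfile_path <- file.path(workdir, sprintf("mut_%s.resfile", format_mutation(mut)))
  out_pdb <- file.path(workdir, sprintf("design_g%03d.pdb", state$generation + 1L))
  extra <- if (is.null(extra_res_path)) ""
           else sprintf(" -extra_res_path %s", extra_res_path)
  commands <- c(
    sprintf("%s -s %s -resfile %s -nstruct 1 -out:path:all %s%s",
            fixbb_exe, state$structure, resfile_path, workdir, extra),
    sprintf("%s -s %s -relax:fast%s -nstruct 1 -out:path:all %s%s",
            relax_exe, out_pdb,
            if (config$relax_flexible_sidechains) " -relax:chi_move true" else "",
            workdir, extra),
    sprintf("%s -s %s -backrub:ntrials %d -backrub:mc_kt %s -nstruct 1 -out:path:all %s%s",
            backrub_exe, out_pdb, config$backrub_trials,
            format(config$kT), workdir, extra))
  list(commands = commands, resfile = resfile, resfile_path = resfile_path,
       output_pdb = out_pdb)
}
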