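# shared fixture builders (everything is generated in code at test time)

nat_codes <- function() natural_amino_acids()$code

start_9mer <- function() parse_sequence("PTSYAGDDS")

synthetic_state <- function(seq = start_9mer())
  prepare("synthetic", "B", sequence = seq)

flat_landscape <- function(length = 9, alphabet = nat_codes()) {
  E <- matrix(0, length, base::length(alphabet),
              dimnames = list(NULL, alphabet))
  planted_landscape(E)
}

fixture_pdb <- function()
  system.file("extdata", "granzymeH_complex_synthetic.pdb", package = "pepmc")

accepted_log_fixture <- function()
  read_mutation_log(system.file("extdata", "granzymeH_design_accepted.tsv",
                                package = "pepmc"))

# minimal valid monomer table rows for load_library tests
monomer_row <- function(code, smiles, mw = NA, natural = FALSE) {
  data.frame(code = code, one_letter = NA, smiles = smiles,
             molecular_weight = mw, is_natural = natural, chirality = "L",
             logp = NA, net_charge_ph7 = NA, isoelectric_point = NA,
             hydrophobicity_group = NA, charge_group = NA, size_group = NA,
             stringsAsFactors = FALSE)
}
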