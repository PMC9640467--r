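# The 20 natural alpha-amino acids.
#
# SMILES follow the package input convention: written N-to-C, starting at the
# backbone nitrogen, ending with the carboxylic acid as "C(=O)O".  Molecular
# weights are average masses of the free monomer in Daltons.

.naturals <- data.frame(
  code = c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL"),
  one_letter = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"),
  smiles = c(
    "N[C@@H](C)C(=O)O",
    "N[C@@H](CCCNC(=N)N)C(=O)O",
    "N[C@@H](CC(N)=O)C(=O)O",
    "N[C@@H](CC(=O)O)C(=O)O",
    "N[C@@H](CS)C(=O)O",
    "N[C@@H](CCC(N)=O)C(=O)O",
    "N[C@@H](CCC(=O)O)C(=O)O",
    "NCC(=O)O",
    "N[C@@H](Cc1c[nH]cn1)C(=O)O",
    "N[C@@H]([C@@H](C)CC)C(=O)O",
    "N[C@@H](CC(C)C)C(=O)O",
    "N[C@@H](CCCCN)C(=O)O",
    "N[C@@H](CCSC)C(=O)O",
    "N[C@@H](Cc1ccccc1)C(=O)O",
    "N1CCC[C@H]1C(=O)O",
    "N[C@@H](CO)C(=O)O",
    "N[C@@H]([C@H](O)C)C(=O)O",
    "N[C@@H](Cc1c[nH]c2ccccc12)C(=O)O",
    "N[C@@H](Cc1ccc(O)cc1)C(=O)O",
    "N[C@@H](C(C)C)C(=O)O"),
  molecular_weight = c(89.09, 174.20, 132.12, 133.10, 121.16, 146.15, 147.13,
                       75.07, 155.15, 131.17, 131.17, 146.19, 149.21, 165.19,
                       115.13, 105.09, 119.12, 204.23, 181.19, 117.15),
  stringsAsFactors = FALSE
)

#' Table of the 20 natural amino acids
#'
#' @return data.frame with columns `code` (3-letter), `one_letter`, `smiles`
#'   (free monomer, N-to-C convention) and `molecular_weight` (Da, average).
#' @export
natural_amino_acids <- function() .naturals

# fast lookups
.nat_one_to_three <- stats::setNames(.naturals$code, .naturals$one_letter)
.nat_three_to_one <- stats::setNames(.naturals$one_letter, .naturals$code)

#' Normalize a monomer code token
#'
#' Strips all whitespace and uppercases (the typography of published tables
#' inserts spaces inside 3-letter PDB codes, e.g. "41 H" == "41H").  A single
#' letter is expanded to the natural amino acid's 3-letter code.
#'
#' @param token character vector of code tokens.
#' @return normalized 3-letter-style codes.
#' @export
normalize_code <- function(token) {
  x <- toupper(gsub("[[:space:]]+", "", token))
  if (any(!nzchar(x))) pd_error("empty monomer code", "pepmc_parse_error")
  one <- nchar(x) == 1L
  x[one] <- ifelse(x[one] %in% names(.nat_one_to_three),
                   .nat_one_to_three[x[one]], x[one])
  if (any(grepl("[^A-Z0-9]", x)))
    pd_error(sprintf("monomer code not alphanumeric: %s",
                     paste(x[grepl("[^A-Z0-9]", x)], collapse = ", ")),
             "pepmc_parse_error")
  unname(x)
}

is_natural_code <- function(code) code %in% .naturals$code
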