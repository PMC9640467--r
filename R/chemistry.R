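# Physico-chemical property computation for monomers, via OpenBabel
# (ChemmineR/ChemmineOB) plus a Henderson-Hasselbalch ionization model.
#
# Input convention for monomer SMILES: the free amino acid written N-to-C,
# starting at the backbone nitrogen and ending with the carboxylic acid as
# "C(=O)O" (or "C(O)=O").  All 20 naturals and the bundled NNAAs follow it;
# under this convention N-acetyl / C-methylamide capping and glycine-flanked
# tripeptide assembly are exact, verifiable string operations.

.acid_tail_re <- "(C\\(=O\\)O|C\\(O\\)=O)$"

.parse_smiles <- function(smiles) {
  out <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL)
  if (is.null(out) || length(out) == 0)
    pd_error(sprintf("SMILES does not parse: '%s'", smiles),
             "pepmc_chemistry_error", smiles = smiles)
  out
}

.smarts_count <- function(sdf, smarts) {
  as.integer(suppressWarnings(
    ChemmineR::smartsSearchOB(sdf, smarts, uniqueMatches = TRUE)))
}

# Side-chain ionizable groups, detected on the CAPPED residue (the backbone
# amine and acid are amides there and match nothing).  pKa values are the
# standard textbook side-chain constants.
.ionizable_groups <- data.frame(
  group  = c("carboxyl", "amine", "guanidinium", "imidazole", "phenol", "thiol"),
  smarts = c("[CX3](=O)[OX2H1]",
             "[NX3;H2,H1;!$(NC=O);!$(NC=N);!$(N=C);!$(nc)]",
             "[NX3][CX3](=[NX2])[NX3]",
             "c1c[nH]cn1",
             "[c][OX2H1]",
             "[SX2H1]"),
  type = c("acid", "base", "base", "base", "acid", "acid"),
  pka  = c(4.0, 10.5, 12.5, 6.0, 10.0, 8.3),
  stringsAsFactors = FALSE
)

# backbone groups of the FREE monomer, used only for the isoelectric point
.backbone_pka <- data.frame(
  type = c("acid", "base"), pka = c(2.3, 9.0), stringsAsFactors = FALSE)

#' Check a SMILES for an alpha-amino-acid backbone
#'
#' @param smiles free-monomer SMILES.
#' @return logical.
#' @export
has_alpha_backbone <- function(smiles) {
  sdf <- .parse_smiles(smiles)
  .smarts_count(sdf, "[NX3][CX4][CX3](=O)[OX2H1]") > 0
}

#' Cap a free amino acid with acetyl and methylamide
#'
#' Builds the N-acetyl / C-methylamide form used for property calculation, so
#' that only side-chain groups remain ionizable and logP reflects the residue
#' in a peptide context.
#'
#' @param smiles free-monomer SMILES in the N-to-C convention.
#' @return capped SMILES.
#' @export
cap_residue_smiles <- function(smiles) {
  smiles <- trimws(smiles)
  if (!grepl("^N", smiles) || !grepl(.acid_tail_re, smiles))
    pd_error(sprintf(
      "SMILES not in N-to-C amino-acid convention (must start at the backbone N and end with the carboxylic acid): '%s'",
      smiles), "pepmc_chemistry_error", smiles = smiles)
  if (!has_alpha_backbone(smiles))
    pd_error(sprintf("no alpha-amino-acid backbone found in '%s'", smiles),
             "pepmc_chemistry_error", smiles = smiles)
  capped <- paste0("CC(=O)", sub(.acid_tail_re, "C(=O)NC", smiles))
  .parse_smiles(capped)  # must remain chemically valid
  capped
}

.hh_net_charge <- function(ph, pkas) {
  pos <- sum(1 / (1 + 10^(ph - pkas$pka[pkas$type == "base"])))
  neg <- sum(1 / (1 + 10^(pkas$pka[pkas$type == "acid"] - ph)))
  pos - neg
}

.detect_side_groups <- function(capped_sdf) {
  counts <- vapply(.ionizable_groups$smarts,
                   function(p) .smarts_count(capped_sdf, p), integer(1))
  idx <- rep(seq_len(nrow(.ionizable_groups)), counts)
  .ionizable_groups[idx, c("group", "type", "pka"), drop = FALSE]
}

#' Compute monomer properties from SMILES
#'
#' logP and formal net charge at pH 7 are computed on the acetyl/methylamide
#' capped residue; molecular weight on the free monomer (the quantity the
#' design-alphabet mass filter uses).  The isoelectric point is computed from
#' the free monomer's ionizable inventory (backbone alpha-amine and
#' alpha-carboxyl plus side-chain groups) since a capped residue without an
#' ionizable side chain has no defined pI.  Charge model: Henderson-
#' Hasselbalch over SMARTS-detected groups with standard pKa values.
#'
#' @param smiles free-monomer SMILES in the N-to-C convention.
#' @return list with `logp`, `net_charge_ph7`, `isoelectric_point`,
#'   `molecular_weight` and `formula`.
#' @export
compute_properties <- function(smiles) {
  free_sdf <- .parse_smiles(smiles)
  capped <- cap_residue_smiles(smiles)
  capped_sdf <- .parse_smiles(capped)
  props_capped <- suppressWarnings(ChemmineR::propOB(capped_sdf))
  props_free <- suppressWarnings(ChemmineR::propOB(free_sdf))

  side <- .detect_side_groups(capped_sdf)
  net7 <- .hh_net_charge(7, side)

  full <- rbind(side[, c("type", "pka")], .backbone_pka)
  lo <- .hh_net_charge(0, full); hi <- .hh_net_charge(14, full)
  pi <- if (lo > 0 && hi < 0) {
    stats::uniroot(function(ph) .hh_net_charge(ph, full), c(0, 14),
                   tol = 1e-6)$root
  } else NA_real_

  list(logp = as.numeric(props_capped[1, "logP"]),
       net_charge_ph7 = net7,
       isoelectric_point = pi,
       molecular_weight = as.numeric(props_free[1, "MW"]),
       formula = as.character(props_free[1, "formula"]))
}

#' Build a glycine-flanked (G-X-G) tripeptide for a monomer
#'
#' Assembles Gly-X-Gly with two peptide bonds, the construct used to
#' parameterize a monomer X in a peptide context, and emits it in MDL MOL
#' (V2000) format together with a sidecar block flagging the central residue's
#' backbone atoms (N, CA, C, O) and the chain connection points, as a polymer
#' parameterizer consumes.
#'
#' @param smiles free-monomer SMILES of X in the N-to-C convention.
#' @param code monomer code used in the MOL title.
#' @return object of class `gxg_tripeptide`: list with `smiles`, `mol`
#'   (character vector of MOL lines), `flags` (sidecar lines), `formula`,
#'   `backbone` (named atom indices).
#' @export
build_gxg_tripeptide <- function(smiles, code = "X") {
  smiles <- trimws(smiles)
  if (!grepl("^N", smiles) || !grepl(.acid_tail_re, smiles) ||
      !has_alpha_backbone(smiles))
    pd_error(sprintf(
      "monomer is not backbone-compatible (needs an alpha carbon bearing both amine and acid): '%s'",
      smiles), "pepmc_chemistry_error", smiles = smiles)

  trip <- paste0("NCC(=O)", sub(.acid_tail_re, "C(=O)NCC(=O)O", smiles))
  sdf <- .parse_smiles(trip)[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n_atoms <- nrow(ab)

  # atom order follows the SMILES: Gly1 = 1..4 (N,CA,C,O); X starts at 5 with
  # its backbone N; the trailing "C(=O)NCC(=O)O" puts X's C,O at n-6,n-5 and
  # Gly3's N at n-4.  X's CA is the atom bonded to both X's N and X's C.
  x_n <- 5L; x_c <- n_atoms - 6L; x_o <- n_atoms - 5L
  nb_of <- function(i) {
    hits <- bb[bb[, 1] == i | bb[, 2] == i, 1:2, drop = FALSE]
    setdiff(unique(as.vector(hits)), i)
  }
  x_ca <- intersect(nb_of(x_n), nb_of(x_c))
  if (length(x_ca) != 1L)
    pd_error(sprintf("could not locate a unique alpha carbon for '%s'", smiles),
             "pepmc_chemistry_error", smiles = smiles)

  props <- suppressWarnings(ChemmineR::propOB(.parse_smiles(trip)))
  mol <- ChemmineR::sdf2str(sdf)
  mol <- mol[mol != "$$$$"]
  mol[1] <- sprintf("GLY-%s-GLY", code)

  flags <- c(
    sprintf("M  POLY_N_BB %d", x_n),
    sprintf("M  POLY_CA_BB %d", x_ca),
    sprintf("M  POLY_C_BB %d", x_c),
    sprintf("M  POLY_O_BB %d", x_o),
    sprintf("M  POLY_LOWER 3"),                  # carbonyl C of Gly1
    sprintf("M  POLY_UPPER %d", n_atoms - 4L))   # backbone N of Gly3

  structure(list(smiles = trip, mol = mol, flags = flags,
                 formula = as.character(props[1, "formula"]),
                 backbone = c(N = x_n, CA = x_ca, C = x_c, O = x_o)),
            class = "gxg_tripeptide")
}

#' Write a tripeptide to an MDL MOL file with its flag sidecar
#'
#' @param trip a [build_gxg_tripeptide()] result.
#' @param path output .mol path; the sidecar is written to `<path>.flags`.
#' @return invisibly, the two paths written.
#' @export
write_tripeptide <- function(trip, path) {
  stopifnot(inherits(trip, "gxg_tripeptide"))
  writeLines(trip$mol, path)
  flag_path <- paste0(path, ".flags")
  writeLines(trip$flags, flag_path)
  invisible(c(path, flag_path))
}
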