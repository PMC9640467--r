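# Monomer library: load, property-annotate, filter, classify and subset the
# alphabet of natural amino acids and NNAAs used as mutation candidates.

.lib_columns <- c("code", "one_letter", "smiles", "molecular_weight",
                  "is_natural", "chirality", "logp", "net_charge_ph7",
                  "isoelectric_point", "hydrophobicity_group", "charge_group",
                  "size_group")

.hydro_labels  <- c("hydrophobic", "polar", "charged")
.charge_labels <- c("neutral", "positive", "negative")
.size_labels   <- c("small", "medium", "large")

#' Classify a monomer on the three category axes
#'
#' Deterministic assignment from computed properties.  Charge comes from the
#' formal net charge at pH 7 (isoelectric point is a fallback when net charge
#' is missing); a non-neutral charge group forces hydrophobicity "charged",
#' otherwise the capped-residue logP cutoff separates hydrophobic from polar;
#' size is by free-monomer molecular weight.
#'
#' @param logp,net_charge_ph7,isoelectric_point,molecular_weight computed
#'   properties (see [compute_properties()]).
#' @param thresholds a [classification_thresholds()] object.
#' @return list with `hydrophobicity_group`, `charge_group`, `size_group`.
#' @export
classify <- function(logp, net_charge_ph7, isoelectric_point,
                     molecular_weight,
                     thresholds = classification_thresholds()) {
  stopifnot(inherits(thresholds, "classification_thresholds"))
  charge <- if (!is.na(net_charge_ph7)) {
    if (net_charge_ph7 >= thresholds$charge_positive_min) "positive"
    else if (net_charge_ph7 <= thresholds$charge_negative_max) "negative"
    else "neutral"
  } else if (!is.na(isoelectric_point)) {
    if (isoelectric_point >= thresholds$pi_positive_min) "positive"
    else if (isoelectric_point <= thresholds$pi_negative_max) "negative"
    else "neutral"
  } else {
    pd_error("cannot classify charge: net charge and isoelectric point both missing",
             "pepmc_config_error")
  }
  hydro <- if (charge != "neutral") "charged"
           else if (!is.na(logp) && logp >= thresholds$logp_hydrophobic_min) "hydrophobic"
           else "polar"
  if (is.na(molecular_weight))
    pd_error("cannot classify size: molecular weight missing", "pepmc_config_error")
  size <- if (molecular_weight <= thresholds$mw_small_max) "small"
          else if (molecular_weight >= thresholds$mw_large_min) "large"
          else "medium"
  list(hydrophobicity_group = hydro, charge_group = charge, size_group = size)
}

.annotate_rows <- function(df, thresholds) {
  num_cols <- c("molecular_weight", "logp", "net_charge_ph7", "isoelectric_point")
  for (cc in num_cols) df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  for (i in seq_len(nrow(df))) {
    need_prop <- any(is.na(df[i, c("molecular_weight", "logp", "net_charge_ph7")]))
    if (need_prop) {
      p <- compute_properties(df$smiles[i])
      if (is.na(df$molecular_weight[i])) df$molecular_weight[i] <- p$molecular_weight
      if (is.na(df$logp[i])) df$logp[i] <- p$logp
      if (is.na(df$net_charge_ph7[i])) df$net_charge_ph7[i] <- p$net_charge_ph7
      if (is.na(df$isoelectric_point[i])) df$isoelectric_point[i] <- p$isoelectric_point
    }
    need_class <- is.na(df$hydrophobicity_group[i]) | !nzchar(df$hydrophobicity_group[i]) |
      is.na(df$charge_group[i]) | !nzchar(df$charge_group[i]) |
      is.na(df$size_group[i]) | !nzchar(df$size_group[i])
    if (need_class) {
      g <- classify(df$logp[i], df$net_charge_ph7[i], df$isoelectric_point[i],
                    df$molecular_weight[i], thresholds)
      df$hydrophobicity_group[i] <- g$hydrophobicity_group
      df$charge_group[i] <- g$charge_group
      df$size_group[i] <- g$size_group
    }
  }
  bad <- !(df$hydrophobicity_group %in% .hydro_labels) |
         !(df$charge_group %in% .charge_labels) |
         !(df$size_group %in% .size_labels)
  if (any(bad))
    pd_error(sprintf("invalid group label(s) for monomer(s): %s",
                     paste(df$code[bad], collapse = ", ")),
             "pepmc_schema_error")
  df
}

#' Construct a monomer library
#'
#' Codes are normalized (whitespace stripped, uppercased), must be unique, and
#' the 20 natural amino acids are always present (missing naturals are filled
#' in from the built-in table).  Missing property or group cells are computed
#' from SMILES on construction.
#'
#' @param monomers data.frame with the columns listed in [load_library()].
#' @param thresholds classification thresholds for any group labels that need
#'   computing.
#' @param provenance free-text source description.
#' @return object of class `monomer_library`.
#' @export
monomer_library <- function(monomers,
                            thresholds = classification_thresholds(),
                            provenance = "in-memory") {
  df <- as.data.frame(monomers, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.lib_columns, names(df))
  if (length(missing_cols))
    pd_error(sprintf("monomer table is missing required column(s): %s",
                     paste(missing_cols, collapse = ", ")),
             "pepmc_schema_error", columns = missing_cols)
  df <- df[, .lib_columns]
  df$code <- normalize_code(df$code)
  dup <- unique(df$code[duplicated(df$code)])
  if (length(dup))
    pd_error(sprintf("duplicate monomer code(s): %s", paste(dup, collapse = ", ")),
             "pepmc_conflict_error", codes = dup)
  df$is_natural <- as.logical(df$is_natural)
  # the natural alphabet is always available
  miss_nat <- setdiff(.naturals$code, df$code)
  if (length(miss_nat)) {
    nat <- .natural_monomers()
    df <- rbind(df, nat[nat$code %in% miss_nat, ])
  }
  df <- .annotate_rows(df, thresholds)
  rownames(df) <- df$code
  structure(list(monomers = df,
                 provenance = list(source = provenance,
                                   loaded_at = format(Sys.time(), tz = "UTC"))),
            class = "monomer_library")
}

# naturals with computed properties, memoized per session
.nat_cache <- new.env(parent = emptyenv())
.natural_monomers <- function() {
  if (is.null(.nat_cache$df)) {
    df <- .naturals
    df$is_natural <- TRUE
    df$chirality <- ifelse(df$code == "GLY", NA_character_, "L")
    df$logp <- NA_real_; df$net_charge_ph7 <- NA_real_
    df$isoelectric_point <- NA_real_
    df$hydrophobicity_group <- NA_character_
    df$charge_group <- NA_character_; df$size_group <- NA_character_
    .nat_cache$df <- .annotate_rows(df[, .lib_columns], classification_thresholds())
  }
  .nat_cache$df
}

#' Load a monomer table from CSV
#'
#' Expected header: `code,one_letter,smiles,molecular_weight,is_natural,`
#' `chirality,logp,net_charge_ph7,isoelectric_point,hydrophobicity_group,`
#' `charge_group,size_group`.  Empty property cells are computed from SMILES
#' on load; duplicate codes are rejected.
#'
#' @param path CSV file.
#' @param thresholds classification thresholds used for missing group labels.
#' @return a `monomer_library`.
#' @export
load_library <- function(path, thresholds = classification_thresholds()) {
  if (!file.exists(path))
    pd_error(sprintf("monomer table not found: %s", path), "pepmc_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  monomer_library(df, thresholds = thresholds, provenance = normalizePath(path))
}

#' Write a monomer library back to CSV
#'
#' Inverse of [load_library()] up to column order and code normalization.
#'
#' @param library a `monomer_library`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "monomer_library"))
  utils::write.csv(library$monomers, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter a library by molecular weight
#'
#' Retains NNAAs with molecular weight strictly below `cutoff`; natural amino
#' acids are retained unconditionally.
#'
#' @param library a `monomer_library`.
#' @param cutoff Daltons (default 300).
#' @return filtered `monomer_library`.
#' @export
filter_by_mw <- function(library, cutoff = 300) {
  stopifnot(inherits(library, "monomer_library"), cutoff > 0)
  df <- library$monomers
  keep <- df$is_natural | df$molecular_weight < cutoff
  library$monomers <- df[keep, , drop = FALSE]
  library
}

#' Subset the design alphabet by category labels
#'
#' Returns all monomers satisfying the conjunction of the given predicates;
#' `NULL` on an axis means no restriction.  An empty result is legal but
#' raises a warning.
#'
#' @param library a `monomer_library`.
#' @param hydrophobicity,charge,size allowed labels per axis (character
#'   vectors), or `NULL`.
#' @return data.frame of matching monomers.
#' @export
subset_alphabet <- function(library, hydrophobicity = NULL, charge = NULL,
                            size = NULL) {
  stopifnot(inherits(library, "monomer_library"))
  check <- function(x, vocab, axis) {
    if (is.null(x)) return(NULL)
    bad <- setdiff(x, vocab)
    if (length(bad))
      pd_error(sprintf("unknown %s label(s): %s (allowed: %s)", axis,
                       paste(bad, collapse = ", "), paste(vocab, collapse = ", ")),
               "pepmc_config_error")
    x
  }
  hydrophobicity <- check(hydrophobicity, .hydro_labels, "hydrophobicity")
  charge <- check(charge, .charge_labels, "charge")
  size <- check(size, .size_labels, "size")
  df <- library$monomers
  keep <- rep(TRUE, nrow(df))
  if (!is.null(hydrophobicity)) keep <- keep & df$hydrophobicity_group %in% hydrophobicity
  if (!is.null(charge)) keep <- keep & df$charge_group %in% charge
  if (!is.null(size)) keep <- keep & df$size_group %in% size
  out <- df[keep, , drop = FALSE]
  if (nrow(out) == 0)
    pd_warn("alphabet subset is empty for the given predicates",
            "pepmc_empty_alphabet")
  out
}

# Bundled non-natural monomers.  ORN, MKD (2-amino-2-methyloctanoic acid) and
# 41H (alpha-methyl-phenylalanine) are real chemical-component entries; the
# remaining codes are synthetic stand-in structures (plausible side-chain-only
# modified alpha-amino acids) used for examples and tests.
.bundled_nnaas <- data.frame(
  code = c("ORN", "MKD", "41H", "54C", "G5G", "C1J", "KHB", "DAB", "AIB", "NLE"),
  smiles = c(
    "N[C@@H](CCCN)C(=O)O",
    "N[C@](C)(CCCCCC)C(=O)O",
    "N[C@](C)(Cc1ccccc1)C(=O)O",
    "N[C@@H](Cc1cn(C)c2ccccc12)C(=O)O",
    "N[C@@H](CC1CCCCC1)C(=O)O",
    "N[C@@H](Cc1ccc(OC)cc1)C(=O)O",
    "N[C@@H](Cc1cccc2ccccc12)C(=O)O",
    "N[C@@H](CCN)C(=O)O",
    "NC(C)(C)C(=O)O",
    "N[C@@H](CCCC)C(=O)O"),
  chirality = c("L", "L", "L", "L", "L", "L", "L", "L", NA, "L"),
  stringsAsFactors = FALSE
)

#' Bundled example library (20 naturals + bundled NNAAs)
#'
#' Properties and group labels are computed from SMILES on first use and
#' memoized for the session.  Several NNAA codes carry synthetic stand-in
#' structures; see the package vignette.
#'
#' @param thresholds classification thresholds.
#' @return a `monomer_library`.
#' @export
example_monomer_library <- function(thresholds = classification_thresholds()) {
  if (is.null(.nat_cache$example_lib)) {
    nn <- .bundled_nnaas
    nn$one_letter <- NA_character_
    nn$molecular_weight <- NA_real_
    nn$is_natural <- FALSE
    nn$logp <- NA_real_; nn$net_charge_ph7 <- NA_real_
    nn$isoelectric_point <- NA_real_
    nn$hydrophobicity_group <- NA_character_
    nn$charge_group <- NA_character_; nn$size_group <- NA_character_
    df <- rbind(.natural_monomers(), nn[, .lib_columns])
    .nat_cache$example_lib <- monomer_library(df, thresholds = thresholds,
                                              provenance = "pepmc built-in")
  }
  .nat_cache$example_lib
}

#' @export
print.monomer_library <- function(x, ...) {
  df <- x$monomers
  cat(sprintf("monomer_library: %d monomers (%d natural, %d NNAA)\n",
              nrow(df), sum(df$is_natural), sum(!df$is_natural)))
  cat(sprintf("source: %s\n", x$provenance$source))
  invisible(x)
}
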