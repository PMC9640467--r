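# Monomer library: loading, MW filtering, classification, alphabet subsetting.

test_that("library loads, keeps naturals, computes missing cells, round-trips", {
  lib <- example_monomer_library()
  expect_s3_class(lib, "monomer_library")
  expect_true(all(natural_amino_acids()$code %in% lib$monomers$code))
  expect_equal(nrow(lib$monomers), 30)  # 20 naturals + 10 bundled NNAAs

  # an empty NNAA section still yields the 20 naturals
  nat_only <- monomer_library(lib$monomers[lib$monomers$is_natural, ][0, ])
  expect_equal(sort(nat_only$monomers$code), sort(natural_amino_acids()$code))

  # round trip through CSV reproduces the table up to row order
  path <- tempfile(fileext = ".csv")
  write_library(lib, path)
  lib2 <- load_library(path)
  a <- lib$monomers[order(lib$monomers$code), ]
  b <- lib2$monomers[order(lib2$monomers$code), ]
  expect_equal(a$code, b$code)
  expect_equal(a$smiles, b$smiles)
  expect_equal(a$hydrophobicity_group, b$hydrophobicity_group)
  expect_equal(a$molecular_weight, b$molecular_weight, tolerance = 1e-4)
})

test_that("schema violations and duplicate codes are rejected by name", {
  lib <- example_monomer_library()
  path <- tempfile(fileext = ".csv")
  df <- lib$monomers
  utils::write.csv(df[, setdiff(names(df), "smiles")], path, row.names = FALSE)
  expect_error(load_library(path), "smiles", class = "pepmc_schema_error")

  dup <- rbind(monomer_row("ORN", "N[C@@H](CCCN)C(=O)O"),
               monomer_row("ORN", "N[C@@H](CCCN)C(=O)O"))
  expect_error(monomer_library(dup), "ORN", class = "pepmc_conflict_error")
})

test_that("codes are normalized: whitespace stripped and uppercased", {
  expect_equal(normalize_code("41 H"), "41H")
  expect_equal(normalize_code(" orn "), "ORN")
  expect_equal(normalize_code("G"), "GLY")
})

test_that("MW filter is strict for NNAAs, exempts naturals, idempotent, monotone", {
  lib <- example_monomer_library()
  big <- monomer_row("XXL", "N[C@@H](CCCCCCCCCCCCCCCCCC)C(=O)O")  # C20 monomer
  edge <- monomer_row("EDG", "N[C@@H](CCCC)C(=O)O", mw = 299.9)
  lib_big <- monomer_library(rbind(lib$monomers, big, edge))
  expect_gt(lib_big$monomers["XXL", "molecular_weight"], 300)

  f <- filter_by_mw(lib_big, 300)
  expect_false("XXL" %in% f$monomers$code)   # >= 300 excluded
  expect_true("EDG" %in% f$monomers$code)    # 299.9 retained (strict <)
  expect_true("TRP" %in% f$monomers$code)    # naturals unconditional

  expect_identical(filter_by_mw(f, 300)$monomers, f$monomers)  # idempotent
  lower <- filter_by_mw(lib_big, 150)
  expect_true(all(lower$monomers$code %in% f$monomers$code))   # monotone
  # naturals survive any positive cutoff
  expect_true(all(natural_amino_acids()$code %in%
                  filter_by_mw(lib_big, 1)$monomers$code))
})

test_that("classification is total, deterministic, and matches known chemistry", {
  lib <- example_monomer_library()
  m <- lib$monomers
  expect_true(all(m$hydrophobicity_group %in% c("hydrophobic", "polar", "charged")))
  expect_true(all(m$charge_group %in% c("neutral", "positive", "negative")))
  expect_true(all(m$size_group %in% c("small", "medium", "large")))

  expect_equal(m["LEU", "hydrophobicity_group"], "hydrophobic")
  expect_equal(m["LEU", "charge_group"], "neutral")
  expect_equal(m["GLY", "size_group"], "small")
  expect_equal(m["ARG", "charge_group"], "positive")
  expect_equal(m["ASP", "charge_group"], "negative")
  # charged hydrophobicity group implies non-neutral charge group
  charged <- m[m$hydrophobicity_group == "charged", ]
  expect_true(all(charged$charge_group != "neutral"))
})

test_that("alphabet subsetting honors the conjunction of predicates", {
  lib <- example_monomer_library()
  sub <- subset_alphabet(lib, hydrophobicity = "hydrophobic",
                         charge = "neutral", size = "medium")
  expect_true(nrow(sub) > 0)
  expect_true(all(sub$hydrophobicity_group == "hydrophobic"))
  expect_true(all(sub$charge_group == "neutral"))
  expect_true(all(sub$size_group == "medium"))
  # subset is always contained in the library
  expect_true(all(sub$code %in% lib$monomers$code))

  # no restriction = identity
  expect_equal(nrow(subset_alphabet(lib)), nrow(lib$monomers))
  # disjoint labels on one axis -> empty, with a warning
  expect_warning(
    out <- subset_alphabet(lib, charge = character(0)),
    class = "pepmc_empty_alphabet")
  expect_equal(nrow(out), 0)
  # unknown label -> config error
  expect_error(subset_alphabet(lib, size = "tiny"), class = "pepmc_config_error")

  # subsetting commutes with MW filtering
  a <- subset_alphabet(filter_by_mw(lib, 150), size = "small")
  b <- subset_alphabet(lib, size = "small")
  b <- b[b$is_natural | b$molecular_weight < 150, ]
  expect_equal(sort(a$code), sort(b$code))
})
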