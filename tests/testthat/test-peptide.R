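# Peptide notation, mutations, replay, and seeded proposals.

test_that("bracketed notation parses and formats as an exact round trip", {
  s <- parse_sequence("PTSYAGDDS")
  expect_length(s, 9)
  expect_equal(format_sequence(s), "PTSYAGDDS")

  mixed <- parse_sequence("P[MKD]SYA[41 H]D[54 C]S")
  expect_length(mixed, 9)
  expect_equal(unclass(mixed)[c(2, 6, 8)], c("MKD", "41H", "54C"))
  expect_equal(format_sequence(mixed), "P[MKD]SYA[41H]D[54C]S")

  # round trip on every accepted-log sequence string
  for (txt in accepted_log_fixture()$sequence)
    expect_equal(format_sequence(parse_sequence(txt)),
                 format_sequence(parse_sequence(format_sequence(parse_sequence(txt)))))

  expect_equal(format_sequence(parse_sequence("[MKD]")), "[MKD]")
  expect_error(parse_sequence("A["), class = "pepmc_parse_error")
  expect_error(parse_sequence("AG]C"), class = "pepmc_parse_error")
  expect_error(parse_sequence("AXZ"), class = "pepmc_unknown_residue_error")
  expect_error(parse_sequence("AG1"), class = "pepmc_parse_error")
  expect_error(parse_sequence(""), class = "pepmc_parse_error")
})

test_that("mutations apply at 1-based positions and stale mutations are caught", {
  s <- parse_sequence("PTSYAGDDS")
  m <- parse_mutation("G-6-[ORN]")
  s2 <- apply_mutation(s, m)
  expect_equal(format_sequence(s2), "PTSYA[ORN]DDS")
  expect_equal(format_sequence(s), "PTSYAGDDS")  # input untouched

  # whitespace inside bracket tokens is insignificant
  s3 <- apply_mutation(s2, parse_mutation("[ORN]-6-[41 H]"))
  expect_equal(format_sequence(s3), "PTSYA[41H]DDS")

  # a mutation is undone by its reverse
  back <- mutation("41H", 6, "ORN")
  expect_equal(format_sequence(apply_mutation(s3, back)), format_sequence(s2))

  # identity mutation is a no-op
  expect_equal(format_sequence(apply_mutation(s, mutation("P", 1, "P"))),
               format_sequence(s))

  # old-code mismatch -> stale error; replay reports the failing step
  expect_error(apply_mutation(s, mutation("A", 6, "ORN")),
               class = "pepmc_stale_mutation_error")
  err <- tryCatch(replay_mutations(s, c("G-6-[ORN]", "G-6-[DAB]")),
                  pepmc_stale_mutation_error = function(e) e)
  expect_equal(err$step, 2)
})

test_that("replaying a log folds mutations in order; prefixes compose", {
  log <- accepted_log_fixture()
  s <- parse_sequence("PTSYAGDDS")
  fin <- replay_mutations(s, log$mutation)
  expect_equal(format_sequence(fin), "P[MKD]SYA[41H]D[54C]S")
  expect_equal(format_sequence(replay_mutations(s, character(0))),
               "PTSYAGDDS")
  # associativity: replay(prefix) then replay(suffix) == replay(all)
  k <- 4
  part <- replay_mutations(replay_mutations(s, log$mutation[1:k]),
                           log$mutation[(k + 1):nrow(log)])
  expect_equal(format_sequence(part), format_sequence(fin))
  # intermediate sequences in the log match the replayed chain
  run <- s
  for (i in seq_len(nrow(log))) {
    run <- apply_mutation(run, parse_mutation(log$mutation[i]))
    expect_equal(format_sequence(run),
                 format_sequence(parse_sequence(log$sequence[i])))
  }
})

test_that("proposals stay inside mutable positions and sample them uniformly", {
  s <- parse_sequence("PTSYAGDDS")
  alpha <- nat_codes()
  st <- rng_streams(2024, 1)[[1]]
  n <- 10000
  pos <- integer(n)
  for (i in seq_len(n)) {
    m <- with_stream(st, propose_mutation(s, c(2, 4, 6, 8), alpha))
    pos[i] <- m$position
    if (i <= 50) {  # structural checks on a sample
      expect_true(m$position %in% c(2, 4, 6, 8))
      expect_false(m$new_code == unclass(s)[m$position])  # no identity by default
      expect_equal(m$old_code, unclass(s)[m$position])
    }
  }
  freq <- table(factor(pos, levels = c(2, 4, 6, 8))) / n
  tol <- 3 * sqrt(0.25 * 0.75 / n)  # 3 sigma binomial
  expect_true(all(abs(freq - 0.25) < tol))
})

test_that("degenerate proposal cases behave as specified", {
  s <- parse_sequence("GG")
  # alphabet of size 1 differing from current -> that code with certainty
  m <- propose_mutation(s, 1, "ORN")
  expect_equal(m$new_code, "ORN")
  # only the current residue allowed everywhere -> exhausted alphabet
  expect_error(propose_mutation(s, c(1, 2), "GLY"),
               class = "pepmc_exhausted_alphabet_error")
  # unless identity proposals are explicitly allowed
  m2 <- propose_mutation(s, c(1, 2), "GLY", allow_identity = TRUE)
  expect_equal(m2$new_code, "GLY")
})
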