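# The design loop: chain validity, determinism, budget accounting,
# trajectories, greedy behavior on a noiseless landscape.

run_fixture_design <- function(seed = 3, attempts = 60, noise_sd = 0.25,
                               n_required = 4, rescore_reference = FALSE) {
  ls <- generate_landscape(9, nat_codes(), gap = 1, seed = 11)
  en <- make_ensemble(ls, 6, noise_sd, seed = 1)
  cfg <- design_config(c(2, 4, 6, 8), nat_codes(),
                       acceptance = list(mode = "consensus",
                                         n_required = n_required),
                       attempts = attempts, seed = seed,
                       rescore_reference = rescore_reference)
  list(result = run_design(synthetic_state(), cfg, en), landscape = ls,
       config = cfg, ensemble = en)
}

test_that("a run produces exactly `attempts` records and a valid accepted chain", {
  out <- run_fixture_design(attempts = 80)
  res <- out$result
  expect_equal(nrow(res$records), 80)
  expect_equal(sum(res$records$accepted) + sum(!res$records$accepted), 80)
  # chain invariant: replay of accepted mutations reproduces final_sequence
  expect_equal(format_sequence(replay_mutations(res$start_sequence,
                                                res$accepted$mutation)),
               format_sequence(res$final_sequence))
  # each accepted sequence equals the previous accepted one with one change
  prev <- res$start_sequence
  for (i in seq_len(nrow(res$accepted))) {
    cur <- parse_sequence(res$accepted$sequence[i])
    expect_equal(sum(unclass(cur) != unclass(prev)), 1)
    prev <- cur
  }
  # mutations never touch immutable positions
  pos <- vapply(lapply(res$records$mutation, parse_mutation), `[[`, 1L, "position")
  expect_true(all(pos %in% c(2, 4, 6, 8)))
})

test_that("identical config and seed give byte-identical run artifacts", {
  d1 <- tempfile(); d2 <- tempfile()
  write_design_run(run_fixture_design(seed = 42)$result, d1)
  write_design_run(run_fixture_design(seed = 42)$result, d2)
  for (f in c("records.tsv", "accepted.tsv", "trajectory.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # and a different seed gives a different trajectory
  d3 <- tempfile()
  write_design_run(run_fixture_design(seed = 43)$result, d3)
  expect_false(identical(readLines(file.path(d1, "records.tsv")),
                         readLines(file.path(d3, "records.tsv"))))
})

test_that("noiseless greedy acceptance yields strictly decreasing true energies", {
  ls <- generate_landscape(9, nat_codes(), gap = 1, seed = 17)
  en <- make_ensemble(ls, 1, 0, seed = 1)
  cfg <- design_config(c(2, 4, 6, 8), nat_codes(),
                       acceptance = list(mode = "consensus", n_required = 1),
                       attempts = 150, seed = 5)
  res <- run_design(synthetic_state(), cfg, en)
  energies <- c(landscape_energy(ls, res$start_sequence),
                vapply(res$accepted$sequence,
                       function(s) landscape_energy(ls, parse_sequence(s)),
                       numeric(1)))
  expect_true(all(diff(energies) < 0))
})

test_that("Metropolis mode runs with a single scorer and warms up with temperature", {
  ls <- generate_landscape(9, nat_codes(), gap = 1, seed = 23)
  en1 <- make_ensemble(ls, 1, 0, seed = 1)
  run_t <- function(temp, seed = 9) {
    cfg <- design_config(c(2, 4, 6, 8), nat_codes(),
                         acceptance = list(mode = "metropolis",
                                           temperature = temp),
                         attempts = 200, seed = seed)
    run_design(synthetic_state(), cfg, en1)
  }
  cold <- suppressWarnings(run_t(1e-9))  # below the usual 1..10 range
  # in the greedy limit with exact scores, accepted energies strictly improve
  e <- vapply(cold$accepted$sequence,
              function(s) landscape_energy(ls, parse_sequence(s)), numeric(1))
  expect_true(all(diff(c(landscape_energy(ls, cold$start_sequence), e)) < 0))
  # a hot chain accepts more moves than a cold one (same proposals)
  hot <- suppressWarnings(run_t(100))
  expect_gt(nrow(hot$accepted), nrow(cold$accepted))
  # multiple scorers without naming one is a config error
  en6 <- make_ensemble(ls, 6, 0, seed = 1)
  cfg_bad <- design_config(c(2, 4, 6, 8), nat_codes(),
                           acceptance = list(mode = "metropolis", temperature = 1),
                           attempts = 10, seed = 1)
  expect_error(run_design(synthetic_state(), cfg_bad, en6),
               class = "pepmc_config_error")
})

test_that("accepted-sequence table and score trajectory have the published layout", {
  out <- run_fixture_design(attempts = 100, seed = 8)
  res <- out$result
  tab <- summarize_accepted(res)
  expect_named(tab, c("step", "mutation", "sequence"))
  expect_equal(nrow(tab), nrow(res$accepted))
  # every mutation string round-trips
  for (ms in tab$mutation) expect_silent(parse_mutation(ms))

  tr <- score_trajectory(res)
  k <- nrow(res$accepted)
  expect_equal(nrow(tr), 6 * (k + 1))  # start + each accepted, per scorer
  expect_true(all(tr$step[tr$point == 0] == 0))

  # zero acceptances -> series of length 1
  ls <- out$landscape
  en <- make_ensemble(ls, 6, 0, seed = 1)
  cfg <- design_config(4, "TYR", attempts = 2, seed = 1,
                       allow_identity = TRUE)  # TYR is already at position 4
  res0 <- run_design(synthetic_state(), cfg, en)
  expect_equal(nrow(res0$accepted), 0)
  expect_equal(nrow(score_trajectory(res0)), 6)
  expect_equal(nrow(summarize_accepted(res0)), 0)
})

test_that("candidate pool ranks accepted sequences by consensus strength", {
  res <- run_fixture_design(attempts = 120, seed = 13)$result
  pool <- res$candidate_pool
  expect_equal(sort(pool$step), sort(res$accepted$step))
  expect_true(all(diff(pool$n_favorable) <= 0))
})
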