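# Benchmark ranking: per-pair sign agreement and dataset threshold summaries.

make_pair <- function(strong, weak, aff = c(1, 1000)) {
  benchmark_pair("cplxA", "cplxB", aff[1], aff[2],
                 score_vector(strong), score_vector(weak))
}

test_that("pair matches count strict oriented agreement; ties never match", {
  sc <- stats::setNames(rep(0, 6), paste0("s", 1:6))
  all_better <- make_pair(sc - 1, sc)
  expect_equal(pair_matches(all_better)$matches, 6)

  tied <- sc; tied["s1"] <- 0
  weak <- sc; weak[2:6] <- 1
  pr <- pair_matches(make_pair(tied, weak))
  expect_equal(pr$matches, 5)            # the tied scorer does not match
  expect_false(pr$per_scorer[["s1"]])

  # scale invariance: any epsilon improvement matches on every scorer
  eps_pair <- make_pair(sc - 1e-9, sc)
  expect_equal(pair_matches(eps_pair)$matches, 6)

  # monotone transform invariance (applied per scorer to both sides)
  a <- c(s1 = -8, s2 = 2, s3 = 0.5); b <- c(s1 = -7, s2 = 1, s3 = 3)
  before <- pair_matches(make_pair(a, b))$matches
  after <- pair_matches(make_pair(exp(a / 4), exp(b / 4)))$matches
  expect_equal(before, after)

  expect_error(benchmark_pair("x", "y", 1, 1000,
                              score_vector(c(s1 = 1)),
                              score_vector(c(s2 = 1))),
               class = "pepmc_data_error")
  expect_error(benchmark_pair("x", "y", 1000, 1,
                              score_vector(sc), score_vector(sc)),
               class = "pepmc_data_error")
})

test_that("dataset summaries count pairs at a threshold and are non-increasing", {
  counts1 <- c(5, 3, 3, 5, 5, 4)
  counts2 <- c(4, 1, 4, 3, 4, 4, 3, 5, 4)
  expect_equal(dataset_summary(counts1, 4), 4)
  expect_equal(dataset_summary(counts2, 4), 6)
  expect_equal(dataset_summary(counts1, 7), 0)  # above the scorer count
  passes <- vapply(1:6, function(t) dataset_summary(counts1, t), numeric(1))
  expect_true(all(diff(passes) <= 0))
  expect_error(dataset_summary(counts1, 0), class = "pepmc_config_error")
})

test_that("the bundled published match counts reproduce the dataset summaries", {
  pub <- published_match_counts()
  expect_equal(nrow(pub), 15)
  expect_true(all(pub$affinity_strong_nM < pub$affinity_weak_nM))
  expect_equal(dataset_summary(pub$matches[pub$dataset == 1], 4), 4)
  expect_equal(dataset_summary(pub$matches[pub$dataset == 2], 4), 6)
})

test_that("scorer error rate counts wrong-or-tied orderings", {
  sc <- stats::setNames(rep(0, 3), c("good", "anti", "mixed"))
  pairs <- lapply(1:15, function(k) {
    strong <- c(good = -1, anti = 1, mixed = if (k <= 9) 1 else -1)
    benchmark_pair(paste0("a", k), paste0("b", k), 1, 1000,
                   score_vector(strong), score_vector(sc))
  })
  expect_equal(scorer_error_rate(pairs, "good"), 0.0)
  expect_equal(scorer_error_rate(pairs, "anti"), 1.0)
  expect_equal(scorer_error_rate(pairs, "mixed"), 9 / 15)  # 60% incorrect
  expect_error(scorer_error_rate(pairs, "absent"), class = "pepmc_data_error")

  # consistency: per-pair matches equals the sum over scorers of correctness
  for (p in pairs[c(1, 12)]) {
    pr <- pair_matches(p)
    expect_equal(pr$matches, sum(pr$per_scorer))
  }
})

test_that("long-format pairs files round-trip with orientation applied at load", {
  # nnscore raw scores are higher-is-better; the loader negates them
  df <- rbind(
    data.frame(pair_id = "p1", complex_id = "strong1", affinity_nM = 1,
               role = "strong", scorer = c("vina", "nnscore"),
               score = c(-9, 8)),
    data.frame(pair_id = "p1", complex_id = "weak1", affinity_nM = 500,
               role = "weak", scorer = c("vina", "nnscore"),
               score = c(-7, 3)))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  pairs <- read_benchmark_pairs(path)
  expect_length(pairs, 1)
  p <- pairs[[1]]
  expect_equal(p$scores_strong[["nnscore"]], -8)  # negated
  expect_equal(pair_matches(p)$matches, 2)        # both rank correctly
})
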