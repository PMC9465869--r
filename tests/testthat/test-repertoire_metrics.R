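test_that("downsampling hits the target depth exactly and never inflates a clone", {
  set.seed(3)
  counts <- setNames(sample(1:200, 50, replace = TRUE),
                     clonotrace:::make_cdr3(50))
  rep <- make_rep(counts)
  for (seed in 1:5) {
    target <- sample(seq_len(rep$depth), 1)
    ds <- downsample(rep, target, seed)
    expect_equal(ds$depth, target)
    cc <- clonotrace:::clone_counts(rep)[ds$clones$cdr3_aa]
    expect_true(all(ds$clones$count <= cc))
    expect_true(all(ds$clones$count >= 1))
  }
})

test_that("downsampling to full depth is the identity and is deterministic in the seed", {
  rep <- make_rep(c(CASSA = 7, CASSK = 3, CASSC = 1))
  expect_identical(downsample(rep, rep$depth, 1), rep)
  a <- downsample(rep, 5, 99)
  b <- downsample(rep, 5, 99)
  expect_identical(a$clones, b$clones)
  expect_error(downsample(rep, rep$depth + 1, 1), "exceeds")
  expect_error(downsample(rep, 0, 1), "positive integer")
})

test_that("drawing one read from {A:1, B:1} picks each clone half the time", {
  rep <- make_rep(c(CASSA = 1, CASSK = 1))
  hits <- vapply(1:10000, function(s)
    downsample(rep, 1, s)$clones$cdr3_aa == "CASSA", logical(1))
  # binomial 3-sigma band around 0.5 at n = 10000
  expect_lt(abs(mean(hits) - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("downsampled clone counts match the hypergeometric expectation", {
  rep <- make_rep(c(CASSA = 9000, CASSK = 1000))
  n_rep <- 1000
  a_counts <- vapply(seq_len(n_rep), function(s) {
    cc <- clonotrace:::clone_counts(downsample(rep, 1000, s))
    if ("CASSA" %in% names(cc)) as.numeric(cc[["CASSA"]]) else 0
  }, numeric(1))
  mu <- 1000 * 9000 / 10000                       # 900
  v <- 1000 * 0.9 * 0.1 * (10000 - 1000) / 9999   # hypergeometric variance
  expect_lt(abs(mean(a_counts) - mu), 3 * sqrt(v / n_rep))
})

test_that("common_depth returns the minimum depth of the set", {
  reps <- list(make_rep(c(CASSA = 5000)), make_rep(c(CASSK = 12000)),
               make_rep(c(CASSC = 7000)))
  expect_equal(common_depth(reps), 5000)
  expect_equal(common_depth(reps[1]), 5000)
  expect_true(all(vapply(reps, `[[`, numeric(1), "depth") >=
                    common_depth(reps)))
  expect_error(common_depth(list()), "empty")
})

test_that("clonality spans 0 (even repertoire) to 1 (monoclonal)", {
  even <- make_rep(setNames(rep(4, 100), clonotrace:::make_cdr3(100)))
  expect_equal(clonality(even), 0)
  expect_equal(clonality(make_rep(c(CASSA = 50))), 1)
  expect_error(clonality(repertoire(data.frame(cdr3_aa = character(),
                                               count = integer()))),
               "empty")
})

test_that("Shannon entropy and clonality match hand-computed values for {3, 1}", {
  rep <- make_rep(c(CASSA = 3, CASSK = 1))
  h <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  expect_equal(shannon_entropy(rep), h, tolerance = 1e-12)
  expect_equal(clonality(rep), 1 - h / log(2), tolerance = 1e-12)
  expect_equal(shannon_entropy(rep), 0.5623, tolerance = 1e-4)
  expect_equal(clonality(rep), 0.1887, tolerance = 1e-3)
})

test_that("clonality is invariant to clone relabeling and uniform count scaling", {
  counts <- c(CASSA = 12, CASSK = 5, CASSC = 2, CASSD = 1)
  base <- clonality(make_rep(counts))
  relabeled <- clonality(make_rep(setNames(counts,
                                           c("CASSM", "CASSN", "CASSP",
                                             "CASSQ"))))
  scaled <- clonality(make_rep(counts * 7))
  expect_equal(relabeled, base, tolerance = 1e-12)
  expect_equal(scaled, base, tolerance = 1e-12)
  expect_gte(base, 0)
  expect_lte(base, 1)
})

test_that("diversity reports richness, entropy, clonality and the depth used", {
  singletons <- make_rep(setNames(rep(1, 100), clonotrace:::make_cdr3(100)))
  d <- diversity(singletons)
  expect_equal(d$richness, 100)
  expect_equal(d$clonality, 0)
  expect_lte(d$shannon_entropy, log(d$richness) + 1e-12)
  mono <- diversity(make_rep(c(CASSA = 50)))
  expect_equal(mono$richness, 1)
  expect_equal(mono$shannon_entropy, 0)
  expect_equal(mono$depth_used, 50)
})

test_that("overlap partitions the union of clone keys", {
  a <- make_rep(c(CASSA = 1, CASSK = 2, CASSC = 3))
  b <- make_rep(c(CASSK = 1, CASSC = 2, CASSD = 3))
  ov <- overlap(a, b)
  expect_equal(ov$shared, c("CASSC", "CASSK"))
  expect_equal(ov$unique_a, "CASSA")
  expect_equal(ov$unique_b, "CASSD")
  self <- overlap(a, a)
  expect_equal(self$n_shared, 3)
  expect_equal(self$n_unique_a + self$n_unique_b, 0)
  disjoint <- overlap(a, make_rep(c(CASSW = 1)))
  expect_equal(disjoint$n_shared, 0)
})

test_that("repertoire fraction follows the summed-count formula and sums to 1 over a partition", {
  rep <- make_rep(c(CASSA = 250, CASSK = 750))
  expect_equal(repertoire_fraction("CASSA", rep), 0.25)
  expect_equal(repertoire_fraction(c("CASSA", "CASSK"), rep), 1)
  expect_equal(repertoire_fraction("CASSW", rep), 0)
  # partition of all keys sums to 1
  big <- make_rep(setNames(sample(1:50, 30, replace = TRUE),
                           clonotrace:::make_cdr3(30)))
  keys <- big$clones$cdr3_aa
  parts <- split(keys, rep(1:3, length.out = length(keys)))
  expect_equal(sum(vapply(parts, repertoire_fraction, numeric(1),
                          rep = big)), 1, tolerance = 1e-12)
})
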