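test_that("recognition probability follows the partition-function form", {
  expect_equal(recognition_probability(scores = numeric(0)), 0)  # empty pool
  expect_equal(recognition_probability(scores = 26), 0.5)        # score at a
  expect_equal(recognition_probability(scores = 27), exp(1) / (1 + exp(1)))
  # direct sum check against the closed form for a small pool
  sc <- c(20, 25, 30)
  S <- sum(exp(-(26 - sc)))
  expect_equal(recognition_probability(scores = sc), S / (1 + S))
  # numerically stable at huge scores, bounded strictly below 1
  r_big <- recognition_probability(scores = c(5000, 4000))
  expect_true(is.finite(r_big) && r_big < 1)
})

test_that("R is bounded and monotone in pool composition", {
  set.seed(21)
  for (i in 1:50) {
    sc <- stats::runif(sample(1:20, 1), 0, 60)
    r <- recognition_probability(scores = sc)
    expect_true(r >= 0 && r < 1)
    # raising one score never lowers R
    j <- sample(length(sc), 1)
    sc2 <- sc; sc2[j] <- sc2[j] + stats::runif(1, 0, 10)
    expect_gte(recognition_probability(scores = sc2), r)
    # adding a pool entry never lowers R
    expect_gte(recognition_probability(scores = c(sc, stats::runif(1, 0, 60))), r)
  }
  # R -> 1 as a score grows without bound
  expect_gt(recognition_probability(scores = 200), 1 - 1e-10)
})

test_that("R from peptides ties alignment and model together", {
  # a pool holding the query itself scores |s,s| = 36 for 9xA -> near 1
  r_self <- recognition_probability("AAAAAAAAA", pool = "AAAAAAAAA")
  expect_equal(r_self, exp(10) / (1 + exp(10)))
})

test_that("identity lookup requires a verbatim full-length match", {
  pool <- c("SIINFEKL", "KLVVVGAGG")
  expect_true(identity_lookup("SIINFEKL", pool))
  expect_true(identity_lookup("siinfekl", pool))  # case-normalized
  expect_false(identity_lookup("SIINFEKM", pool))
  expect_false(identity_lookup("SIINFEK", pool))
  expect_equal(identity_lookup(c("SIINFEKL", "AAAA"), pool), c(TRUE, FALSE))
})

test_that("pool hygiene folds case, strips, drops and deduplicates", {
  raw <- c(" siinfekl ", "SIINFEKL", "KLVVXGAGG", "", NA, "klvvvgagg")
  expect_warning(clean <- clean_epitope_pool(raw), "non-canonical")
  expect_setequal(clean, c("SIINFEKL", "KLVVVGAGG"))
})

test_that("pair score maps positive-call counts to the published grid", {
  expect_equal(pair_score(c(TRUE, TRUE, TRUE)), 1)
  expect_equal(pair_score(c(TRUE, TRUE, FALSE)), 0.75)
  expect_equal(pair_score(c(TRUE, FALSE, FALSE)), 0.25)
  expect_equal(pair_score(c(FALSE, FALSE, FALSE)), 0)
  m <- rbind(c(1, 1, 1), c(0, 1, 0), c(0, 0, 0))
  expect_equal(pair_score(m), c(1, 0.25, 0))
  expect_error(pair_score(c(TRUE, TRUE)), "three")
  expect_error(pair_score(c(1, 2, 0)), "binary")
})

test_that("TIS aggregates pair scores under both readings", {
  expect_equal(tis(c(1, 1, 0, 0)), 0.5)
  expect_equal(tis(c(1, 0.75, 0.75, 1)), 1)
  expect_equal(tis(c(0.25, 0, 0.25)), 0)
  expect_equal(tis(c(1, 0.75, 0.25, 0), method = "mean"), 0.5)
  expect_error(tis(numeric(0)), "empty")
  expect_error(tis(c(0.3, 0.6)), "pair_score")
})
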