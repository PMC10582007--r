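test_that("NPS combines gates, ratio, recognition and TAP as defined", {
  expect_equal(nps_class1(1, 1, 20, 0.5, 4), 2.5)
  expect_equal(nps_class1(0, 1, 20, 0.5, 4), 0)   # expression gate
  expect_equal(nps_class1(1, 0, 20, 0.5, 4), 0)   # proteasome gate
  expect_equal(nps_class2(1, 8, 0.25), 2)
  expect_equal(nps_class2(0, 8, 0.25), 0)
  expect_equal(nps_class2(1, 1, 0), 0)            # empty-pool R
  # the TIC guard keeps the minimum-TBS core finite
  expect_equal(nps_class1(1, 1, 10, 0.5, 0), 10 * 0.5 / 1e-6)
})

test_that("NPS is monotone in its continuous inputs", {
  base <- nps_class1(1, 1, 10, 0.5, 3)
  expect_gt(nps_class1(1, 1, 11, 0.5, 3), base)
  expect_gt(nps_class1(1, 1, 10, 0.6, 3), base)
  expect_lt(nps_class1(1, 1, 10, 0.5, 4), base)
  expect_gt(nps_class2(1, 9, 0.25), nps_class2(1, 8, 0.25))
})

test_that("ranking is by descending NPS with deterministic tie-breaks", {
  sc <- data.frame(NPS = c(3, 1, 2), A = 1, ic50_mut = 1,
                   core_mut = c("AAA", "CCC", "DDD"))
  r <- rank_candidates(sc)
  expect_equal(r$core_mut, c("AAA", "DDD", "CCC"))
  expect_equal(r$rank, 1:3)
  # all-equal NPS: falls through to lexicographic peptide order
  tie <- data.frame(NPS = 1, A = 1, ic50_mut = 1,
                    core_mut = c("GGG", "AAA", "CCC"))
  expect_equal(rank_candidates(tie)$core_mut, c("AAA", "CCC", "GGG"))
  # gated-out candidates rank after every positive-NPS candidate
  mix <- data.frame(NPS = c(0, 2, 0, 1), A = c(9, 1, 1, 1), ic50_mut = 1,
                    core_mut = c("AAA", "CCC", "DDD", "EEE"))
  rm <- rank_candidates(mix)
  expect_equal(rm$core_mut[1:2], c("CCC", "EEE"))
  expect_true(all(rm$NPS[1:2] > 0) && all(rm$NPS[3:4] == 0))
  # top_k slicing
  out <- rank_candidates(mix, top_k = 2)
  expect_equal(nrow(out$top), 2)
  expect_equal(nrow(out$ranked), 4)
})
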