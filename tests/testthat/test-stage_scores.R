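test_that("FPKM->TPM is proportional and conserves one million", {
  expect_equal(fpkm_to_tpm(c(g1 = 5, g2 = 5)), c(g1 = 5e5, g2 = 5e5))
  expect_equal(fpkm_to_tpm(c(g1 = 1, g2 = 3)), c(g1 = 2.5e5, g2 = 7.5e5))
  expect_error(fpkm_to_tpm(c(g1 = 0, g2 = 0)), "zero")
  set.seed(7)
  for (i in 1:20) {
    fpkm <- stats::rexp(sample(2:200, 1), rate = 1 / 50)
    expect_equal(sum(fpkm_to_tpm(fpkm)), 1e6, tolerance = 1e-9)
  }
})

test_that("expression and hydrolysis gates use strict thresholds", {
  expect_equal(tpm_score(c(0, 3, 3.1, 100)), c(0L, 0L, 1L, 1L))
  expect_equal(hydrolysis_score(0.8, 0.1), 1L)
  expect_equal(hydrolysis_score(0.7, 0.7), 0L)
  expect_equal(hydrolysis_score(0.69, 0.71), 1L)
  expect_error(hydrolysis_score(1.2, 0.5), "\\[0, 1\\]")
  # gates are idempotent and monotone
  x <- seq(0, 20, by = 0.5)
  ts <- tpm_score(x)
  expect_equal(tpm_score(ts * 10), ts)  # re-gating scaled output is stable
  expect_true(all(diff(ts) >= 0))
  ph <- hydrolysis_score(seq(0, 1, 0.05), 0)
  expect_true(all(diff(ph) >= 0))
})

test_that("TAP transform shifts log IC50 to a non-negative score", {
  tt <- tap_transform(c(1e2, 1e3, 1e5))
  expect_equal(tt$TBS, c(2, 3, 5))
  expect_equal(tt$TIC, c(4, 5, 7))
  expect_equal(attr(tt, "TBS_min"), 2)
  expect_equal(tap_transform(10^4.20)$TBS, 4.20)
  tt2 <- tap_transform(c(1e-1, 1e2))
  expect_equal(tt2$TIC, c(0, 3))
  expect_error(tap_transform(c(10, -1)), "positive")
  # order preservation: ranking by TBS equals ranking by TIC
  set.seed(11)
  ic <- exp(stats::runif(50, 0, 11))
  tt3 <- tap_transform(ic)
  expect_equal(order(tt3$TBS), order(tt3$TIC))
  expect_true(all(tt3$TIC >= 0))
  expect_equal(which.min(tt3$TBS), which.min(tt3$TIC))
})

test_that("core boundary cleavage reads N' before the start and C' at the end", {
  probs <- seq(0.1, 1, by = 0.1)  # residue i has probability i/10
  bc <- core_cleavage_probs(probs, offsets = c(1L, 2L), core_len = 9L)
  expect_equal(bc$n_prime, c(1, 0.1))  # free N-terminus needs no upstream cut
  expect_equal(bc$c_prime, c(0.9, 1.0))
})

test_that("surrogate backends are deterministic and respect their contracts", {
  b <- surrogate_backend("mhc1", seed = 5, alleles = c("H2-Db", "H2-Kb"))
  peps <- replicate(12, random_peptide(9, c("A", "C", "D", "E", "G", "K")))
  r1 <- surrogate_predict(b, peps)
  r2 <- surrogate_predict(b, peps)
  expect_identical(r1, r2)
  # a different seed changes at least one record in any decent batch
  b2 <- surrogate_backend("mhc1", seed = 6, alleles = c("H2-Db", "H2-Kb"))
  expect_true(any(surrogate_predict(b2, peps)$ic50_nM != r1$ic50_nM))
  expect_true(all(r1$ic50_nM >= 1 & r1$ic50_nM <= 5e4))
  expect_error(surrogate_predict(b, "ACDEACDE"), "9-mers")
  expect_error(surrogate_predict(b, peps, alleles = "HLA-A02"), "not listed")
  # cleavage surrogates emit one probability per residue, in [0,1]
  cb <- surrogate_backend("cleavage", seed = 5)
  cr <- surrogate_predict(cb, c("ACDEFGHIK", "ACD"))
  expect_equal(nrow(cr), 12)
  expect_true(all(cr$probability >= 0 & cr$probability <= 1))
})
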