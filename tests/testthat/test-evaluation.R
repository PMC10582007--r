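test_that("RCS matches the hand-evaluated example and is antisymmetric", {
  expect_equal(rank_coverage_score(c(1, 2), c(3, 4), 4), 0.6875)
  expect_equal(rank_coverage_score(c(3, 4), c(1, 2), 4), -0.6875)
  expect_error(rank_coverage_score(integer(0), c(1), 4), "at least one")
  expect_error(rank_coverage_score(c(1), c(9), 4), "1..T")
  # best case tends to 1 as the list grows
  expect_gt(rank_coverage_score(1, 10000, 10000), 0.999)
})

test_that("RCS stays inside [-1, 1] over random rank/label configurations", {
  set.seed(5)
  for (i in 1:300) {
    T_total <- sample(4:400, 1)
    n_lab <- sample(2:min(T_total, 40), 1)
    ranks <- sample(T_total, n_lab)
    pos <- sample(n_lab, sample(seq_len(n_lab - 1), 1))
    rcs <- rank_coverage_score(ranks[pos], ranks[-pos], T_total)
    expect_true(rcs >= -1 && rcs <= 1)
  }
})

test_that("ranking score is rank over list size, 1 when undetected", {
  expect_equal(ranking_score(1, 100), 0.01)
  expect_equal(ranking_score(NA, 100), 1)
  expect_equal(ranking_score(100, 100), 1)
  expect_error(ranking_score(101, 100), "1..T")
  # positives beat negatives in RS on a separated ranking
  rs_p <- ranking_score(1:10, 100)
  rs_n <- ranking_score(91:100, 100)
  expect_lt(mean(rs_p), mean(rs_n))
})

test_that("confusion metrics reproduce the published benchmark arithmetic", {
  m <- confusion_metrics(TP = 20, FN = 14, TN = 57, FP = 23)
  expect_equal(round(m$sensitivity, 4), 0.5882)    # 20 of 34 positives
  expect_equal(round(m$specificity, 4), 0.7125)
  expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2)
  perfect <- confusion_metrics(TP = 10, FN = 0, TN = 10, FP = 0)
  expect_equal(perfect$balanced_accuracy, 1)
  expect_error(confusion_metrics(TP = 0, FN = 0, TN = 5, FP = 5), "classes")
  # BA is prevalence-invariant: scaling one class leaves it unchanged
  a <- confusion_metrics(TP = 8, FN = 2, TN = 30, FP = 10)
  b <- confusion_metrics(TP = 80, FN = 20, TN = 30, FP = 10)
  expect_equal(a$balanced_accuracy, b$balanced_accuracy)
})

test_that("AUC equals brute-force pair counting, with tie correction", {
  expect_equal(auc_and_cutoff(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(auc_and_cutoff(c(0.9, 0.3, 0.8), c(1, 1, 0))$auc, 0.5)
  expect_equal(auc_and_cutoff(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  expect_error(auc_and_cutoff(1:4, c(1, 1, 1, 1)), "both classes")
  set.seed(9)
  for (i in 1:30) {
    n <- sample(5:50, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # forces ties
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    expect_equal(auc_and_cutoff(scores, labels)$auc, bf_auc(scores, labels))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(13)
  scores <- c(stats::rnorm(40, 1), stats::rnorm(60, 0))
  labels <- rep(c(1, 0), c(40, 60))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc_and_cutoff(scores, labels)$auc, ref)
})

test_that("the chosen cutoff maximizes balanced accuracy", {
  scores <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.2)
  labels <- c(1, 1, 0, 1, 0, 0)
  out <- auc_and_cutoff(scores, labels)
  bas <- vapply(sort(unique(scores)), function(thr) {
    sen <- sum(scores >= thr & labels == 1) / 3
    spe <- sum(scores < thr & labels == 0) / 3
    (sen + spe) / 2
  }, numeric(1))
  expect_equal(out$balanced_accuracy, max(bas))
})

test_that("ranked lists evaluate end-to-end against labels", {
  ranked <- data.frame(peptide = sprintf("PEP%02d", 1:20), rank = 1:20,
                       score = 21 - (1:20))
  labels <- data.frame(peptide = c("PEP01", "PEP02", "PEP18", "PEP19", "GHOST"),
                       label = c("positive", "positive", "negative", "negative",
                                 "negative"))
  ev <- evaluate_ranking(ranked, labels)
  expect_equal(ev$T_total, 20)
  expect_equal(ev$rs$RS, c(0.05, 0.10, 0.90, 0.95, 1))  # ghost undetected -> 1
  expect_gt(ev$rcs, 0)
  expect_equal(ev$auc, 1)
  # duplicated peptides take their first (best) rank
  dup <- rbind(ranked, data.frame(peptide = "PEP01", rank = 21, score = -1))
  ev2 <- evaluate_ranking(dup, labels)
  expect_equal(ev2$rs$rank[1], 1)
  expect_error(evaluate_ranking(ranked,
                                data.frame(peptide = c("PEP01", "PEP01"),
                                           label = c("positive", "negative"))),
               "unique")
})
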