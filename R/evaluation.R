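#' Rank coverage score (RCS)
#'
#' A signed summary of how well a prediction list separates validated
#' positives (should rank high, i.e. small rank numbers) from validated
#' negatives (should rank low). With list size T,
#'
#'   RCS = sum(rank_n) / (T * num(n)) * coverage(n)
#'       - sum(rank_p) / (T * num(p)) * coverage(p),
#'   coverage(k) = max(rank_k) / T,
#'
#' so RCS lies in (-1, 1), larger is better.
#'
#' @param ranks_p Integer ranks of the validated positive peptides.
#' @param ranks_n Integer ranks of the validated negative peptides.
#' @param T_total Total list size T (>= max rank).
#' @return RCS value.
#' @examples
#' rank_coverage_score(c(1, 2), c(3, 4), 4)  # 0.6875
#' @export
rank_coverage_score <- function(ranks_p, ranks_n, T_total) {
  if (length(ranks_p) == 0 || length(ranks_n) == 0)
    stop("RCS needs at least one positive and one negative", call. = FALSE)
  ranks <- c(ranks_p, ranks_n)
  if (any(ranks < 1) || any(ranks > T_total))
    stop("ranks must lie in 1..T_total", call. = FALSE)
  cov_n <- max(ranks_n) / T_total
  cov_p <- max(ranks_p) / T_total
  sum(ranks_n) / (T_total * length(ranks_n)) * cov_n -
    sum(ranks_p) / (T_total * length(ranks_p)) * cov_p
}

#' Ranking score (RS)
#'
#' A peptide's rank divided by the list size: small for peptides a tool
#' ranks near the top, 1 for the bottom of the list, and 1 by convention
#' for peptides the tool did not detect at all.
#'
#' @param rank Integer rank(s); `NA` means undetected.
#' @param T_total Total list size (>= 1).
#' @return RS in (0, 1\].
#' @export
ranking_score <- function(rank, T_total) {
  stopifnot(T_total >= 1)
  if (any(!is.na(rank) & (rank < 1 | rank > T_total)))
    stop("ranks must lie in 1..T_total", call. = FALSE)
  ifelse(is.na(rank), 1, rank / T_total)
}

#' Sensitivity, specificity and balanced accuracy
#'
#' @param TP,TN,FP,FN Confusion counts (TP+FN >= 1 and TN+FP >= 1).
#' @return Named list with `sensitivity`, `specificity`,
#'   `balanced_accuracy`.
#' @examples
#' confusion_metrics(TP = 20, FN = 14, TN = 57, FP = 23)
#' @export
confusion_metrics <- function(TP, TN, FP, FN) {
  counts <- c(TP, TN, FP, FN)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  if (TP + FN < 1 || TN + FP < 1)
    stop("both classes must be represented", call. = FALSE)
  sen <- TP / (TP + FN)
  spe <- TN / (TN + FP)
  list(sensitivity = sen, specificity = spe,
       balanced_accuracy = (sen + spe) / 2)
}

#' AUC and balanced-accuracy-maximizing cutoff
#'
#' AUC is the Mann-Whitney rank estimator with tie correction: the
#' probability that a random positive scores above a random negative,
#' ties counting one half. The cutoff is the score threshold (classifier:
#' score >= cutoff is called positive) that maximizes balanced accuracy;
#' ties go to the smaller threshold.
#'
#' @param scores Numeric prediction scores (larger = more positive).
#' @param labels Logical or 0/1 vector of validated labels.
#' @return List with `auc`, `cutoff`, `balanced_accuracy`,
#'   `sensitivity`, `specificity` at the cutoff.
#' @export
auc_and_cutoff <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !any(is.na(scores)), !any(is.na(labels)))
  n_p <- sum(labels); n_n <- sum(!labels)
  if (n_p == 0 || n_n == 0)
    stop("both classes must be present for AUC", call. = FALSE)
  r <- rank(scores)  # midranks handle ties
  auc <- (sum(r[labels]) - n_p * (n_p + 1) / 2) / (n_p * n_n)

  best <- list(ba = -Inf, cutoff = NA_real_, sen = NA_real_, spe = NA_real_)
  for (thr in sort(unique(scores))) {
    pred <- scores >= thr
    sen <- sum(pred & labels) / n_p
    spe <- sum(!pred & !labels) / n_n
    ba <- (sen + spe) / 2
    if (ba > best$ba) best <- list(ba = ba, cutoff = thr, sen = sen, spe = spe)
  }
  list(auc = auc, cutoff = best$cutoff, balanced_accuracy = best$ba,
       sensitivity = best$sen, specificity = best$spe)
}

#' Evaluate a ranked prediction list against validation labels
#'
#' Matches labelled peptides into a ranked list by exact identity after
#' case-folding (duplicated peptides take their first, i.e. best, rank),
#' then computes RCS, per-peptide RS, AUC and the balanced-accuracy
#' cutoff. Labelled peptides missing from the list are treated as
#' undetected: RS = 1 and rank = T for RCS so both metrics share one
#' convention.
#'
#' @param ranked Data.frame with columns `peptide` and `rank` (and
#'   optionally `score`; defaults to `-rank`).
#' @param labels Data.frame with columns `peptide` and `label`
#'   (`"positive"`/`"negative"`, or logical/0-1).
#' @return List with `rcs`, `rs` (data.frame peptide/label/rank/RS),
#'   `auc`, `cutoff`, `balanced_accuracy`, `sensitivity`, `specificity`,
#'   `T_total`.
#' @export
evaluate_ranking <- function(ranked, labels) {
  stopifnot(all(c("peptide", "rank") %in% names(ranked)),
            all(c("peptide", "label") %in% names(labels)))
  T_total <- max(ranked$rank)
  key <- toupper(trimws(ranked$peptide))
  lab_pep <- toupper(trimws(labels$peptide))
  if (anyDuplicated(lab_pep)) stop("labelled peptides must be unique", call. = FALSE)
  pos <- if (is.character(labels$label)) tolower(labels$label) == "positive"
         else as.logical(labels$label)

  # first (= best) rank per labelled peptide; NA if undetected
  idx <- match(lab_pep, key)
  rk <- ranked$rank[idx]
  rs <- ranking_score(rk, T_total)
  rk_rcs <- ifelse(is.na(rk), T_total, rk)  # undetected ranked worst

  rcs <- rank_coverage_score(rk_rcs[pos], rk_rcs[!pos], T_total)
  score <- if ("score" %in% names(ranked)) ranked$score[idx] else -rk
  score[is.na(score)] <- min(score, na.rm = TRUE) - 1  # undetected below all
  roc <- auc_and_cutoff(score, pos)

  list(rcs = rcs,
       rs = data.frame(peptide = labels$peptide,
                       label = ifelse(pos, "positive", "negative"),
                       rank = rk, RS = rs, stringsAsFactors = FALSE),
       auc = roc$auc, cutoff = roc$cutoff,
       balanced_accuracy = roc$balanced_accuracy,
       sensitivity = roc$sensitivity, specificity = roc$specificity,
       T_total = T_total)
}
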