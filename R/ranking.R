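#' Neoantigen probability score, class I
#'
#' NPS = TS * PHS * A * R / TIC: the expression and proteasome gates
#' multiply the binding fold-change and recognition probability, divided
#' by the TAP score so poorly transported cores are penalized. When
#' TIC falls below the guard `epsilon` (the sample's minimum-TBS core has
#' TIC = 0 by construction) the divisor is clamped to `epsilon`; callers
#' flag clamped rows.
#'
#' @param TS Expression score, 0 or 1.
#' @param PHS Hydrolysis score, 0 or 1.
#' @param A Affinity ratio (> 0).
#' @param R Recognition probability in \[0, 1).
#' @param TIC Shifted TAP score (>= 0).
#' @param epsilon Divisor guard, default 1e-6.
#' @return Numeric NPS (vectorized).
#' @examples
#' nps_class1(1, 1, 20, 0.5, 4)   # 2.5
#' @export
nps_class1 <- function(TS, PHS, A, R, TIC, epsilon = 1e-6) {
  stopifnot(all(TS %in% c(0, 1)), all(PHS %in% c(0, 1)),
            all(A > 0), all(R >= 0 & R < 1), all(TIC >= 0))
  TS * PHS * A * R / pmax(TIC, epsilon)
}

#' Neoantigen probability score, class II
#'
#' NPS = TS * A * R: the class II pathway has no proteasome or TAP stage,
#' so only the expression gate, affinity ratio and recognition
#' probability enter.
#'
#' @inheritParams nps_class1
#' @return Numeric NPS (vectorized).
#' @examples
#' nps_class2(1, 8, 0.25)  # 2
#' @export
nps_class2 <- function(TS, A, R) {
  stopifnot(all(TS %in% c(0, 1)), all(A > 0), all(R >= 0 & R < 1))
  TS * A * R
}

#' Rank candidates by NPS
#'
#' Sorts a candidate table by descending NPS with a deterministic tie
#' rule — higher A, then lower mutant IC50, then lexicographic mutant
#' peptide — so reruns are byte-identical. Gated-out candidates
#' (NPS = 0) stay in the table, ranked after every positive-NPS
#' candidate, because rank-based evaluation needs every peptide ranked.
#'
#' @param scores Data.frame with at least columns `NPS`, `A`,
#'   `ic50_mut`, `core_mut`.
#' @param top_k Optional size of the head slice to return alongside the
#'   full ranking.
#' @return `scores` reordered with a `rank` column prepended; when
#'   `top_k` is given, a list with elements `ranked` and `top`.
#' @export
rank_candidates <- function(scores, top_k = NULL) {
  stopifnot(nrow(scores) >= 1,
            all(c("NPS", "A", "ic50_mut", "core_mut") %in% names(scores)))
  ord <- order(-scores$NPS, -scores$A, scores$ic50_mut, scores$core_mut)
  ranked <- scores[ord, , drop = FALSE]
  ranked <- cbind(rank = seq_len(nrow(ranked)), ranked)
  rownames(ranked) <- NULL
  if (is.null(top_k)) return(ranked)
  list(ranked = ranked, top = utils::head(ranked, top_k))
}
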