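#' Clean an epitope pool
#'
#' Pool hygiene before scoring: case-fold, strip whitespace, drop
#' entries with non-canonical residues (warned), deduplicate.
#'
#' @param pool Character vector of epitope peptides.
#' @return Cleaned character vector.
#' @export
clean_epitope_pool <- function(pool) {
  pool <- toupper(trimws(pool))
  pool <- pool[!is.na(pool) & nchar(pool) > 0]
  ok <- is_canonical_peptide(pool)
  if (any(!ok))
    warning(sprintf("dropped %d pool entries with non-canonical residues", sum(!ok)))
  unique(pool[ok])
}

#' TCR-recognition probability R
#'
#' The probability that a presented peptide is recognized by the T-cell
#' repertoire, modelled from its similarity to experimentally validated
#' epitopes. With alignment scores `|s,e|` against each pool entry e,
#'
#'   R = Z(k)^-1 * sum_e exp(-k (a - |s,e|)),
#'   Z(k) = 1 + sum_e exp(-k (a - |s,e|)),
#'
#' i.e. R = S / (1 + S) with S the summed similarity weight: a logistic
#' saturation in which a single pool entry at score `a` gives R = 0.5 and
#' stronger or additional matches push R towards (never onto) 1. The
#' defaults a = 26, k = 1 are calibrated for raw BLOSUM62 local-alignment
#' scores. Computed via log-sum-exp so large scores cannot overflow.
#'
#' @param s Query peptide, or `NULL` if `scores` is supplied directly.
#' @param pool Cleaned epitope pool (character vector; may be empty).
#' @param a Horizontal displacement, default 26.
#' @param k Slope at `a`, default 1 (> 0).
#' @param scores Optional precomputed alignment scores (bypasses `s` and
#'   `pool`).
#' @return R in \[0, 1).
#' @examples
#' recognition_probability(scores = 26)           # 0.5
#' recognition_probability(scores = numeric(0))   # empty pool: 0
#' @export
recognition_probability <- function(s = NULL, pool = character(0), a = 26, k = 1,
                                    scores = NULL) {
  stopifnot(is.finite(a), is.finite(k), k > 0)
  if (is.null(scores)) scores <- pool_align_scores(s, pool)
  if (length(scores) == 0) return(0)
  x <- -k * (a - scores)
  mx <- max(x)
  logS <- mx + log(sum(exp(x - mx)))
  # R = S/(1+S) = logistic(log S); clamp to the largest double below 1 so the
  # strict upper bound survives floating-point saturation at huge scores
  min(stats::plogis(logS), 1 - .Machine$double.eps / 2)
}

#' Exact-identity lookup in the epitope pool
#'
#' 100% sequence identity search: a query counts as previously validated
#' only when it matches a pool entry verbatim over its full length
#' (case-normalized).
#'
#' @param s Character vector of query peptides.
#' @param pool Epitope pool (character vector).
#' @return Logical vector, one per query.
#' @export
identity_lookup <- function(s, pool) {
  toupper(trimws(s)) %in% toupper(trimws(pool))
}

#' Three-predictor pair score for a peptide-CDR3 pair
#'
#' Aggregates the binary positive/negative calls of three independent
#' peptide-TCR binding predictors into one score: 1 when all three call
#' positive, 0.75 for two, 0.25 for one, 0 for none.
#'
#' @param calls Logical vector of length 3 (or a 3-column logical/0-1
#'   matrix, one row per pair).
#' @return Numeric score(s) in \{0, 0.25, 0.75, 1\}.
#' @export
pair_score <- function(calls) {
  map <- c(`0` = 0, `1` = 0.25, `2` = 0.75, `3` = 1)
  if (is.matrix(calls) || is.data.frame(calls)) {
    calls <- as.matrix(calls)
    if (ncol(calls) != 3) stop("pair_score needs exactly three calls", call. = FALSE)
    if (any(is.na(calls)) || !all(calls %in% c(0, 1, TRUE, FALSE)))
      stop("calls must be binary", call. = FALSE)
    return(unname(map[as.character(rowSums(calls != 0))]))
  }
  if (length(calls) != 3) stop("pair_score needs exactly three calls", call. = FALSE)
  if (any(is.na(calls)) || !all(calls %in% c(0, 1, TRUE, FALSE)))
    stop("calls must be binary", call. = FALSE)
  unname(map[as.character(sum(calls != 0))])
}

#' T-cell interaction score (TIS)
#'
#' Summarizes a peptide's pair scores across a CDR3 panel. The default
#' reading is the fraction of CDR3 sequences whose pair score reaches
#' the threshold (default 0.75, i.e. at least two of three predictors
#' positive); `method = "mean"` instead averages the pair scores. The
#' published definition is ambiguous between the two, so the choice is
#' explicit rather than silent.
#'
#' @param pair_scores Numeric vector of per-CDR3 pair scores (>= 1
#'   value, each in \{0, 0.25, 0.75, 1\}).
#' @param threshold Pair-score threshold for a positive CDR3, default
#'   0.75.
#' @param method `"fraction"` (default) or `"mean"`.
#' @return TIS in \[0, 1\].
#' @export
tis <- function(pair_scores, threshold = 0.75, method = c("fraction", "mean")) {
  method <- match.arg(method)
  if (length(pair_scores) == 0) stop("empty CDR3 set", call. = FALSE)
  if (!all(pair_scores %in% c(0, 0.25, 0.75, 1)))
    stop("pair scores must come from pair_score()", call. = FALSE)
  if (method == "fraction") mean(pair_scores >= threshold) else mean(pair_scores)
}
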