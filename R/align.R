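# cached BLOSUM62 from Biostrings' shipped data
.align_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.align_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .align_cache$BLOSUM62 <- e$BLOSUM62
  }
  .align_cache$BLOSUM62
}

#' Smith-Waterman local alignment score
#'
#' Exact optimal local alignment score under an affine gap model: a gap
#' of length L costs `gap_open + L * gap_ext` (so the first gapped
#' residue costs 11 + 1 = 12 at the defaults, the common BLASTp
#' accounting). Scored with BLOSUM62 by default and returned as the raw
#' score, the scale on which the recognition-model displacement `a` is
#' calibrated. Dynamic programming (Gotoh) — deterministic, and never
#' below what a heuristic search would find.
#'
#' @param s,e Peptides (canonical residues only).
#' @param gap_open Gap opening penalty (positive), default 11.
#' @param gap_ext Per-residue gap extension penalty (positive), default 1.
#' @param submat Substitution matrix; default BLOSUM62 from Biostrings.
#' @return The optimal local alignment score (>= 0).
#' @examples
#' local_align_score("KLVVVGAGG", "KLVVVGAGG")  # 43
#' @export
local_align_score <- function(s, e, gap_open = 11, gap_ext = 1, submat = blosum62()) {
  a <- strsplit(toupper(s), "")[[1]]
  b <- strsplit(toupper(e), "")[[1]]
  if (length(a) == 0 || length(b) == 0)
    stop("peptides must be non-empty", call. = FALSE)
  bad <- setdiff(unique(c(a, b)), AA_CANONICAL)
  if (length(bad) > 0)
    stop(sprintf("non-canonical residues in alignment input: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  sub <- submat[a, b, drop = FALSE]
  n <- length(a); m <- length(b)
  first_gap <- gap_open + gap_ext
  NEG <- -1e9
  Hprev <- numeric(m + 1)             # H[i-1, ]
  Fprev <- rep(NEG, m + 1)            # F[i-1, ]
  best <- 0
  for (i in seq_len(n)) {
    Hrow <- numeric(m + 1)
    Frow <- numeric(m + 1)
    Ecur <- NEG
    for (j in seq_len(m)) {
      Ecur <- max(Hrow[j] - first_gap, Ecur - gap_ext)           # gap in s
      Frow[j + 1] <- max(Hprev[j + 1] - first_gap, Fprev[j + 1] - gap_ext)  # gap in e
      h <- max(0, Hprev[j] + sub[i, j], Ecur, Frow[j + 1])
      Hrow[j + 1] <- h
      if (h > best) best <- h
    }
    Hprev <- Hrow
    Fprev <- Frow
  }
  best
}

#' Alignment scores of one peptide against an epitope pool
#'
#' @param s Query peptide.
#' @param pool Character vector of pool peptides (see
#'   [clean_epitope_pool()]).
#' @inheritParams local_align_score
#' @return Numeric vector of local alignment scores, one per pool entry.
#' @export
pool_align_scores <- function(s, pool, gap_open = 11, gap_ext = 1,
                              submat = blosum62()) {
  if (length(pool) == 0) return(numeric(0))
  vapply(pool, function(e) local_align_score(s, e, gap_open, gap_ext, submat),
         numeric(1), USE.NAMES = FALSE)
}
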