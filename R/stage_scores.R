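#' Convert FPKM to TPM
#'
#' TPM_i = FPKM_i / sum(FPKM) * 1e6. The sum over all genes of a sample is
#' exactly one million, which makes the expression gate comparable across
#' samples with different library compositions.
#'
#' @param fpkm Named numeric vector of per-gene FPKM values (all >= 0, at
#'   least one positive).
#' @return Named numeric vector of TPM values summing to 1e6.
#' @examples
#' fpkm_to_tpm(c(g1 = 1, g2 = 3))
#' @export
fpkm_to_tpm <- function(fpkm) {
  if (length(fpkm) == 0) stop("empty FPKM table", call. = FALSE)
  if (any(is.na(fpkm)) || any(fpkm < 0))
    stop("FPKM values must be non-negative and non-missing", call. = FALSE)
  total <- sum(fpkm)
  if (total <= 0)
    stop("all FPKM values are zero; TPM is undefined", call. = FALSE)
  fpkm / total * 1e6
}

#' Expression score TS
#'
#' The expression gate of the presentation cascade: a candidate scores 1
#' only when the TPM of its gene strictly exceeds the threshold
#' (default 3), otherwise 0.
#'
#' @param tpm Numeric vector of TPM values (>= 0).
#' @param threshold Gate threshold, default 3.
#' @return Integer vector of 0/1 scores.
#' @export
tpm_score <- function(tpm, threshold = 3) {
  stopifnot(all(tpm >= 0))
  as.integer(tpm > threshold)
}

#' Proteasomal hydrolysis score PHS
#'
#' A core can be produced by the proteasome when a cut is likely at
#' either of its boundaries: PHS = 1 if the cleavage probability just
#' before the N-terminus or at the C-terminal residue strictly exceeds
#' the threshold (default 0.7), else 0.
#'
#' @param n_prime Probability of cleavage at the residue immediately
#'   preceding the core's N-terminus (1 for a core starting at a free
#'   N-terminus, which needs no upstream cut).
#' @param c_prime Probability of cleavage at the core's C-terminal
#'   residue.
#' @param threshold Gate threshold, default 0.7.
#' @return Integer vector of 0/1 scores.
#' @export
hydrolysis_score <- function(n_prime, c_prime, threshold = 0.7) {
  if (any(is.na(n_prime)) || any(is.na(c_prime)) ||
      any(n_prime < 0 | n_prime > 1) || any(c_prime < 0 | c_prime > 1))
    stop("cleavage probabilities must lie in [0, 1]", call. = FALSE)
  as.integer(n_prime > threshold | c_prime > threshold)
}

#' TAP binding score and its non-negative shift
#'
#' TBS = log(IC50) (base 10 by default); the transported-IC50 score
#' TIC = TBS + |TBS_min| shifts the sample so its minimum is
#' non-negative while preserving the ordering. TBS_min is taken over the
#' candidate set passed in — the mutation-containing candidate cores of
#' the current run.
#'
#' @param ic50 Positive numeric vector of TAP IC50 values in nM.
#' @param log_base Logarithm base, default 10.
#' @return A data.frame with columns `ic50`, `TBS`, `TIC`, plus an
#'   attribute `TBS_min`.
#' @examples
#' tap_transform(c(100, 1000, 1e5))
#' @export
tap_transform <- function(ic50, log_base = 10) {
  if (length(ic50) == 0) stop("empty IC50 vector", call. = FALSE)
  if (any(is.na(ic50)) || any(ic50 <= 0))
    stop("TAP IC50 values must be positive", call. = FALSE)
  tbs <- log(ic50, base = log_base)
  tbs_min <- min(tbs)
  out <- data.frame(ic50 = ic50, TBS = tbs, TIC = tbs + abs(tbs_min))
  attr(out, "TBS_min") <- tbs_min
  out
}

#' Read boundary cleavage probabilities for cores
#'
#' Given per-residue cleavage probabilities over an MCP, returns for each
#' core offset the pair (N', C') feeding [hydrolysis_score()]: N' is the
#' probability at the residue immediately before the core start (1 when
#' the core starts at the MCP N-terminus — a free terminus needs no
#' upstream cut) and C' the probability at the core's last residue.
#'
#' @param probs Numeric vector of per-residue cleavage probabilities,
#'   one per MCP residue.
#' @param offsets Integer vector of core start offsets within the MCP.
#' @param core_len Core length (9 or 15).
#' @return A data.frame with columns `offset`, `n_prime`, `c_prime`.
#' @export
core_cleavage_probs <- function(probs, offsets, core_len) {
  stopifnot(all(offsets >= 1), all(offsets + core_len - 1 <= length(probs)))
  n_prime <- ifelse(offsets == 1L, 1, probs[pmax(offsets - 1L, 1L)])
  c_prime <- probs[offsets + core_len - 1L]
  data.frame(offset = offsets, n_prime = n_prime, c_prime = c_prime)
}
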