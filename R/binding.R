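#' MHC candidacy filter
#'
#' Only mutant cores predicted to bind MHC with IC50 strictly below the
#' cutoff (default 500 nM) remain neoantigen candidates; the same rule is
#' applied to both MHC classes.
#'
#' @param aff_mut Predicted IC50 of the mutant core in nM (> 0).
#' @param cutoff_nM Candidacy cutoff, default 500.
#' @return Logical vector.
#' @export
candidacy_filter <- function(aff_mut, cutoff_nM = 500) {
  stopifnot(all(aff_mut > 0))
  aff_mut < cutoff_nM
}

#' Wild-type/mutant affinity ratio A
#'
#' A = Aff(WT) / Aff(mutant): the fold-change in MHC binding caused by
#' the mutation. A > 1 means the mutation strengthened binding (IC50
#' dropped). When the wild-type core is absent (frameshift or indel cores
#' with no positionally matched wild-type segment), Aff(WT) is set to the
#' candidacy cutoff so that A >= 1 exactly when the mutant passes the
#' filter; such ratios are flagged by the caller.
#'
#' @param aff_wt IC50 of the wild-type core in nM, or `NA` when absent.
#' @param aff_mut IC50 of the mutant core in nM (> 0).
#' @param wt_fallback_nM Substitute for an absent wild-type affinity,
#'   default 500 (the candidacy cutoff).
#' @return Numeric vector of ratios.
#' @examples
#' affinity_ratio(2000, 100)  # 20-fold gain
#' @export
affinity_ratio <- function(aff_wt, aff_mut, wt_fallback_nM = 500) {
  if (any(is.na(aff_mut)) || any(aff_mut <= 0))
    stop("mutant affinities must be positive", call. = FALSE)
  if (any(!is.na(aff_wt) & aff_wt <= 0))
    stop("wild-type affinities must be positive when present", call. = FALSE)
  aff_wt <- ifelse(is.na(aff_wt), wt_fallback_nM, aff_wt)
  aff_wt / aff_mut
}

#' Pick the best allele for a core and form its binding pair
#'
#' Presentation is dominated by the strongest binder, so the per-core
#' record used downstream is the allele with the minimum mutant IC50
#' (ties broken by allele name); the wild-type IC50 is taken for that
#' same allele. The full per-allele table is kept for the detailed
#' output.
#'
#' @param records Data.frame with one row per allele for a single core:
#'   columns `allele`, `ic50_mut`, `ic50_wt` (`NA` allowed),
#'   optionally more.
#' @param cutoff_nM Candidacy cutoff, default 500.
#' @param wt_fallback_nM Fallback for absent wild-type affinity, default
#'   the cutoff.
#' @return A one-row data.frame: `allele`, `ic50_mut`, `ic50_wt`, `A`,
#'   `passes_filter`, `wt_absent`.
#' @export
best_allele_binding <- function(records, cutoff_nM = 500, wt_fallback_nM = cutoff_nM) {
  stopifnot(nrow(records) >= 1,
            all(c("allele", "ic50_mut", "ic50_wt") %in% names(records)))
  ord <- order(records$ic50_mut, records$allele)
  best <- records[ord[1], , drop = FALSE]
  wt_absent <- is.na(best$ic50_wt)
  data.frame(allele = best$allele,
             ic50_mut = best$ic50_mut,
             ic50_wt = ifelse(wt_absent, NA_real_, best$ic50_wt),
             A = affinity_ratio(best$ic50_wt, best$ic50_mut, wt_fallback_nM),
             passes_filter = candidacy_filter(best$ic50_mut, cutoff_nM),
             wt_absent = wt_absent,
             stringsAsFactors = FALSE)
}
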