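#' Default run configuration
#'
#' Collects every tunable of the prioritization pipeline in one list:
#' gate thresholds, recognition-model constants, allele sets, input paths
#' and the random seed. A run's configuration is echoed as YAML into its
#' output directory so results are reproducible from the echo alone.
#'
#' @param tpm_threshold Expression gate: a candidate's gene must exceed this
#'   TPM for the expression score TS to be 1. Default 3.
#' @param cleavage_threshold Proteasomal cleavage gate on the per-residue
#'   cleavage probability; the hydrolysis score PHS is 1 when either the
#'   N'-flank or C-terminal probability strictly exceeds it. Default 0.7.
#' @param affinity_cutoff_nM Candidacy filter: mutant cores with predicted
#'   MHC IC50 at or above this value (nM) are dropped. Default 500.
#' @param a Horizontal displacement of the TCR-recognition curve, on the
#'   raw Smith-Waterman score scale. Default 26.
#' @param k Slope of the TCR-recognition curve at `a`. Default 1.
#' @param epsilon Lower guard for the TIC divisor in the class-I NPS;
#'   values below it are clamped and flagged. Default 1e-6.
#' @param log_base Base of the logarithm defining the TAP binding score
#'   TBS from the TAP IC50. Default 10.
#' @param alleles_mhc1,alleles_mhc2 Character vectors of allele names
#'   scored per class; defaults are the mouse H2 sets.
#' @param top_k Number of top-ranked candidates reported per class.
#'   Default 10.
#' @param seed Integer seed driving every stochastic component.
#' @param paths Named list of input file paths (proteome, variants,
#'   expression, epitope pool, predictor score tables); see
#'   [run_pipeline()] for the expected names.
#'
#' @return A list of class `neoprio_config`.
#' @seealso [run_pipeline()], [generate_fixtures()]
#' @export
neoprio_config <- function(tpm_threshold = 3,
                           cleavage_threshold = 0.7,
                           affinity_cutoff_nM = 500,
                           a = 26,
                           k = 1,
                           epsilon = 1e-6,
                           log_base = 10,
                           alleles_mhc1 = c("H2-Db", "H2-Dd", "H2-Kb", "H2-Kd", "H2-Ld"),
                           alleles_mhc2 = c("H2-IAb", "H2-IAd"),
                           top_k = 10,
                           seed = 1L,
                           paths = list()) {
  stopifnot(tpm_threshold >= 0, cleavage_threshold >= 0, cleavage_threshold <= 1,
            affinity_cutoff_nM > 0, k > 0, epsilon > 0, log_base > 1,
            length(alleles_mhc1) >= 1, length(alleles_mhc2) >= 1, top_k >= 1)
  cfg <- list(
    tpm_threshold = tpm_threshold,
    cleavage_threshold = cleavage_threshold,
    affinity_cutoff_nM = affinity_cutoff_nM,
    a = a,
    k = k,
    epsilon = epsilon,
    log_base = log_base,
    alleles_mhc1 = alleles_mhc1,
    alleles_mhc2 = alleles_mhc2,
    top_k = as.integer(top_k),
    seed = as.integer(seed),
    paths = paths
  )
  class(cfg) <- "neoprio_config"
  cfg
}

#' @export
print.neoprio_config <- function(x, ...) {
  cat("neoprio run configuration\n")
  cat(sprintf("  gates: TPM > %g, cleavage > %g, mutant IC50 < %g nM\n",
              x$tpm_threshold, x$cleavage_threshold, x$affinity_cutoff_nM))
  cat(sprintf("  recognition model: a = %g, k = %g (raw alignment score scale)\n",
              x$a, x$k))
  cat(sprintf("  TAP: log base %g, TIC guard %g\n", x$log_base, x$epsilon))
  cat(sprintf("  alleles MHC-I: %s\n", paste(x$alleles_mhc1, collapse = ", ")))
  cat(sprintf("  alleles MHC-II: %s\n", paste(x$alleles_mhc2, collapse = ", ")))
  cat(sprintf("  top_k = %d, seed = %d\n", x$top_k, x$seed))
  invisible(x)
}

#' Write / read a configuration echo
#'
#' @param config A `neoprio_config` list.
#' @param path File to write to / read from (YAML).
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `neoprio_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "neoprio_config"))
  x <- unclass(config)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(neoprio_config, x)
}

# residues accepted in input sequences; 'X' is tolerated on input but
# disqualifies a candidate core (substitution scores are undefined there)
AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

is_canonical_peptide <- function(x) {
  !is.na(x) & nchar(x) > 0 &
    vapply(strsplit(toupper(x), ""), function(ch) all(ch %in% AA_CANONICAL), logical(1))
}

validate_sequence <- function(x, what = "sequence") {
  ch <- strsplit(toupper(x), "")[[1]]
  bad <- setdiff(unique(ch), c(AA_CANONICAL, "X"))
  if (length(bad) > 0)
    stop(sprintf("%s contains non-amino-acid characters: %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  paste(ch, collapse = "")
}
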