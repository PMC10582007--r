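#' Deterministic surrogate predictor backends
#'
#' The pipeline consumes cleavage, TAP and MHC predictions through a
#' canonical table contract, so any external tool can be plugged in via
#' a small adapter. For offline runs and testing, surrogate backends
#' generate deterministic pseudo-scores from a seeded hash of
#' (peptide, allele): the same inputs and seed always give the same
#' records. Surrogate scores carry the right units and ranges
#' (probabilities for cleavage, nM IC50 for TAP/MHC) but no biology —
#' they exercise the plumbing, not the predictors.
#'
#' @param kind One of `"cleavage"`, `"tap"`, `"mhc1"`, `"mhc2"`.
#' @param seed Integer seed mixed into every hash.
#' @param alleles For MHC kinds, the allele names the backend will
#'   accept.
#' @return A list of class `surrogate_backend`.
#' @seealso [surrogate_predict()]
#' @export
surrogate_backend <- function(kind = c("cleavage", "tap", "mhc1", "mhc2"),
                              seed = 1L, alleles = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("mhc1", "mhc2") && (is.null(alleles) || length(alleles) == 0))
    stop("MHC surrogate backends need an allele list", call. = FALSE)
  structure(list(name = paste0("surrogate-", kind), kind = kind,
                 seed = as.integer(seed), alleles = alleles),
            class = "surrogate_backend")
}

# deterministic string -> [0,1) hash, independent of R's RNG state.
# Polynomial rolling hash mod the Mersenne prime 2^31-1, remixed once with
# a Lehmer step; all intermediates stay below 2^53 so doubles are exact.
hash01 <- function(x, salt = "") {
  m <- 2147483647
  vapply(paste0(salt, "\r", x), function(s) {
    h <- 17
    for (b in utf8ToInt(s)) h <- (h * 31 + b) %% m
    h <- (h * 48271 + 11) %% m
    h <- (h * 48271 + 7) %% m
    h / m
  }, numeric(1), USE.NAMES = FALSE)
}

# log-uniform IC50 in [lo, hi] nM from a unit-interval draw
lu_ic50 <- function(u, lo = 1, hi = 5e4) exp(log(lo) + u * (log(hi) - log(lo)))

#' Generate surrogate predictor records
#'
#' Maps peptide (and allele) batches to canonical score records using the
#' backend's seeded hash. Cleavage backends return one probability per
#' residue of each peptide; TAP backends one IC50 (nM, log-uniform in
#' \[1, 5e4\]) per peptide; MHC backends one IC50 per (peptide, allele)
#' pair.
#'
#' @param backend A [surrogate_backend()].
#' @param peptides Character vector of peptides (9-mers for `mhc1`,
#'   15-mers for `mhc2`; any length otherwise).
#' @param alleles For MHC kinds, allele names to score; must be listed in
#'   the backend.
#' @return A data.frame in the canonical layout for the backend kind:
#'   cleavage `(peptide_id, residue_index, probability)`; tap
#'   `(peptide, ic50_nM)`; mhc `(peptide, allele, ic50_nM)`.
#' @export
surrogate_predict <- function(backend, peptides, alleles = NULL) {
  stopifnot(inherits(backend, "surrogate_backend"))
  if (length(peptides) == 0) stop("no peptides supplied", call. = FALSE)
  bad <- !is_canonical_peptide(peptides)
  if (any(bad))
    stop(sprintf("non-canonical peptides passed to %s backend: %s", backend$kind,
                 paste(utils::head(peptides[bad], 3), collapse = ", ")), call. = FALSE)
  salt <- sprintf("%s|%d", backend$kind, backend$seed)

  if (backend$kind == "cleavage") {
    rows <- lapply(seq_along(peptides), function(i) {
      p <- peptides[i]
      idx <- seq_len(nchar(p))
      data.frame(peptide_id = p, residue_index = idx,
                 probability = hash01(paste0(p, "#", idx), salt),
                 stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }

  if (backend$kind == "tap") {
    return(data.frame(peptide = peptides,
                      ic50_nM = lu_ic50(hash01(peptides, salt)),
                      stringsAsFactors = FALSE))
  }

  # MHC backends
  need_len <- if (backend$kind == "mhc1") 9L else 15L
  if (any(nchar(peptides) != need_len))
    stop(sprintf("%s backend scores %d-mers only", backend$kind, need_len),
         call. = FALSE)
  if (is.null(alleles)) alleles <- backend$alleles
  unknown <- setdiff(alleles, backend$alleles)
  if (length(unknown) > 0)
    stop(sprintf("alleles not listed for backend %s: %s", backend$name,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  grid <- expand.grid(peptide = peptides, allele = alleles,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$ic50_nM <- lu_ic50(hash01(paste0(grid$peptide, "@", grid$allele), salt))
  grid
}
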