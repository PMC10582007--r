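#' Apply a protein-level somatic variant to a wild-type sequence
#'
#' Builds the mutant protein for the four supported variant classes.
#' A SNP substitutes one residue; an insertion inserts `alt` immediately
#' after `position`; a deletion removes the residues matching `ref`
#' starting at `position`; a frameshift keeps the wild-type prefix up to
#' `position - 1` and appends the supplied mutant tail (no CDS
#' translation is performed — the tail must come with the variant).
#'
#' @param wt_sequence Wild-type protein sequence (string, 1-based
#'   coordinates).
#' @param variant A list or one-row data.frame with fields
#'   `variant_class` (one of `"SNP"`, `"insertion"`, `"deletion"`,
#'   `"frameshift"`), `position`, `ref`, `alt`, and `mutant_tail`
#'   (frameshift only). `ref` is checked against `wt_sequence` where
#'   applicable.
#'
#' @return The mutant protein sequence (string).
#' @examples
#' build_mutant_protein("ACDEF", list(variant_class = "SNP", position = 2,
#'                                    ref = "C", alt = "W"))
#' build_mutant_protein("ACDEF", list(variant_class = "deletion",
#'                                    position = 3, ref = "DE", alt = ""))
#' @export
build_mutant_protein <- function(wt_sequence, variant) {
  mutation_context(wt_sequence, variant)$mut_sequence
}

#' Resolve a variant into its mutation context
#'
#' Like [build_mutant_protein()] but also returns the span of mutated
#' residues on the mutant protein, which downstream windowing needs.
#'
#' @inheritParams build_mutant_protein
#' @return A list of class `mutation_context` with elements
#'   `wt_sequence`, `mut_sequence`, `variant_class`, `position` (on the
#'   wild-type), `mut_start`/`mut_end` (mutated span, mutant coordinates)
#'   and `aligned_prefix` (last mutant position at which mutant and
#'   wild-type coordinates still agree).
#' @export
mutation_context <- function(wt_sequence, variant) {
  wt <- validate_sequence(wt_sequence, "wt_sequence")
  v <- as.list(variant)
  cls <- match.arg(v$variant_class, c("SNP", "insertion", "deletion", "frameshift"))
  pos <- as.integer(v$position)
  L <- nchar(wt)
  if (is.na(pos) || pos < 1L || pos > L)
    stop(sprintf("variant position %s outside protein of length %d", v$position, L),
         call. = FALSE)
  ref <- toupper(if (is.null(v$ref) || is.na(v$ref)) "" else as.character(v$ref))
  alt <- toupper(if (is.null(v$alt) || is.na(v$alt)) "" else as.character(v$alt))

  check_ref <- function(expected_len) {
    if (nchar(ref) == 0) return(invisible())
    found <- substr(wt, pos, pos + nchar(ref) - 1L)
    if (found != ref)
      stop(sprintf("ref '%s' does not match wild-type residues '%s' at position %d",
                   ref, found, pos), call. = FALSE)
  }

  if (cls == "SNP") {
    if (nchar(alt) != 1L) stop("SNP requires a single alt residue", call. = FALSE)
    check_ref(1L)
    mut <- paste0(substr(wt, 1L, pos - 1L), alt, substr(wt, pos + 1L, L))
    span <- c(pos, pos)
    aligned <- nchar(mut)  # coordinates agree everywhere for a substitution
  } else if (cls == "insertion") {
    if (nchar(alt) < 1L) stop("insertion requires a non-empty alt string", call. = FALSE)
    validate_sequence(alt, "alt")
    check_ref(1L)
    mut <- paste0(substr(wt, 1L, pos), alt, substr(wt, pos + 1L, L))
    span <- c(pos + 1L, pos + nchar(alt))
    aligned <- pos
  } else if (cls == "deletion") {
    if (nchar(ref) < 1L) stop("deletion requires the deleted residues in ref", call. = FALSE)
    if (pos + nchar(ref) - 1L > L)
      stop("deletion runs past the end of the protein", call. = FALSE)
    check_ref(nchar(ref))
    mut <- paste0(substr(wt, 1L, pos - 1L), substr(wt, pos + nchar(ref), L))
    if (nchar(mut) == 0L) stop("deletion removes the entire protein", call. = FALSE)
    span <- c(min(pos, nchar(mut)), min(pos, nchar(mut)))  # junction residue
    aligned <- pos - 1L
  } else {  # frameshift
    tail <- toupper(if (is.null(v$mutant_tail) || is.na(v$mutant_tail)) ""
                    else as.character(v$mutant_tail))
    if (nchar(tail) < 1L)
      stop("frameshift requires the mutant tail in the variant record", call. = FALSE)
    validate_sequence(tail, "mutant_tail")
    check_ref(1L)
    mut <- paste0(substr(wt, 1L, pos - 1L), tail)
    span <- c(pos, nchar(mut))
    aligned <- pos - 1L
  }

  structure(list(wt_sequence = wt, mut_sequence = mut, variant_class = cls,
                 position = pos, mut_start = span[1], mut_end = span[2],
                 aligned_prefix = aligned),
            class = "mutation_context")
}

# window geometry per MHC class: flank n and core length c
class_params <- function(mhc_class) {
  mhc_class <- match.arg(as.character(mhc_class), c("I", "II"))
  if (mhc_class == "I") list(mhc_class = "I", n = 22L, c = 9L)
  else list(mhc_class = "II", n = 27L, c = 15L)
}

#' Extract the mutation-containing peptide (MCP) around a variant
#'
#' Cuts the window from `m - n` to `m + n` around the (first) mutated
#' residue of the mutant protein: a 45-mer for MHC-I (n = 22) and a
#' 55-mer for MHC-II (n = 27), shorter when the mutation lies near a
#' terminus. The wild-type counterpart is the identical coordinate slice
#' of the wild-type protein (clipped to its length for indels).
#'
#' @param ctx A `mutation_context` from [mutation_context()].
#' @param mhc_class `"I"` or `"II"`.
#' @return A list of class `mcp_window`: `mhc_class`, `n`, `start`,
#'   `end` (1-based inclusive, mutant protein coordinates), `seq_mut`
#'   (P_M), `seq_wt` (P_WT), `mut_local` (mutated positions local to the
#'   window) and `aligned_local` (last window-local position where
#'   wild-type coordinates still align).
#' @export
extract_mcp <- function(ctx, mhc_class) {
  stopifnot(inherits(ctx, "mutation_context"))
  p <- class_params(mhc_class)
  m <- ctx$mut_start
  L <- nchar(ctx$mut_sequence)
  start <- max(1L, m - p$n)
  end <- min(L, m + p$n)
  seq_mut <- substr(ctx$mut_sequence, start, end)
  seq_wt <- substr(ctx$wt_sequence, start, min(end, nchar(ctx$wt_sequence)))
  mut_local <- seq.int(max(ctx$mut_start, start), min(ctx$mut_end, end)) - start + 1L
  structure(list(mhc_class = p$mhc_class, n = p$n, start = start, end = end,
                 seq_mut = seq_mut, seq_wt = seq_wt, mut_local = mut_local,
                 aligned_local = ctx$aligned_prefix - start + 1L,
                 variant_class = ctx$variant_class),
            class = "mcp_window")
}

#' Enumerate candidate cores from an MCP by sliding window
#'
#' Slides a window of the class core length (9-mer for MHC-I, 15-mer for
#' MHC-II) across the mutation-containing peptide at step 1, pairing each
#' mutant core with the wild-type core at the identical offset. Cores
#' covering a mutated position are flagged; cores containing 'X' or other
#' non-canonical residues are marked invalid (binding predictors and
#' BLOSUM62 are undefined there). For insertions, deletions and
#' frameshifts the wild-type protein has no positionally matched segment
#' once the window reaches the edit, so the wild-type core is `NA` there.
#'
#' @param mcp An `mcp_window` from [extract_mcp()].
#' @return A data.frame with one row per core: `mhc_class`, `offset`
#'   (1-based within the MCP), `core_mut`, `core_wt` (`NA` when absent),
#'   `contains_mutation`, `valid`. Zero rows (with a warning) when the
#'   MCP is shorter than the core length.
#' @export
enumerate_cores <- function(mcp) {
  stopifnot(inherits(mcp, "mcp_window"))
  cl <- class_params(mcp$mhc_class)
  len <- nchar(mcp$seq_mut)
  if (len < cl$c) {
    warning(sprintf("MCP of length %d is shorter than the %d-mer core; no cores",
                    len, cl$c))
    return(data.frame(mhc_class = character(), offset = integer(),
                      core_mut = character(), core_wt = character(),
                      contains_mutation = logical(), valid = logical(),
                      stringsAsFactors = FALSE))
  }
  offs <- seq_len(len - cl$c + 1L)
  core_mut <- substring(mcp$seq_mut, offs, offs + cl$c - 1L)
  # WT core exists when the full window lies inside P_WT and, for variants
  # that shift coordinates, strictly before the edit (where it would just
  # duplicate the mutant core anyway)
  wt_ok <- (offs + cl$c - 1L) <= nchar(mcp$seq_wt)
  if (mcp$variant_class != "SNP")
    wt_ok <- wt_ok & (offs + cl$c - 1L) <= mcp$aligned_local
  core_wt <- ifelse(wt_ok, substring(mcp$seq_wt, offs, offs + cl$c - 1L), NA_character_)
  contains <- vapply(offs, function(o) {
    any(mcp$mut_local >= o & mcp$mut_local <= o + cl$c - 1L)
  }, logical(1))
  # mutation-containing cores of a coordinate-shifting variant never have a
  # matched WT core
  core_wt[contains & mcp$variant_class != "SNP"] <- NA_character_
  valid <- is_canonical_peptide(core_mut) &
    (is.na(core_wt) | is_canonical_peptide(core_wt))
  data.frame(mhc_class = mcp$mhc_class, offset = offs, core_mut = core_mut,
             core_wt = core_wt, contains_mutation = contains, valid = valid,
             stringsAsFactors = FALSE)
}

#' Enumerate all mutation-containing candidate cores for a variant table
#'
#' Convenience wrapper running [mutation_context()], [extract_mcp()] and
#' [enumerate_cores()] over a variant table for one MHC class, keeping
#' only valid mutation-containing cores.
#'
#' @param variants Variant data.frame (see [read_variants()]).
#' @param proteome Named character vector of wild-type protein sequences
#'   (names are protein ids), e.g. from [read_proteome()].
#' @param mhc_class `"I"` or `"II"`.
#' @return A data.frame of candidate cores with variant annotation
#'   columns (`variant_id`, `protein_id`, `gene_id`, `position`,
#'   `mcp_start`, `mcp_end`, `mcp_seq`).
#' @export
candidate_cores <- function(variants, proteome, mhc_class) {
  out <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    wt <- proteome[[v$protein_id]]
    if (is.null(wt)) {
      warning(sprintf("variant %s: protein %s not in proteome; skipped",
                      v$variant_id, v$protein_id))
      next
    }
    ctx <- mutation_context(wt, v)
    mcp <- extract_mcp(ctx, mhc_class)
    cores <- enumerate_cores(mcp)
    cores <- cores[cores$contains_mutation & cores$valid, , drop = FALSE]
    if (nrow(cores) == 0) next
    cores$variant_id <- v$variant_id
    cores$protein_id <- v$protein_id
    cores$gene_id <- v$gene_id
    cores$position <- v$position
    cores$mcp_start <- mcp$start
    cores$mcp_end <- mcp$end
    cores$mcp_seq <- mcp$seq_mut
    out[[i]] <- cores
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(mhc_class = character(), offset = integer(),
                      core_mut = character(), core_wt = character(),
                      contains_mutation = logical(), valid = logical(),
                      variant_id = character(), protein_id = character(),
                      gene_id = character(), position = integer(),
                      mcp_start = integer(), mcp_end = integer(),
                      mcp_seq = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
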