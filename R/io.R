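# All tables are tab-separated UTF-8 with '#'-prefixed comment lines; the
# writer stamps the coordinate convention (1-based inclusive) into every file.

#' Write / read a canonical TSV
#'
#' @param x Data.frame to write.
#' @param path File path.
#' @param comment Extra comment lines (without the leading `#`).
#' @return `write_tsv` returns `path` invisibly; `read_tsv` a data.frame.
#' @export
write_tsv <- function(x, path, comment = character(0)) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (cm in c("coordinates: 1-based inclusive", comment))
    writeLines(paste0("# ", cm), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Read a proteome FASTA
#'
#' @param path FASTA file of wild-type protein sequences.
#' @return Named character vector (names = record ids up to the first
#'   whitespace).
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- sub("\\s.*$", "", names(aa))
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Read the protein-level somatic variant table
#'
#' Expected columns: `protein_id`, `gene_id`, `position` (1-based residue
#' index on the wild-type protein), `ref`, `alt`, `variant_class`
#' (`SNP`/`insertion`/`deletion`/`frameshift`) and optional
#' `mutant_tail` (required for frameshifts). A `variant_id` column is
#' derived when absent.
#'
#' @param path TSV path.
#' @return Data.frame of variants.
#' @export
read_variants <- function(path) {
  v <- read_tsv(path)
  need <- c("protein_id", "gene_id", "position", "ref", "alt", "variant_class")
  miss <- setdiff(need, names(v))
  if (length(miss) > 0)
    stop(sprintf("variant table %s lacks columns: %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (!"mutant_tail" %in% names(v)) v$mutant_tail <- NA_character_
  if (!"variant_id" %in% names(v))
    v$variant_id <- sprintf("%s_%d_%s", v$protein_id, v$position, v$variant_class)
  v$position <- as.integer(v$position)
  v
}

#' Read the expression table
#'
#' @param path TSV with columns `gene_id`, `FPKM`.
#' @return Named numeric vector of FPKM values.
#' @export
read_expression <- function(path) {
  x <- read_tsv(path)
  if (!all(c("gene_id", "FPKM") %in% names(x)))
    stop(sprintf("expression table %s needs columns gene_id, FPKM", path),
         call. = FALSE)
  stats::setNames(as.numeric(x$FPKM), x$gene_id)
}

#' Read an epitope pool
#'
#' Accepts either FASTA or a TSV whose first column holds peptides; the
#' pool is cleaned with [clean_epitope_pool()].
#'
#' @param path File path.
#' @return Character vector of pool peptides.
#' @export
read_epitope_pool <- function(path) {
  first <- readLines(path, n = 1)
  pool <- if (startsWith(first, ">")) unname(read_proteome(path))
          else read_tsv(path)[[1]]
  clean_epitope_pool(pool)
}

#' Read canonical predictor tables
#'
#' `read_cleavage_scores`: per-residue cleavage probabilities
#' (`peptide_id`, `residue_index`, `probability`).
#' `read_tap_scores`: TAP IC50 per core (`peptide`, `ic50_nM`).
#' `read_mhc_scores`: MHC IC50 per (core, allele) with the wild-type
#' counterpart (`peptide`, `allele`, `ic50_nM`, `wt_peptide`,
#' `wt_ic50_nM`; the wild-type fields may be `NA`).
#'
#' @param path TSV path.
#' @return Data.frame in the canonical layout.
#' @export
read_cleavage_scores <- function(path) {
  x <- read_tsv(path)
  need <- c("peptide_id", "residue_index", "probability")
  if (!all(need %in% names(x)))
    stop(sprintf("cleavage table %s needs columns: %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  if (any(x$probability < 0 | x$probability > 1))
    stop("cleavage probabilities must lie in [0, 1]", call. = FALSE)
  x
}

#' @rdname read_cleavage_scores
#' @export
read_tap_scores <- function(path) {
  x <- read_tsv(path)
  if (!all(c("peptide", "ic50_nM") %in% names(x)))
    stop(sprintf("TAP table %s needs columns peptide, ic50_nM", path),
         call. = FALSE)
  if (any(x$ic50_nM <= 0)) stop("TAP IC50 must be positive", call. = FALSE)
  x
}

#' @rdname read_cleavage_scores
#' @export
read_mhc_scores <- function(path) {
  x <- read_tsv(path)
  need <- c("peptide", "allele", "ic50_nM")
  if (!all(need %in% names(x)))
    stop(sprintf("MHC table %s needs columns: %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  if (!"wt_peptide" %in% names(x)) x$wt_peptide <- NA_character_
  if (!"wt_ic50_nM" %in% names(x)) x$wt_ic50_nM <- NA_real_
  if (any(x$ic50_nM <= 0)) stop("MHC IC50 must be positive", call. = FALSE)
  x
}

#' Read a validation label table
#'
#' @param path TSV with columns `peptide`, `label`
#'   (`positive`/`negative` or 0/1); an optional `allele` column is kept.
#' @return Data.frame.
#' @export
read_labels <- function(path) {
  x <- read_tsv(path)
  if (!all(c("peptide", "label") %in% names(x)))
    stop(sprintf("label table %s needs columns peptide, label", path),
         call. = FALSE)
  x
}

# header for MCP FASTA records: protein|position|class|start-end
mcp_fasta_id <- function(protein_id, position, mhc_class, start, end) {
  sprintf("%s|%d|%s|%d-%d", protein_id, position, mhc_class, start, end)
}
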