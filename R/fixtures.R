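#' Generate a seeded synthetic fixture bundle
#'
#' Emits every input the pipeline needs — proteome FASTA, variant TSV,
#' expression TSV, epitope pool FASTA and the three canonical predictor
#' tables — entirely from a seed, so the full pipeline runs offline and
#' its behaviour can be checked against planted truth. A chosen fraction
#' of variants is "planted" as unambiguous positives: their gene gets
#' TPM > 3, every MCP residue cleaves with probability > 0.7, one
#' mutation-containing core per class binds its best allele below
#' 500 nM with a wild-type/mutant ratio of at least 10, and that core is
#' placed verbatim in the epitope pool so its alignment score reaches
#' the recognition displacement. Every non-planted variant violates at
#' least one gate shared by both classes (silenced expression or no
#' sub-500 nM core), so planted mutations provably occupy the top ranks.
#' Scores are synthetic: they exercise the pipeline's arithmetic and
#' plumbing, not predictor biology.
#'
#' @param seed Integer seed; the bundle is a pure function of it and the
#'   size parameters.
#' @param out_dir Directory for the bundle files (created).
#' @param n_proteins Number of proteins/genes (>= `n_variants`).
#' @param n_variants Number of somatic variants.
#' @param fraction_planted Fraction of variants planted as positives.
#' @return List with `paths` (named file paths), `config` (a ready
#'   [neoprio_config()]), and `truth` (data.frame: `variant_id`,
#'   `planted`, `mode`, planted core per class).
#' @export
generate_fixtures <- function(seed, out_dir,
                              n_proteins = 60, n_variants = 50,
                              fraction_planted = 0.2) {
  stopifnot(n_proteins >= n_variants, n_variants >= 1,
            fraction_planted >= 0, fraction_planted <= 1)
  set.seed(as.integer(seed))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- neoprio_config(seed = as.integer(seed))

  rpep <- function(n) paste(sample(AA_CANONICAL, n, replace = TRUE), collapse = "")

  # proteome: one gene per protein
  prot_len <- sample(120:250, n_proteins, replace = TRUE)
  proteome <- vapply(prot_len, rpep, character(1))
  names(proteome) <- sprintf("prot%03d", seq_len(n_proteins))
  genes <- sprintf("gene%03d", seq_len(n_proteins))
  names(genes) <- names(proteome)

  # variants on distinct proteins; planted ones are SNPs, the rest mix classes
  n_planted <- round(fraction_planted * n_variants)
  prot_ids <- sample(names(proteome), n_variants)
  planted <- seq_len(n_variants) <= n_planted
  mode <- ifelse(planted, "planted",
                 sample(c("low_expression", "weak_binding"),
                        n_variants, replace = TRUE))
  variants <- do.call(rbind, lapply(seq_len(n_variants), function(i) {
    pid <- prot_ids[i]
    wt <- proteome[[pid]]
    L <- nchar(wt)
    cls <- if (planted[i]) "SNP"
           else sample(c("SNP", "SNP", "SNP", "deletion", "insertion", "frameshift"), 1)
    pos <- sample(seq_len(L - 10L), 1)
    ref <- substr(wt, pos, pos)
    if (cls == "SNP") {
      alt <- sample(setdiff(AA_CANONICAL, ref), 1)
      tail <- NA_character_
    } else if (cls == "deletion") {
      ref <- substr(wt, pos, pos + sample(1:3, 1))
      alt <- ""
      tail <- NA_character_
    } else if (cls == "insertion") {
      alt <- rpep(sample(1:3, 1))
      tail <- NA_character_
    } else {
      alt <- ""
      tail <- rpep(sample(15:30, 1))
    }
    data.frame(protein_id = pid, gene_id = unname(genes[pid]), position = pos,
               ref = ref, alt = alt, variant_class = cls, mutant_tail = tail,
               variant_id = sprintf("var%03d", i), stringsAsFactors = FALSE)
  }))

  # expression: planted and bystander genes well above the TPM gate,
  # silenced genes effectively off
  fpkm <- stats::runif(n_proteins, 20, 300)
  names(fpkm) <- genes
  fpkm[variants$gene_id[mode == "low_expression"]] <- stats::runif(
    sum(mode == "low_expression"), 0, 1e-4)

  # enumerate the candidate cores both classes will see
  cores1 <- candidate_cores(variants, proteome, "I")
  cores2 <- candidate_cores(variants, proteome, "II")

  # pick one mutation-containing core per planted variant and class
  pick_core <- function(cores, vid) {
    sub <- cores[cores$variant_id == vid, , drop = FALSE]
    if (nrow(sub) == 0) return(NA_character_)
    sub$core_mut[ceiling(nrow(sub) / 2)]
  }
  planted_core1 <- vapply(variants$variant_id, pick_core, character(1),
                          cores = cores1)
  planted_core2 <- vapply(variants$variant_id, pick_core, character(1),
                          cores = cores2)
  planted_core1[!planted] <- NA_character_
  planted_core2[!planted] <- NA_character_

  # cleavage: per-residue probabilities over each class-I MCP; planted MCPs
  # cleave everywhere, others draw freely from [0, 1]
  mcp_tab <- unique(data.frame(
    mcp_id = mcp_fasta_id(cores1$protein_id, cores1$position, cores1$mhc_class,
                          cores1$mcp_start, cores1$mcp_end),
    variant_id = cores1$variant_id, mcp_seq = cores1$mcp_seq,
    stringsAsFactors = FALSE))
  cleavage <- do.call(rbind, lapply(seq_len(nrow(mcp_tab)), function(i) {
    n <- nchar(mcp_tab$mcp_seq[i])
    is_pl <- planted[match(mcp_tab$variant_id[i], variants$variant_id)]
    p <- if (is_pl) stats::runif(n, 0.85, 0.99) else stats::runif(n, 0, 1)
    data.frame(peptide_id = mcp_tab$mcp_id[i], residue_index = seq_len(n),
               probability = p, stringsAsFactors = FALSE)
  }))

  # TAP: planted cores transport well, others draw log-uniformly
  tap_pep <- unique(cores1$core_mut)
  tap <- data.frame(peptide = tap_pep,
                    ic50_nM = lu_ic50(stats::runif(length(tap_pep))),
                    stringsAsFactors = FALSE)
  pl1 <- stats::na.omit(planted_core1)
  tap$ic50_nM[tap$peptide %in% pl1] <- stats::runif(sum(tap$peptide %in% pl1),
                                                    100, 3000)

  # MHC tables: per (core, allele) mutant and wild-type IC50
  mhc_table <- function(cores, alleles, planted_core) {
    rows <- expand.grid(idx = seq_len(nrow(cores)), allele = alleles,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    vid <- cores$variant_id[rows$idx]
    vmode <- mode[match(vid, variants$variant_id)]
    pep <- cores$core_mut[rows$idx]
    is_planted_core <- !is.na(planted_core[match(vid, variants$variant_id)]) &
      pep == planted_core[match(vid, variants$variant_id)]
    # default: non-binders (>= 600 nM keeps them clear of the 500 nM filter)
    ic50 <- exp(stats::runif(nrow(rows), log(600), log(5e4)))
    # low-expression decoys bind freely across the whole range
    free <- vmode == "low_expression"
    ic50[free] <- lu_ic50(stats::runif(sum(free)))
    # each planted core binds its first allele strongly
    strong <- is_planted_core & rows$allele == alleles[1]
    ic50[strong] <- stats::runif(sum(strong), 10, 400)
    ratio <- stats::runif(nrow(rows), 10, 50)
    wt_pep <- cores$core_wt[rows$idx]
    wt_ic50 <- ifelse(is.na(wt_pep), NA_real_,
                      pmin(ic50 * ifelse(strong, ratio, stats::runif(nrow(rows), 0.5, 2)),
                           5e4))
    data.frame(peptide = pep, allele = rows$allele, ic50_nM = ic50,
               wt_peptide = wt_pep, wt_ic50_nM = wt_ic50,
               stringsAsFactors = FALSE)
  }
  mhc1 <- mhc_table(cores1, cfg$alleles_mhc1, planted_core1)
  mhc2 <- mhc_table(cores2, cfg$alleles_mhc2, planted_core2)

  # epitope pool: planted cores verbatim plus unrelated decoys
  pool <- c(stats::na.omit(planted_core1), stats::na.omit(planted_core2),
            vapply(sample(9:15, 30, replace = TRUE), rpep, character(1)))
  pool <- clean_epitope_pool(pool)
  names(pool) <- sprintf("epitope%03d", seq_along(pool))

  paths <- list(
    proteome = file.path(out_dir, "proteome.fasta"),
    variants = file.path(out_dir, "variants.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    epitope_pool = file.path(out_dir, "epitope_pool.fasta"),
    cleavage = file.path(out_dir, "cleavage.tsv"),
    tap = file.path(out_dir, "tap.tsv"),
    mhc1 = file.path(out_dir, "mhc1.tsv"),
    mhc2 = file.path(out_dir, "mhc2.tsv"),
    truth = file.path(out_dir, "truth.tsv")
  )
  truth <- data.frame(variant_id = variants$variant_id, planted = planted,
                      mode = mode, core_mhc1 = planted_core1,
                      core_mhc2 = planted_core2, stringsAsFactors = FALSE)
  write_fasta(proteome, paths$proteome)
  write_tsv(variants, paths$variants)
  write_tsv(data.frame(gene_id = names(fpkm), FPKM = unname(fpkm)),
            paths$expression)
  write_fasta(pool, paths$epitope_pool)
  write_tsv(cleavage, paths$cleavage, "synthetic surrogate scores, not predictions")
  write_tsv(tap, paths$tap, "synthetic surrogate scores, not predictions")
  write_tsv(mhc1, paths$mhc1, "synthetic surrogate scores, not predictions")
  write_tsv(mhc2, paths$mhc2, "synthetic surrogate scores, not predictions")
  write_tsv(truth, paths$truth, "planted ground truth")

  cfg$paths <- paths
  list(paths = paths, config = cfg, truth = truth)
}
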