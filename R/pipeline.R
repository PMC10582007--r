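#' Score candidate cores for one MHC class
#'
#' Applies the presentation cascade to an enumerated core table: the
#' expression gate (TS), for class I the proteasome gate (PHS) and the
#' TAP transform (TBS/TIC), the 500 nM candidacy filter with the
#' best-allele affinity ratio A, the TCR-recognition probability R, and
#' finally the combined NPS. Candidates lacking predictor records are
#' dropped with a logged reason; candidates failing the candidacy filter
#' are excluded from ranking; candidates failing only a binary gate are
#' kept with NPS = 0 so rank-based evaluation sees the full list.
#'
#' @param cores Core table from [candidate_cores()].
#' @param expression Named FPKM vector (see [read_expression()]).
#' @param pool Cleaned epitope pool.
#' @param mhc_tab Canonical MHC table (see [read_mhc_scores()]) for this
#'   class.
#' @param cleavage_tab Canonical cleavage table (class I only).
#' @param tap_tab Canonical TAP table (class I only).
#' @param config A [neoprio_config()].
#' @return List with `scored` (per-core data.frame), `log` (named stage
#'   counts) and `dropped` (data.frame of dropped candidates with
#'   reasons).
#' @export
score_candidates <- function(cores, expression, pool, mhc_tab,
                             cleavage_tab = NULL, tap_tab = NULL,
                             config = neoprio_config()) {
  is_c1 <- length(cores$mhc_class) > 0 && cores$mhc_class[1] == "I"
  log <- c(cores_enumerated = nrow(cores))
  empty <- function() {
    list(scored = cores[0, , drop = FALSE], log = log,
         dropped = data.frame(core_mut = character(), reason = character()))
  }
  if (nrow(cores) == 0) return(empty())

  dropped <- list()
  drop <- function(df, keep, reason) {
    if (!all(keep))
      dropped[[length(dropped) + 1]] <<- data.frame(
        core_mut = df$core_mut[!keep], reason = reason, stringsAsFactors = FALSE)
    df[keep, , drop = FALSE]
  }

  # expression gate (gene level)
  tpm <- fpkm_to_tpm(expression)
  cores <- drop(cores, cores$gene_id %in% names(tpm), "gene not in expression table")
  log["with_expression"] <- nrow(cores)
  if (nrow(cores) == 0) return(empty())
  cores$TPM <- unname(tpm[cores$gene_id])
  cores$TS <- tpm_score(cores$TPM, config$tpm_threshold)

  if (is_c1) {
    # proteasome gate: boundary probabilities from per-residue cleavage
    # predictions over each MCP
    cores$mcp_id <- mcp_fasta_id(cores$protein_id, cores$position,
                                 cores$mhc_class, cores$mcp_start, cores$mcp_end)
    if (is.null(cleavage_tab)) stop("class I scoring needs a cleavage table", call. = FALSE)
    cl_split <- split(cleavage_tab, cleavage_tab$peptide_id)
    have <- cores$mcp_id %in% names(cl_split)
    cores <- drop(cores, have, "no cleavage record for MCP")
    log["with_cleavage"] <- nrow(cores)
    if (nrow(cores) == 0) return(empty())
    np <- cp <- numeric(nrow(cores))
    for (i in seq_len(nrow(cores))) {
      tab <- cl_split[[cores$mcp_id[i]]]
      probs <- tab$probability[order(tab$residue_index)]
      bc <- core_cleavage_probs(probs, cores$offset[i], nchar(cores$core_mut[i]))
      np[i] <- bc$n_prime; cp[i] <- bc$c_prime
    }
    cores$n_prime <- np; cores$c_prime <- cp
    cores$PHS <- hydrolysis_score(np, cp, config$cleavage_threshold)

    # TAP transform; TBS_min is taken over this run's candidate cores
    if (is.null(tap_tab)) stop("class I scoring needs a TAP table", call. = FALSE)
    idx <- match(cores$core_mut, tap_tab$peptide)
    cores <- drop(cores, !is.na(idx), "no TAP record for core")
    log["with_tap"] <- nrow(cores)
    if (nrow(cores) == 0) return(empty())
    tap <- tap_transform(tap_tab$ic50_nM[match(cores$core_mut, tap_tab$peptide)],
                         config$log_base)
    cores$TBS <- tap$TBS
    cores$TIC <- tap$TIC
  } else {
    cores$PHS <- NA_integer_
    cores$TBS <- NA_real_
    cores$TIC <- NA_real_
  }

  # MHC binding: best allele per core, then the candidacy filter
  mhc_split <- split(mhc_tab, mhc_tab$peptide)
  cores <- drop(cores, cores$core_mut %in% names(mhc_split), "no MHC record for core")
  log["with_mhc"] <- nrow(cores)
  if (nrow(cores) == 0) return(empty())
  bind <- do.call(rbind, lapply(seq_len(nrow(cores)), function(i) {
    recs <- mhc_split[[cores$core_mut[i]]]
    recs <- data.frame(allele = recs$allele, ic50_mut = recs$ic50_nM,
                       ic50_wt = if (is.na(cores$core_wt[i])) NA_real_
                                 else recs$wt_ic50_nM,
                       stringsAsFactors = FALSE)
    best_allele_binding(recs, config$affinity_cutoff_nM)
  }))
  cores <- cbind(cores, bind)
  cores <- drop(cores, cores$passes_filter,
                sprintf("mutant IC50 >= %g nM", config$affinity_cutoff_nM))
  log["pass_affinity"] <- nrow(cores)
  if (nrow(cores) == 0) return(empty())

  # TCR recognition, once per unique core sequence
  uniq <- unique(cores$core_mut)
  rvals <- vapply(uniq, function(s)
    recognition_probability(s, pool, config$a, config$k), numeric(1))
  cores$R <- unname(rvals[match(cores$core_mut, uniq)])
  cores$in_pool <- identity_lookup(cores$core_mut, pool)

  if (is_c1) {
    cores$NPS <- nps_class1(cores$TS, cores$PHS, cores$A, cores$R, cores$TIC,
                            config$epsilon)
    cores$flags <- paste0(ifelse(cores$TIC < config$epsilon, "tic_clamped;", ""),
                          ifelse(cores$wt_absent, "wt_absent;", ""))
  } else {
    cores$NPS <- nps_class2(cores$TS, cores$A, cores$R)
    cores$flags <- ifelse(cores$wt_absent, "wt_absent;", "")
  }
  log["scored"] <- nrow(cores)

  dropped <- if (length(dropped)) do.call(rbind, dropped)
             else data.frame(core_mut = character(), reason = character())
  list(scored = cores, log = log, dropped = dropped)
}

# best-scoring core per mutation, preserving rank order of the per-core table
aggregate_per_mutation <- function(ranked_cores) {
  keep <- !duplicated(ranked_cores$variant_id)
  out <- ranked_cores[keep, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# columns written to the ranked TSVs, in the published layout
ranked_columns <- function(x) {
  data.frame(rank = x$rank, mhc_class = x$mhc_class, peptide = x$core_mut,
             wt_peptide = ifelse(is.na(x$core_wt), "NA", x$core_wt),
             gene_id = x$gene_id, variant_id = x$variant_id, allele = x$allele,
             TS = x$TS, PHS = x$PHS, TBS = x$TBS, TIC = x$TIC,
             Aff_WT = x$ic50_wt, Aff_M = x$ic50_mut, A = x$A, R = x$R,
             NPS = x$NPS, flags = x$flags, stringsAsFactors = FALSE)
}

#' Run the full prioritization pipeline
#'
#' Executes extract -> gate -> bind -> recognize -> rank for both MHC
#' classes from the files named in `config$paths`:
#' `proteome` (FASTA), `variants` (TSV), `expression` (TSV),
#' `epitope_pool` (FASTA/TSV), `cleavage` and `tap` (canonical TSVs,
#' class I), `mhc1` and `mhc2` (canonical MHC TSVs). Writes per-core and
#' per-mutation ranked tables, the top-k slice, a YAML config echo and a
#' plain-text run log of per-stage survivor counts into `out_dir`.
#'
#' @param config A [neoprio_config()] whose `paths` name the inputs.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @return List with per-class results: `ranked_cores`, `ranked`
#'   (per-mutation), `top`, `log`, `dropped`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  p <- config$paths
  need <- c("proteome", "variants", "expression", "epitope_pool",
            "cleavage", "tap", "mhc1", "mhc2")
  miss <- setdiff(need, names(p))
  if (length(miss) > 0)
    stop(sprintf("config$paths lacks: %s", paste(miss, collapse = ", ")),
         call. = FALSE)

  proteome <- read_proteome(p$proteome)
  variants <- read_variants(p$variants)
  expression <- read_expression(p$expression)
  pool <- read_epitope_pool(p$epitope_pool)
  cleavage_tab <- read_cleavage_scores(p$cleavage)
  tap_tab <- read_tap_scores(p$tap)
  mhc_tabs <- list(I = read_mhc_scores(p$mhc1), II = read_mhc_scores(p$mhc2))

  if (nrow(variants) == 0)
    warning("empty variant table; ranked output is empty")

  res <- list()
  for (cls in c("I", "II")) {
    if (nrow(variants) == 0) {
      cores <- candidate_cores(variants[0, , drop = FALSE], proteome, cls)
      res[[cls]] <- list(ranked_cores = cores, ranked = cores, top = cores,
                         log = c(variants = 0), dropped = NULL)
      next
    }
    cores <- candidate_cores(variants, proteome, cls)
    sc <- score_candidates(cores, expression, pool, mhc_tabs[[cls]],
                           cleavage_tab = if (cls == "I") cleavage_tab,
                           tap_tab = if (cls == "I") tap_tab,
                           config = config)
    if (nrow(sc$scored) > 0) {
      ranked_cores <- rank_candidates(sc$scored)
      ranked <- aggregate_per_mutation(ranked_cores)
      top <- utils::head(ranked, config$top_k)
    } else {
      ranked_cores <- ranked <- top <- sc$scored
    }
    res[[cls]] <- list(ranked_cores = ranked_cores, ranked = ranked, top = top,
                       log = c(variants = nrow(variants), sc$log), dropped = sc$dropped)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_config(config, file.path(out_dir, "config.yaml"))
    lines <- character(0)
    for (cls in c("I", "II")) {
      tag <- if (cls == "I") "mhc1" else "mhc2"
      r <- res[[cls]]
      if (nrow(r$ranked) > 0) {
        write_tsv(ranked_columns(r$ranked_cores),
                  file.path(out_dir, sprintf("candidates_%s.tsv", tag)),
                  comment = "one row per (core, best allele) candidate")
        write_tsv(ranked_columns(r$ranked),
                  file.path(out_dir, sprintf("ranked_%s.tsv", tag)),
                  comment = "one row per mutation (best-scoring core)")
        write_tsv(ranked_columns(r$top),
                  file.path(out_dir, sprintf("top_%s.tsv", tag)))
      } else {
        write_tsv(data.frame(rank = integer(), peptide = character(), NPS = numeric()),
                  file.path(out_dir, sprintf("ranked_%s.tsv", tag)))
      }
      lines <- c(lines, sprintf("[%s] %s", tag,
                                paste(names(r$log), r$log, sep = "=", collapse = " ")))
      if (!is.null(r$dropped) && nrow(r$dropped) > 0)
        lines <- c(lines, sprintf("[%s] dropped %d candidates (%s)", tag,
                                  nrow(r$dropped),
                                  paste(unique(r$dropped$reason), collapse = "; ")))
    }
    writeLines(lines, file.path(out_dir, "run_log.txt"))
  }
  res
}
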