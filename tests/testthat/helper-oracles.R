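# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force optimal local alignment: a local alignment is determined by its
# chain of matched index pairs (i1<...<iL, j1<...<jL); unmatched interior
# residues form gaps costing open + len * ext on each sequence. Enumerate
# every chain and take the maximum (or 0 for the empty alignment).
bf_local_align <- function(s, e, open = 11, ext = 1, mat = neoprio:::blosum62()) {
  a <- strsplit(s, "")[[1]]
  b <- strsplit(e, "")[[1]]
  n <- length(a); m <- length(b)
  best <- 0
  gap_cost <- function(idx) {
    d <- diff(idx) - 1L
    sum(ifelse(d > 0, open + d * ext, 0))
  }
  for (L in seq_len(min(n, m))) {
    ia <- utils::combn(n, L, simplify = FALSE)
    jb <- utils::combn(m, L, simplify = FALSE)
    for (ii in ia) {
      ga <- gap_cost(ii)
      subs_rows <- a[ii]
      for (jj in jb) {
        sc <- sum(mat[cbind(subs_rows, b[jj])]) - ga - gap_cost(jj)
        if (sc > best) best <- sc
      }
    }
  }
  best
}

# Brute-force AUC by concordant-pair counting, ties counted half.
bf_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  sp <- scores[labels]; sn <- scores[!labels]
  tot <- 0
  for (x in sp) for (y in sn) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(sp) * length(sn))
}

random_peptide <- function(len, alphabet = c("A", "C", "D", "E", "G")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# small in-memory fixture bundle shared by pipeline-level tests
fixture_bundle <- function(seed = 17, dir = tempfile("fx"), ...) {
  generate_fixtures(seed, dir, ...)
}
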