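test_that("variants edit the wild-type protein correctly", {
  expect_equal(build_mutant_protein("ACDEF", list(variant_class = "SNP",
                                                  position = 2, ref = "C", alt = "W")),
               "AWDEF")
  expect_equal(build_mutant_protein("ACDEF", list(variant_class = "deletion",
                                                  position = 3, ref = "DE", alt = "")),
               "ACF")
  expect_equal(build_mutant_protein("ACDEF", list(variant_class = "insertion",
                                                  position = 2, ref = "C", alt = "GG")),
               "ACGGDEF")
  expect_equal(build_mutant_protein("ACDEF", list(variant_class = "frameshift",
                                                  position = 3, ref = "D", alt = "",
                                                  mutant_tail = "WWWW")),
               "ACWWWW")
  # ref mismatch and out-of-range position are rejected
  expect_error(build_mutant_protein("ACDEF", list(variant_class = "SNP",
                                                  position = 2, ref = "G", alt = "W")),
               "does not match")
  expect_error(build_mutant_protein("ACDEF", list(variant_class = "SNP",
                                                  position = 9, ref = "C", alt = "W")),
               "outside")
})

test_that("MCP windows have the class geometry and clip at termini", {
  wt <- paste(rep("A", 100), collapse = "")
  snp_at <- function(m) mutation_context(wt, list(variant_class = "SNP",
                                                  position = m, ref = "A", alt = "W"))
  w <- extract_mcp(snp_at(50), "I")
  expect_equal(c(w$start, w$end), c(28, 72))
  expect_equal(nchar(w$seq_mut), 45)
  w3 <- extract_mcp(snp_at(3), "I")
  expect_equal(c(w3$start, w3$end), c(1, 25))
  expect_equal(nchar(w3$seq_mut), 25)
  w2 <- extract_mcp(snp_at(50), "II")
  expect_equal(nchar(w2$seq_mut), 55)
  # the mutant residue sits at the window-local mutation position
  expect_equal(substr(w$seq_mut, w$mut_local, w$mut_local), "W")
})

test_that("core enumeration counts match the closed forms", {
  wt <- paste(rep("A", 200), collapse = "")
  ctx <- mutation_context(wt, list(variant_class = "SNP", position = 100,
                                   ref = "A", alt = "W"))
  cores1 <- enumerate_cores(extract_mcp(ctx, "I"))
  expect_equal(nrow(cores1), 45 - 9 + 1)            # 37 sliding windows
  expect_equal(sum(cores1$contains_mutation), 9)     # centred SNP, 9-mer
  cores2 <- enumerate_cores(extract_mcp(ctx, "II"))
  expect_equal(nrow(cores2), 55 - 15 + 1)
  expect_equal(sum(cores2$contains_mutation), 15)
  # WT and mutant cores differ exactly at the mutated offset
  mutc <- cores1[cores1$contains_mutation, ]
  for (i in seq_len(nrow(mutc))) {
    d <- which(strsplit(mutc$core_mut[i], "")[[1]] != strsplit(mutc$core_wt[i], "")[[1]])
    expect_length(d, 1)
  }
})

test_that("window and mutation-containing counts hold for random SNP placements", {
  set.seed(42)
  for (rep in 1:25) {
    L <- sample(30:120, 1)
    m <- sample(seq_len(L), 1)
    wt <- random_peptide(L, LETTERS[c(1, 3, 4, 5, 7)])
    alt <- setdiff(c("W", "Y", "K"), substr(wt, m, m))[1]
    ctx <- mutation_context(wt, list(variant_class = "SNP", position = m,
                                     ref = substr(wt, m, m), alt = alt))
    mcp <- extract_mcp(ctx, "I")
    cores <- enumerate_cores(mcp)
    len <- nchar(mcp$seq_mut)
    expect_equal(nrow(cores), len - 9 + 1)
    off <- m - mcp$start + 1
    expect_equal(sum(cores$contains_mutation),
                 min(9, off, len - off + 1, len - 9 + 1))
    # coordinate round-trip: the MCP-local mutation position carries alt
    expect_equal(substr(mcp$seq_mut, off, off), alt)
  }
})

test_that("cores lose their WT partner beyond a coordinate-shifting edit", {
  wt <- paste(rep(c("A", "C", "D", "E", "G"), 30), collapse = "")
  ctx <- mutation_context(wt, list(variant_class = "frameshift", position = 60,
                                   ref = "", alt = "",
                                   mutant_tail = strrep("W", 40)))
  cores <- enumerate_cores(extract_mcp(ctx, "I"))
  expect_true(all(is.na(cores$core_wt[cores$contains_mutation])))
  # 'X' inside a core disqualifies it
  ctx2 <- mutation_context("AAAAXAAAAAAAAAAAAAAA",
                           list(variant_class = "SNP", position = 10,
                                ref = "A", alt = "W"))
  cores2 <- enumerate_cores(extract_mcp(ctx2, "I"))
  expect_true(any(!cores2$valid))
  expect_false(any(grepl("X", cores2$core_mut[cores2$valid])))
})

test_that("an MCP shorter than the core length yields no cores, with warning", {
  ctx <- mutation_context("ACDEFG", list(variant_class = "SNP", position = 3,
                                         ref = "D", alt = "W"))
  mcp <- extract_mcp(ctx, "I")
  mcp$seq_mut <- substr(mcp$seq_mut, 1, 6)  # force a degenerate window
  expect_warning(cores <- enumerate_cores(mcp), "shorter")
  expect_equal(nrow(cores), 0)
})
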