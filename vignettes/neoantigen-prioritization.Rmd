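---
title: "Staged presentation modelling for neoantigen prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged presentation modelling for neoantigen prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoprio)
```

## The model

A tumour-specific mutant peptide becomes a T-cell target only if it survives
every stage of antigen presentation: its gene must be expressed, the
proteasome must liberate it, TAP must transport it into the ER (class I
only), an MHC molecule must bind it more avidly than its wild-type
counterpart, and finally a T-cell receptor must recognize the complex.
`neoprio` scores each stage separately and multiplies them into a single
neoantigen probability score (NPS) per candidate core:

* **Expression gate** `TS ∈ {0, 1}`. FPKM values are renormalized to TPM
  (`TPM_i = FPKM_i / ΣFPKM × 10⁶`, so `ΣTPM = 10⁶` exactly) and the gate
  opens only when the gene's TPM strictly exceeds 3.
* **Proteasome gate** `PHS ∈ {0, 1}` (class I). From per-residue cleavage
  probabilities over the mutation-containing peptide, a core passes when
  the probability just upstream of its N-terminus *or* at its C-terminal
  residue strictly exceeds 0.7. A core starting at the window's free
  N-terminus needs no upstream cut, so its N' probability is taken as 1;
  the predictions say nothing about a boundary that does not exist.
* **TAP score** `TIC` (class I). `TBS = log₁₀(IC50_TAP)`;
  `TIC = TBS + |TBS_min|` with `TBS_min` the minimum over the run's
  mutation-containing candidate cores, shifting the sample so the score is
  non-negative while preserving order. Base 10 is the natural scale of TAP
  predictors (a reported log-IC50 of 4.20 corresponds to ≈16 µM) and is
  configurable.
* **Binding ratio** `A = Aff(WT) / Aff(mutant)`. Mutant cores with IC50 at
  or above 500 nM are removed from candidacy (strict inequality, both
  classes); among the scored alleles the one with minimum mutant IC50
  represents the core (ties by allele name), because presentation is
  dominated by the strongest binder. The full per-allele table is still
  written.
* **TCR recognition** `R = S / (1 + S)` with
  `S = Σ_e exp(−k (a − |s,e|))` over an epitope pool of experimentally
  validated T-cell epitopes. `|s,e|` is the raw Smith–Waterman local
  alignment score under BLOSUM62 with affine gaps (opening 11, extension 1,
  so a gap of length L costs 11 + L). The displacement `a = 26` and slope
  `k = 1` are calibrated for this raw-score scale. `R` is computed by
  log-sum-exp, lies in `[0, 1)` by construction, equals 0 for an empty
  pool and 0.5 when a single pool entry aligns at exactly `a`.

The combined scores are

```
NPS(class I)  = TS · PHS · A · R / TIC
NPS(class II) = TS · A · R
```

Candidates are ranked per MHC class by descending NPS. Class II skips the
proteasome and TAP stages because the exogenous/autophagy routes into the
MHC-II loading compartment do not pass through either.

## Peptide windows

For a mutation at protein position `m` the mutation-containing peptide
(MCP) spans `[max(1, m − n), min(L, m + n)]`: a 45-mer for class I
(`n = 22`) and a 55-mer for class II (`n = 27`), shorter near a terminus.
Candidate cores are all 9-mers (class I) or 15-mers (class II) obtained by
a step-1 sliding window; only cores covering a mutated residue are
candidates. The counts obey closed forms (a full 45-mer yields 37 windows,
9 of which cover a central SNP) that the test suite checks.

Coordinates are 1-based inclusive throughout, and every output table
carries that convention in its header comment.

## Handling of indels and frameshifts

Inputs are protein-level, so a frameshift variant must carry its mutant
tail in the variant record; the package deliberately contains no CDS
translator. Once a window crosses a coordinate-shifting edit (insertion,
deletion, frameshift) the wild-type protein has no positionally matched
segment, so the wild-type core is recorded as absent and its affinity is
substituted with the 500 nM candidacy bound. This makes `A ≥ 1` exactly
when the mutant passes the filter — an absent wild-type competitor is
treated as a non-binder at the threshold, neither rewarding nor punishing
the candidate — and such rows are flagged `wt_absent` in the output.
Cores containing `'X'` or other non-canonical residues are disqualified
(logged, not fatal) because neither the predictors nor BLOSUM62 are
defined there.

Overlapping variants are treated independently; the package does not
phase them into haplotype peptides.

## Numerical choices

* `R` saturates logistic-style; at extreme alignment scores it is clamped
  to the largest double below 1 so the strict bound `R < 1` survives
  floating point.
* The core attaining `TBS_min` has `TIC = 0`; the class-I NPS divisor is
  guarded at `ε = 10⁻⁶` (configurable) and clamped rows are flagged
  `tic_clamped`.
* Ties in ranking are broken by higher `A`, then lower mutant IC50, then
  lexicographic peptide, so reruns are byte-identical. Gated-out
  candidates (NPS = 0) stay in the ranked table after all positive
  candidates, because rank-based evaluation needs the complete list.
* The balanced-accuracy cutoff search calls a candidate positive at
  `score ≥ threshold` and resolves ties toward the smaller threshold.

## Benchmark statistics

For comparing ranked predictions against validated peptides the package
implements the rank coverage score

```
RCS = Σ_n rank_n / (T · num(n)) · coverage(n)
    − Σ_p rank_p / (T · num(p)) · coverage(p),   coverage(k) = max(rank_k) / T
```

(in `[−1, 1]`, larger better), the ranking score `RS = rank / T` with
undetected peptides scored 1, sensitivity/specificity/balanced accuracy,
and the Mann–Whitney AUC with tie correction. Label matching is by exact
identity after case folding; duplicated peptides take their first (best)
rank. Undetected peptides enter RCS at rank `T` so both metrics share one
convention (the published definition states it only for RS). The printed
per-tool cutoff is the balanced-accuracy-maximizing threshold — our
convention, stated as such.

The three-predictor peptide–CDR3 pair score maps the count of positive
calls {3, 2, 1, 0} to {1, 0.75, 0.25, 0}. The T-cell interaction score
(TIS) aggregates a peptide's pair scores over a CDR3 panel; its published
definition is ambiguous between "fraction of CDR3s with pair score above a
threshold" and "mean pair score", so the fraction reading (threshold
0.75) is the default and the mean is available via `method = "mean"`
rather than being chosen silently.

## The synthetic cohort generator

`generate_fixtures()` emits a complete input bundle — proteome, variant
table, expression table, epitope pool and the three canonical predictor
tables — as a pure function of a seed. Its defaults (60 proteins of
120–250 residues, 50 variants, 20% planted positives) are the cohort size
used by the acceptance script and are sized so a full two-class run takes
seconds. Planted variants pass every gate with margin: TPM far above 3,
cleavage probabilities in 0.85–0.99 across the MCP, one
mutation-containing core per class bound below 500 nM with a wild-type /
mutant ratio of at least 10, and that core placed verbatim in the epitope
pool (self-alignment of any 9-mer scores ≥ 36 > a). Every non-planted
variant violates a gate shared by both classes — silenced expression or no
core under 500 nM — so planted variants provably occupy the top ranks and
no gate-violating candidate can score above zero.

What the generator does *not* emulate: real predictor score
distributions and their inter-correlation, anchor-residue binding motifs,
sequence homology between variants, expression dispersion within a gene,
or shared mutations across samples. Passing the planted-recovery tests
therefore demonstrates the pipeline's arithmetic, gating, ordering and
determinism — not predictive accuracy on real tumours, which is bounded by
the external predictors plugged into the canonical tables.

Deterministic surrogate backends (`surrogate_backend()`) serve the same
purpose at the single-table level: seeded-hash pseudo-scores with the
right units and ranges, clearly labelled non-biological.

## Worked example

```{r example}
bundle <- generate_fixtures(seed = 17, out_dir = tempfile("fx"),
                            n_proteins = 30, n_variants = 25,
                            fraction_planted = 0.2)
res <- run_pipeline(bundle$config)
head(res$I$ranked[, c("rank", "variant_id", "core_mut", "TS", "PHS",
                      "TIC", "A", "R", "NPS")], 6)
res$I$log
```

All five planted variants occupy the top five class-I ranks; the stage
log shows survivor counts falling monotonically through the cascade.

## Limitations

* External predictors are consumed through canonical tables only; the
  package neither wraps nor re-implements them, and its output quality on
  real data inherits theirs.
* The expression gate is applied at gene level (the expression table is
  per gene); transcript-level gating would need a transcript-resolved
  table.
* Whether cleavage probabilities are best computed on the 45-mer window
  or the full protein is left to the upstream predictor; the package reads
  whatever context the cleavage table was computed on.
* Ranking aggregates per mutation by its best-scoring core for the
  headline table; the per-core table is always written alongside for
  users who rank (core, allele) pairs directly.
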