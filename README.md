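# neoprio

Prioritization of tumour neoantigen candidates by staged modelling of
T-cell epitope presentation.

## The problem

Most neoantigen predictors rank mutant peptides by MHC binding affinity
alone, yet a peptide that binds MHC strongly is useless as a vaccine
target if its gene is silent, the proteasome never liberates it, TAP
never transports it, or no T-cell receptor recognizes the complex.
`neoprio` is for computational immunologists and vaccine designers who
want candidate ranking that reflects the whole presentation cascade, for
both MHC class I (CD8⁺) and class II (CD4⁺) epitopes, plus the
benchmark statistics needed to compare ranked predictions against
experimentally validated peptides.

## The model

Starting from protein-level somatic variants, the package extracts a
mutation-containing peptide (45-mer for class I, 55-mer for class II)
around each mutation and slides a 9-mer / 15-mer window to enumerate
candidate cores. Each core is scored through the cascade:

| Stage | Score | Definition |
|---|---|---|
| Expression | TS ∈ {0,1} | 1 iff gene TPM > 3 (TPM from FPKM renormalization) |
| Proteasome (I) | PHS ∈ {0,1} | 1 iff N′ or C′ cleavage probability > 0.7 |
| TAP (I) | TIC ≥ 0 | TBS = log₁₀ IC50; TIC = TBS + \|TBS_min\| |
| MHC binding | A > 0 | Aff(WT)/Aff(mutant); mutant IC50 < 500 nM required |
| TCR recognition | R ∈ [0,1) | R = S/(1+S), S = Σ_e exp(−k(a−\|s,e\|)), a = 26, k = 1 |

where |s,e| is the raw Smith–Waterman score (BLOSUM62, gap open 11,
extend 1) of the core against a pool of validated epitopes. The combined
neoantigen probability score is

    NPS(I)  = TS · PHS · A · R / TIC
    NPS(II) = TS · A · R

and candidates are ranked per class by descending NPS. For benchmarking,
the package implements the rank coverage score (RCS ∈ [−1,1]), the
ranking score (RS = rank/T, undetected = 1), sensitivity / specificity /
balanced accuracy, tie-corrected Mann–Whitney AUC, and the
three-predictor peptide–CDR3 pair score {1, 0.75, 0.25, 0} with T-cell
interaction score (TIS) aggregation.

## Worked example

A seeded synthetic cohort (25 variants, 5 planted as true positives)
through the full two-class pipeline:

```r
library(neoprio)
bundle <- generate_fixtures(seed = 17, out_dir = tempfile("fx"),
                            n_proteins = 30, n_variants = 25,
                            fraction_planted = 0.2)
res <- run_pipeline(bundle$config)
head(res$I$ranked[, c("rank", "variant_id", "core_mut", "TS", "PHS",
                      "TIC", "A", "R", "NPS")], 6)
#>   rank variant_id  core_mut TS PHS    TIC      A        R   NPS
#> 1    1     var004 AQRDCDPQY  1   1 3.0106  49.08 1.000000 16.30
#> 2    2     var001 SRCIAIVSA  1   1 3.0814  44.76 1.000000 14.53
#> 3    3     var005 FKPKMFNKY  1   1 3.4049  49.21 1.000000 14.45
#> 4    4     var002 SYLIVHYAK  1   1 2.9687  39.84 1.000000 13.42
#> 5    5     var003 KCQCRMIWC  1   1 3.3977  31.29 1.000000  9.21
#> 6    6     var014 ACQQFNCSH  0   1 0.2048 472.31 0.006765  0.00
res$I$log
#>         variants cores_enumerated  with_expression    with_cleavage
#>               25              252              252              252
#>         with_tap         with_mhc    pass_affinity           scored
#>              252              252               85               85
```

The five planted variants fill ranks 1–5 with NPS > 0: their genes pass
the TPM gate (TS = 1), their cores cleave (PHS = 1), bind under 500 nM
with a 30–50× wild-type/mutant ratio (A), and match the epitope pool
(R ≈ 1). Rank 6 is a decoy whose silenced gene forces TS = 0 and hence
NPS = 0. The stage log counts survivors through the cascade — 252
mutation-containing cores enumerated, 85 passing the 500 nM candidacy
filter. Evaluating this ranking against the planted truth gives
RCS = 0.6420 and AUC = 1.0000.

A thin CLI wraps the same functions
(`Rscript inst/cli/neoprio.R <fixtures|extract|run|evaluate> ...`).

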