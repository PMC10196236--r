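# tcemscan

Scores missense tumor mutations for immune visibility by combining
three patient-specific signals:

1. **Motif frequency.** A peptide bound in an MHC groove exposes only a
   pentamer of its residues to the T cell receptor — the *T cell
   exposed motif* (TCEM): positions p4–p8 of a class I 9mer, and the
   discontinuous positions 5, 6, 8, 10, 11 of a class II 15mer. T cells
   are tolerized against motifs common in the self proteome and the gut
   microbiome, so a mutation matters most when its exposed pentamer is
   **rare or absent** in those references. `build_ppf()` tallies the
   exposed pentamer of every reference window over the complete
   20⁵ = 3,200,000 key space, so an unseen motif is an honest zero.
2. **Binding.** A bagged regression ensemble over principal-component
   amino-acid descriptors (`train_ensemble()`) predicts Ln(ic50) per
   allele; predictions are standardized within protein and allele by a
   monotone sinh-arcsinh transform (`zscale_within_protein()`), and a
   peptide counts as binding at Zscale ≤ −1 (≈ 16th percentile). Any
   other predictor can be plugged in through `predict_binding()`.
3. **Register.** An interior mutation sits in exactly 9 sliding 9mers;
   five registers expose it to the TCR, four bury it in anchor
   positions. Exposing registers create novel motifs; anchor registers
   can create or destroy binding of an unchanged self motif. The
   down-selection cascade (`downselect()`) and genotype bitmaps
   (`bitmap_class_i()`, 64 patterns) do this bookkeeping per case.

Everything runs at desk scale on seeded synthetic data — proteomes,
microbiomes, mutation sets, HLA genotypes, and binding ground truths
with realistic anchor dominance (`gen_*` functions).

## Worked example

Motif extraction — the classic KRAS G12D 9mer `VGADGVGKS` exposes
`DGVGK` and buries `VGAS`:

```r
library(tcemscan)
extract_tcem_i("VGADGVGKS")
#> [1] "DGVGK"
extract_gem_i("VGADGVGKS")
#> [1] "VGAS"
```

Register enumeration for one interior mutation (L30W): 9 windows, 5
exposing, and each exposing register spells a different novel pentamer:

```r
p <- protein_record("prot1", paste(rep("ACDEFGHIKL", 6), collapse = ""))
m <- mutation("case001", "prot1", 30, "L", "W")
regs <- enumerate_mutant_registers(apply_mutation(p, m), m, 9)
regs[, c("start", "offset", "mutant_pocket", "exposed", "tcem")]
#>  start offset mutant_pocket exposed  tcem
#>     22     -8             9   FALSE FGHIK
#>     23     -7             8    TRUE GHIKW
#>     24     -6             7    TRUE HIKWA
#>     25     -5             6    TRUE IKWAC
#>     26     -4             5    TRUE KWACD
#>     27     -3             4    TRUE WACDE
#>     28     -2             3   FALSE ACDEF
#>     29     -1             2   FALSE CDEFG
#>     30      0             1   FALSE DEFGH
```

A complete synthetic case — 60 proteins, 30 rare-biased mutations, one
genotype, deterministic synthetic binding truth:

```r
proteome <- gen_proteome(60, min_length = 80, max_length = 160, seed = 11)
mutations <- gen_mutations(proteome, 30, seed = 12, rare_bias = TRUE)
genotypes <- gen_genotypes(1, seed = 13)
res <- run_case(list(proteome = proteome, mutations = mutations,
                     genotypes = genotypes, truth_seed = 14))
res
#> case_run: 1 cases, 2520 annotation rows, 0 exclusions
res$downselect
#>   case_id n_mutations n_peptides_9_15 n_9mers n_nonbinding_9mers
#> 1 case001          30             720     270                119
#>   n_nonbinding_or_nonTCEM n_binding n_binding_and_TCEM_exposed
#> 1                     185       151                         85
#>   n_binding_TCEM_I_and_II
#> 1                      52
```

The cascade narrows 270 mutant 9mers to 151 binders, 85 that also
expose the mutant, and 52 whose mutation additionally yields a bound,
exposing class II 15mer. Exposure and pattern diversity sit where the
register combinatorics predict (5/9 ≈ 0.56 under register-blind
binding; up to 64 bitmap patterns):

```r
s <- res$case_summaries$case001
round(s$exposure$event_fraction, 3)
#> [1] 0.567
s$diversity
#> $n_distinct_patterns
#> [1] 17
#> $shannon_entropy_bits
#> [1] 2.01
```

Wildtype TCEMs come from the reference itself, so their counts are
positive; the mutant motifs are novel and almost all absent — the
signal the whole method is built on:

```r
cmp <- compare_mut_wt(res$annotations, "I", "hppf")
cmp$class_tally_wt
#>    absent singleton doubleton        3+
#>         0       148         2         0
cmp$class_tally_mut
#>    absent singleton doubleton        3+
#>       149         1         0         0
```

See `vignette("tcem-immune-visibility")` for the model, the
statistical machinery (zero-inflated Poisson, SHASH standardization,
4PL and Weibull fits), and the design of the synthetic generators.

## Reproduction

- Unit, property, and acceptance tests:
  `Rscript -e 'testthat::test_dir("tests/testthat", package = "tcemscan", load_package = "installed")'`
  (install the package first). The acceptance tests cover the key-space
  and register combinatorics, threshold calibration, the register-blind
  exposure null, oracle equivalence of the pentamer tally and the
  down-selection cascade, parameter recovery for every fitted model,
  and the qualitative anchor/TCEM asymmetry.
- Register accounting target:
  `Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`
  regenerates, from scratch, the count of mutant-containing 9mer
  windows produced by 1,234 interior one-per-protein missense
  mutations (9 × 1,234 = 11,106) and writes it as JSON. The result is
  exact for every seed.

All randomness is seeded; identical inputs give identical outputs.
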