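---
title: "Scoring tumor mutations by T cell exposed motif frequency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring tumor mutations by T cell exposed motif frequency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(tcemscan)
```

## The model

A missense tumor mutation is only visible to T cells if three
independent conditions line up:

1. **A peptide containing the mutant residue binds an MHC molecule the
   patient actually carries.** Binding is allele-specific: each of the
   six class I slots (A1, A2, B1, B2, C1, C2) and two DRB1 slots can
   bind or not bind independently.
2. **The binding register places the mutant residue where the T cell
   receptor can touch it.** A 9mer bound in class I exposes only
   positions p4–p8 to the TCR — the *T cell exposed motif* (TCEM), a
   continuous pentamer. Positions p1, p2, p3, p9 are the anchors, buried
   in the MHC groove (the *groove exposed motif*, GEM). For class II,
   the 15mer's central core (positions 4–12) sits in the groove and the
   TCEM is the discontinuous pentamer at 15mer positions 5, 6, 8, 10,
   11 (core pockets 2, 3, 5, 7, 8); positions 4, 7, 9, 12 (core pockets
   1, 4, 6, 9) are the anchors.
3. **The exposed pentamer is one the immune system has not learned to
   ignore.** T cells are tolerized against motifs that are common in
   the self proteome and the commensal microbiome. A mutant TCEM that
   is *rare or absent* in those references is the interesting case.

The package quantifies condition 3 with **pentamer frequency tables**:
for every clean window of a reference proteome, tally the TCEM pentamer
it exposes. Because the pentamer alphabet is $20^5 = 3{,}200{,}000$,
every possible motif is a key and an unobserved motif is an honest
count of zero, not a missing value. The human table (hPPF) and a
gastrointestinal-microbiome table (giPPF) are built identically from
different references.

### Register combinatorics

An interior mutation (at least 14 residues from both termini) appears
in exactly 9 sliding 9mers and 15 sliding 15mers. Of the nine class I
registers, five place the mutant in a TCEM position; likewise five of
the fifteen class II registers. So one point mutation generates at
most 10 *novel* exposed pentamers — and simultaneously, in the
non-exposing registers, peptides whose TCEM is identical to wildtype
but whose anchor residues changed, which can create or destroy binding
of a fully self motif. The down-selection cascade, the register
matrix, and the mutant-aligned profiles in this package are all
bookkeeping over this small combinatorial structure.

## Binding prediction and the Zscale

The reference predictor is a bagged regression ensemble. Peptides are
encoded by amino-acid physicochemical descriptors: the packaged table
(`aa_property_table()`) carries eight classical property scales
(hydropathy, mass, volume, polarity, isoelectric point, two secondary
structure propensities, charge), which `compute_descriptors()` reduces
to three orthogonal unit-variance principal components. A peptide is
the concatenation of its per-position descriptor triples (27 numbers
for a 9mer). `train_ensemble()` draws bootstrap resamples (300
candidates by default), fits a small feed-forward network (or a linear
model) to each, scores each candidate on its out-of-bag examples, and
keeps the best 25 by out-of-bag RMSE. Prediction reports the ensemble
mean and between-member standard deviation of Ln(ic50). A floor of 200
training examples per allele is enforced.

Raw Ln(ic50) values are not comparable across alleles, so the pipeline
standardizes **within protein and allele**: all windows of one protein
under one allele are transformed to zero mean and unit variance by a
maximum-likelihood sinh-arcsinh (SHASH) fit (`fit_shash()`,
`zscale_within_protein()`). SHASH is a four-parameter family
(location, scale, skew, tailweight) whose fitted transform is strictly
monotone — ranks are exactly preserved — and absorbs the skew and
heavy tails that Ln(ic50) distributions typically show. The working
binding threshold is Zscale ≤ −1, about the 16th percentile
(`normal_percentile(-1)` = 15.87): roughly the strongest sixth of the
windows of that protein for that allele.

Any predictor can stand behind the pipeline through the
`predict_binding()` interface: a trained `ensemble_model`, a synthetic
`binding_truth`, or a plain function of peptides.

## Genotype logic

For each mutant 9mer and each class I slot the pipeline records the
mutant and wildtype Zscale. A six-bit **bitmap** (`bitmap_class_i()`)
encodes, per slot, whether the peptide is both bound (z ≤ threshold)
and mutant-exposing; 64 patterns are possible and their Shannon
entropy (`pattern_diversity()`) summarizes how evenly a case's
peptides spread over them. Binding changes classify as *Lost*
(wildtype bound, mutant not), *Gained*, or *Retained*
(`classify_binding_change()`). The 6 × 5 grid of mutant Zscales over
(slot, exposing register) identifies the most probable presenting
combination as its minimum (`register_matrix()`; ties resolve
slot-major A1..C2 then ascending register, within a 10⁻⁹ tolerance).
`downselect()` tallies the cascade from all mutant peptides down to
those simultaneously bound, mutant-exposing, and (optionally) paired
with a bound exposing class II 15mer — either any such 15mer of the
same mutation (`dual_rule = "mutation"`) or one physically containing
the 9mer (`"nested"`).

## Statistical summaries

Pentamer counts for mutant TCEMs are dominated by zeros, so
`fit_zip()` fits a zero-inflated Poisson by maximum likelihood —
$P(0) = \pi + (1-\pi)e^{-\lambda}$ — with Wald intervals from the
observed Fisher information on the (log λ, logit π) scale. When the
observed zero fraction does not exceed $e^{-\bar x}$ the data carry no
evidence of inflation and a plain Poisson fit with π = 0 is returned;
all-zero input returns an explicit degenerate fit (π = 1, λ
unidentifiable) rather than a spurious estimate. `compare_mut_wt()`
contrasts wildtype and mutant TCEM count distributions on the exposed
registers, where the motif actually changes.

Two curve families summarize derived quantities: a four-parameter
logistic (`fit_4pl()`) for sigmoid responses such as binding
probability against Zscale, and a Weibull growth curve
(`fit_weibull_growth()`) for the cumulative fraction of bound exposed
peptides by hPPF count, with the asymptote bounded at 1 when the
response is a fraction. Both use deterministic multi-start
Levenberg–Marquardt least squares: the 4PL start comes from an
empirical-logit linearization (tried with both hill signs) plus
quantile-anchored starts, and the converged fit with the lowest RMSE
wins, ties broken by the smaller parameter norm. On noiseless data
both recover generating parameters to far better than 10⁻⁶.

## Synthetic data: what is realistic and what is not

Everything runs at desk scale on generated data
(`gen_proteome()`, `gen_microbiome()`, `gen_mutations()`,
`gen_genotypes()`, `gen_binding_truth()`, `gen_training_set()`). The
generators aim to reproduce the *structural* properties the methods
depend on, not biological sequence content:

- **Residue composition.** The `"human"` preset down-weights W, C, M,
  H — the rarest residues in real proteomes — so that mutations toward
  them (`rare_bias = TRUE`, emulating the observed enrichment of
  tumor mutations to these residues) generate rare exposed pentamers.
- **Microbiome reference.** `gen_microbiome()` produces about
  `scale` times the window count of the paired proteome with a
  composition that is a 70/30 mixture of the human preset and uniform:
  its pentamer population overlaps the human one but differs.
- **Mutations.** Interior placement (≥ 14 residues from termini)
  guarantees the full 9 + 15 register sets, one mutation per protein
  by default, always verifiable against the sequence.
- **Binding truth.** `gen_binding_truth()` builds a deterministic
  additive energy over positions. Per-position residue weights are
  linear combinations of the packaged descriptors, with standard
  deviations 5× larger (by default) at the class I anchors p2/p9 (for
  15mers: large at core anchors, moderate in the core, small in the
  flanks). Two consequences follow by construction: anchor-position
  substitutions move predictions more than TCEM-position substitutions,
  and the energy surface lies in the feature space the ensemble
  learns in, so with zero noise an ensemble re-ranks held-out peptides
  essentially perfectly and with realistic noise still exceeds
  Spearman ρ of 0.9. What the truth does *not* model: register
  competition, allele-specific anchor preferences, or any real
  binding-motif data.

## Numerical choices

- Pentamers are base-20 integer keys (A=0…Y=19, most significant
  first), tallied with a single `tabulate()` pass over all windows —
  building both tables for a reference is linear in its length.
- SHASH likelihoods use an overflow-safe `log(cosh)` and a
  Nelder–Mead then BFGS optimization with tight tolerance; groups too
  small for a stable fit (n < 8) fall back to a rank-based
  inverse-normal transform and are flagged, never silently fitted.
- ZIP optimization is on the unconstrained (log λ, logit π) scale so
  boundary estimates cannot escape the parameter space.
- All generators and training are seeded; equal configurations give
  byte-identical outputs.

## Limitations

- The SHASH family cannot exactly normalize every distribution; for
  raw (unlogged) lognormal input the maximum-likelihood transform
  leaves residual skewness of about 0.2 (from ~6). The pipeline
  always applies it on log scales, where the fit is near-perfect.
- With a small synthetic reference, most mutant pentamers are absent
  and the mutant-side ZIP fit is legitimately degenerate (π = 1);
  summaries report the flag rather than a fabricated λ.
- Class II register enumeration treats the core placement as fixed by
  the sliding window; real class II binding chooses the core within
  the 15mer.
- The down-selection counts depend on the chosen Zscale threshold and
  dual-class linkage rule; both are explicit arguments, not constants.

## A complete run

```{r, eval = FALSE}
proteome <- gen_proteome(200, seed = 1)
mutations <- gen_mutations(proteome, 50, seed = 2, rare_bias = TRUE)
genotypes <- gen_genotypes(1, seed = 3)

res <- run_case(list(
  proteome = proteome,
  mutations = mutations,
  genotypes = genotypes,
  truth_seed = 4,
  outdir = "case001_out"
))

res$downselect
res$case_summaries$case001$exposure
res$case_summaries$case001$zip
```

`run_case()` validates every input before computing, reports skipped
mutations with reason codes in `res$exclusions`, and writes
`annotations.tsv`, `windows.tsv`, `downselect.tsv` and `summary.json`
when an output directory is given.
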