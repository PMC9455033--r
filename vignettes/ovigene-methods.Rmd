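---
title: "Methods and design choices in ovigene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in ovigene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovigene)
```

`ovigene` packages the computational stages of a single-locus
candidate-gene study in sheep: population-genetic summaries and
Hardy-Weinberg testing, a fixed-effects litter-size model, Livak
relative-expression analysis, and cloned-cDNA characterization. This
vignette explains each method, its assumptions, the parameters that
matter, and the design decisions taken where the conventions of the
field are ambiguous. It also describes what the synthetic-data
generators do and do not emulate, so the reader can judge what a green
test suite demonstrates about real data.

## Population-genetic summaries

All statistics derive from a per-locus genotype tally
(`genotype_counts`). Allele frequencies use gene counting: each
homozygote contributes two copies, each heterozygote one, out of 2N
gametes. From frequencies *p₁…p_k* we report homozygosity
Ho = Σpᵢ², gene diversity He = 1 − Σpᵢ², effective allele number
Ne = 1/Σpᵢ² and Botstein's polymorphism information content
PIC = 1 − Σpᵢ² − Σᵢ<ⱼ2pᵢ²pⱼ². Two conventions deserve emphasis:

- **"Ho" is expected homozygosity.** Livestock SNP tables habitually
  print Σpᵢ² under the heading "homozygosity", not the observed
  homozygote proportion, and the two differ whenever the locus departs
  from equilibrium. `diversity_indices()` computes Σpᵢ² and says so in
  its documentation; the observed proportion is recoverable from
  `genotype_frequencies()` if wanted.
- **PIC class boundaries are inclusive.** The conventional bands are
  quoted with strict inequalities (0.25 < PIC < 0.5 for "moderate"),
  which leaves the boundary points unclassified. Boundary values cannot
  occur with real allele counts of any realistic denominator, so for
  totality we class PIC = 0.25 and PIC = 0.5 as moderate.

The Hardy-Weinberg test is a chi-square goodness of fit of observed
genotype counts against N·pᵢ², 2N·pᵢpⱼ expectations computed from the
*sample* allele frequencies. All k(k+1)/2 genotype classes enter the
expectation, including unobserved ones (for a nearly fixed biallelic
locus the rare-homozygote class has a fractional expected count and
still contributes). Degrees of freedom are k(k−1)/2 — one for a
biallelic SNP — the number of genotype classes minus one, minus the
k−1 frequencies estimated from the data. Classes with expected count
below 5 trigger a warning (the classical validity condition) but are
*not* pooled by default, because pooling changes the statistic and the
conventional reports in this literature evidently do not pool.
`hwe_chi_square()` refuses monomorphic loci: equilibrium is undefined
with one allele.

One resulting behaviour is worth recording: for a locus with counts
409/24 and no rare homozygote observed, the three-class test gives
χ² ≈ 0.35 and p ≈ 0.55, a two-class collapse gives p ≈ 0.94, and a
2-df reference gives p ≈ 0.84. A published value of exactly 1.00 for
such data is not reproducible by any standard chi-square variant; the
package reports its own consistent value.

## The litter-size association model

`fit_association()` fits the fixed-effects model
Y = μ + parity + genotype + parity×genotype + e by least squares on
per-parity records. Because field data are unbalanced (genotype classes
of 256/150/27 animals, say), sequential sums of squares depend on term
order; we therefore use sum-to-zero effect coding and Type III partial
F-tests, computed as the residual-sum-of-squares increase when a term's
columns are deleted from the full design matrix. A unit test verifies
this agrees with `car::Anova(type = "III")` to machine precision.

Two response conventions coexist in this literature: the per-parity
record (which is what gives the parity term meaning) and the per-animal
mean across parities (which is what summary tables print). The default
is the per-record model; `response = "animal_mean"` collapses to a
one-way genotype model on animal means. `genotype_summary()` always
summarises per-animal means — n, mean, sample SD (n−1) — because that
is the unit a breeder's table reports.

Degenerate designs are handled explicitly rather than by fallthrough:
a single genotype class is an error; an empty parity×genotype cell
drops the interaction (with a warning) but keeps both main effects; a
zero-variance response (every ewe a singleton bearer) reports all F
statistics as not computable and declares no significance; a saturated
design is an error naming the cause. Small cells — a genotype carried
by 27 animals, or a zero-variance cell — are retained, not dropped:
they are data.

## Livak relative expression and letter groups

`relative_expression()` implements 2^−ΔΔCt with technical replicates
averaged first: per animal and tissue, ΔCt = Ct(target) − Ct(reference);
ΔΔCt subtracts the calibrator tissue's mean ΔCt; fold change is
2^−ΔΔCt. The method assumes near-100 % amplification efficiency for
both genes (the usual Livak caveat); efficiency-corrected variants are
out of scope. Design choices:

- **Calibrator.** When none is named, the lowest-expressing tissue
  (largest mean ΔCt) is used, so the reported profile is ≥ 1-fold
  everywhere and the "lowest in muscle" pattern of skeletal tissues
  reads naturally. The tissue-level fold change is computed from the
  tissue-mean ΔCt, which makes the calibrator exactly 1.00 by
  construction; per-animal fold changes against the same baseline carry
  the biological dispersion.
- **Dispersion.** The SD reported per tissue is the SD of per-animal
  fold changes — simple and matching the "mean ± SD" bars of expression
  figures — rather than a ΔCt-scale SD transformed through the
  exponential.
- **ANOVA and letters.** Across-tissue differences are tested by
  classical one-way ANOVA on per-animal fold changes (3 biological
  replicates per tissue), followed by pairwise comparisons — Fisher's
  LSD by default (the common choice in this literature), Tukey-Kramer
  by option. The comparisons are *protected*: when the overall F-test
  is not significant at α, all tissues share one letter. Protection is
  what keeps the family-wise error of 78 pairwise comparisons among 13
  tissues from fabricating letter structure under the null.
- **Letters.** `letter_display()` uses the insert-and-absorb
  construction, which guarantees the defining property — two groups
  share a letter exactly when their comparison is non-significant —
  and is verified in tests against an exhaustive check of that
  property over every significance pattern on 3–4 groups and hundreds
  of random 5–6-group patterns. Letters are assigned in
  descending-mean order so the top tissue carries "a".

## Sequence characterization

`find_longest_orf()` scans the three forward frames for ATG→stop spans
and returns the longest, ties broken by the 5′-most start; input is
assumed to be oriented cDNA, with reverse-complement scanning behind a
flag. Reported ORF length includes the stop codon, so an ORF of L nt
encodes L/3 − 1 residues. Translation uses the standard code
(via Biostrings), removes the terminal stop and refuses internal stops.

Protein molecular weight sums average (not monoisotopic) residue masses
plus one water, reported in kDa to 2 dp, the convention of cloning
reports. The isoelectric point solves for zero Henderson-Hasselbalch
net charge over free termini and D/E/C/Y/H/K/R side chains by bisection
on pH ∈ [0, 14] to |charge| < 10⁻⁴; published pKa sets differ by
several tenths of a unit, so the table used (N-term 7.50, C-term 3.55,
D 4.05, E 4.45, C 9.00, Y 10.00, H 5.98, K 10.00, R 12.00) is fixed,
documented, and overridable through the `pka` argument. pI values are
therefore comparable within the package but can differ from other
software by ~0.1–0.5 pH units.

Percent identity uses Needleman-Wunsch global alignment with match +1,
mismatch −1, linear gap −2, identity = matches / alignment length. The
desktop tools historically used for homology tables do not publish
their scoring schemes, so identity percentages should be read as
pattern-level (identical sequences are exactly 100 %; rankings are
stable; the second decimal is scheme-dependent). Trees are built by
Saitou-Nei neighbor joining on distance 1 − identity (no multiple-hit
correction by default; a Poisson correction is a one-liner on the
distance matrix). NJ can return slightly negative branch lengths on
noisy input; these are clamped to zero and the clamped total reported.
Newick output is written with 15 significant digits so that
write-then-parse round-trips branch lengths to 10⁻¹⁰.

## What the synthetic generators emulate — and what they do not

The generators produce inputs with the statistical structure the
analyses assume, at the scales of the motivating study, and those
scales are fixed as defaults rather than tuned per experiment:

- `gen_genotypes()`: 433 animals, major-allele frequency 0.76 (0.97
  for the second locus), genotypes drawn from
  (p² + Fpq, 2pq(1−F), q² + Fpq). `f` is an inbreeding-like knob for
  making disequilibrium data; `f = 0` is equilibrium.
- `gen_phenotypes()`: litter size is 1 + Bernoulli(π), baseline
  π₀ = 0.07. The singleton/twin model is deliberate: a flock mean of
  1.07 with a zero-variance minor-genotype cell implies essentially no
  triplets, and 1 + Bernoulli reproduces both the mean (1.07) and the
  SD (√(0.07·0.93) ≈ 0.26) with one parameter. Parity, genotype and
  interaction effects act on the log-odds of twinning by default; an
  `effect_scale = "probability"` mode displaces the probability
  directly, which is the natural way to specify an effect of stated
  phenotypic size (a +0.3 displacement raises the twin rate from 7 %
  to 37 %, i.e. +0.3 lambs in expectation — the planted effect used in
  the detection benchmark, where a +0.3 *log-odds* nudge would move
  the mean by only ~0.02 lambs and no test of this size could or
  should find it).
- `gen_ct_table()`: 13 tissues × 3 ewes × 3 technical replicates, with
  tissue-specific true fold changes (defaults high in ovary, lung,
  spleen, uterus; lowest in longissimus dorsi), biological noise
  (SD 0.2 Ct) at the animal×tissue level and technical noise (SD 0.1
  Ct) per well. Noiseless settings make the Livak pipeline exactly
  invertible, which the tests exploit.
- `gen_homolog_family()`: a random topology with uniform branch
  lengths, sequences evolved by independent per-site substitution
  (probability `subst_rate` × branch length, substituting to a uniform
  different base), returning both sequences and the true tree.

What they do *not* emulate: genotyping error and missingness patterns,
pedigree and shared-environment structure among ewes (every animal is
independent), selection or age structure in parity records, PCR
amplification-efficiency differences, reference-gene instability
across tissues, and realistic codon- or rate-heterogeneous sequence
evolution. A green suite therefore demonstrates that the *methods* are
implemented correctly and hold their nominal statistical properties
under clean data of the right shape — not that any particular field
dataset satisfies those assumptions.

## Validation design and problem sizes

The package's guarantees are checked at sizes chosen to balance
Monte-Carlo resolution against a test suite that stays pleasant to run:
test sizes of the HWE and association tests are measured on 2000
synthetic flocks of 433 ewes (rejection rate required within 0.05 ±
0.02); detection of the planted +0.3 twin-probability effect on 200
balanced 60-ewe designs (required ≥ 90 %, observed ≈ 100 %);
neighbor-joining on 100 random additive 4–8-taxon matrices (required
exact to 10⁻⁹, path-length metric); the ORF finder against an
exhaustive enumeration oracle on 1000 random 300-nt sequences; the
letter display against its defining property on every 3–4-group
significance pattern and 300–500 random 5–6-group patterns. The
acceptance script re-runs the same designs from a user-supplied seed.

## Known limitations

- Single-locus only: no linkage disequilibrium, haplotypes or
  multi-locus F-statistics.
- The HWE test is asymptotic; an exact test is not provided, only the
  small-expected-count warning.
- The association model is fixed-effects least squares on a binary-ish
  response; it matches the field's standard workflow, but a mixed
  model with a random animal effect (repeated parities) or a logistic
  model would be more efficient and is deliberately out of scope.
- pI and identity values are convention-dependent as discussed above.
- The report orchestrator writes flat CSVs; no figures beyond what the
  caller makes of the returned tables.
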