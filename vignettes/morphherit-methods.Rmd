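---
title: "Models and methods behind morphherit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind morphherit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphherit)
```

## The scientific problem

Throat-colour polymorphism in agamid lizards (and many other squamates)
presents four discrete morphs — orange (O), yellow (Y), orange surrounded by
yellow (OY) and grey (G) — while the *extent* of orange and yellow coverage
varies continuously among individuals of the same morph. `morphherit`
implements the two analyses this situation calls for on a two-generation
captive breeding pedigree:

1. **Discrete inheritance**: which simple Mendelian architecture is
   compatible with observed offspring morph frequencies, given parental
   morphs but not parental genotypes?
2. **Quantitative inheritance**: how heritable is the proportion of orange
   and of yellow throat coverage, treated as a quantitative trait on the
   arcsine-square-root scale?

Everything runs on a plain CSV pedigree (one row per individual: id, sex,
generation, cohort, clutch, parent links, colour proportions, morph); a
simulator generates pedigrees with known ground truth so every stage is
testable without the original animals, which were never deposited.

## Phenotype processing

Colour proportions come from upstream image segmentation (out of scope
here). Small orange/yellow pixel fractions can be produced by cream throat
colouration, so values below an expression threshold are treated as absence:
2% (orange) and 5% (yellow) in mature animals, 1% for both in juveniles.
Comparisons are strict — a value exactly at the threshold counts as
expressed. Morph classification is the presence/absence cross of the two
thresholded colours.

In OY morphs the central orange patch overlays yellow, so the yellow trait
value used in all quantitative analyses is the *effective yellow*, the sum
of orange and yellow coverage. Below-threshold values are handled per
analysis: declared missing for the animal model (`zero_policy =
"as_missing"`), excluded for parent–offspring regressions (`"exclude"`).

## Discrete models of morph inheritance

Three architectures are considered, each autosomally or Z-linked (the ZW
system makes females hemizygous at Z loci):

* **model1** — one locus, four morph-specific alleles. Its heterozygote
  phenotypes are unspecified, so it is handled only through necessary
  conditions: autosomally an offspring must share its morph with a parent;
  Z-linked, daughters must express their father's morph. Note these
  conditions are exact only when parents are effectively homozygous; with
  heterozygous parents and a dominance order, a parent can transmit an
  allele masked in its own phenotype. The simulator therefore defaults to
  homozygous founders for model1.
* **model2** — one locus, three alleles O, Y, G; O and Y co-dominant (the
  OY heterozygote *is* the OY morph), G recessive. Z-linked model2 is
  excluded categorically because hemizygous females could never be OY.
* **model3** — two unlinked di-allelic loci, `O/o` switching orange and
  `Y/y` switching yellow, dominant alleles expressing. Z-linked model3
  forbids specific father→daughter combinations (grey fathers must have grey
  daughters; yellow fathers no orange-expressing daughters; orange fathers
  no yellow-expressing daughters).

### Parental zygosity assumptions

An O- or Y-morph parent may be homozygous or heterozygous at the colour
locus. Three schemes assign the probabilities: **equal** (50:50),
**hwe** (probabilities implied by population allele frequencies at
Hardy–Weinberg equilibrium, estimated from adult morph fractions by moment
formulas: e.g. under model3, `freq(y) = sqrt(f_G + f_O)`), and
**threshold** (deterministic: above the reference-population mean coverage
→ homozygous, at or below → heterozygous; reference means default to
sex-specific means of the pedigree founders). For OY parents under model3
the scheme applies independently at each locus. Ties in the threshold
scheme go to heterozygous; `fit_all_models()` marks the model2/hwe row
not-evaluable when no grey adults exist (the moment estimator needs
`sqrt(f_G)`).

### Expected frequencies and the G test

Each phenotyped offspring with known parental morphs contributes its
mating's offspring-morph probability vector (per-sex under Z linkage;
son/daughter average if unsexed), computed by exact gamete enumeration over
the parents' genotype distributions. Parents are treated independently per
offspring — no conditioning on sibs — so expected totals equal the number of
offspring and the fit statistic remains a classical likelihood-ratio G test,
`G = 2 * sum(O * log(O/E))` on df = 3 (categories − 1; no reduction for
estimated allele frequencies, matching the published table's df; no
continuity corrections). A category with observed > 0 but expected = 0 is
reported as an infinite-G incompatibility rather than an error.

## Quantitative genetics

### Animal model

The numerator relationship matrix A is built by the tabular recursion
(`a_jj = 1 + a_sd/2`, `a_ij = (a_is + a_id)/2`). The univariate animal model
`y = Xb + a + e`, `a ~ N(0, A Va)`, `e ~ N(0, I Ve)` is fitted by REML with
fixed factors sex, cohort and generation, on transformed trait values, with
unsexed individuals excluded and below-threshold records missing (they still
link relatives through A). Because design sizes are ~10², the restricted
likelihood is profiled to the ratio `h2 = Va/Vp` and maximised by a grid
scan plus golden-section refinement with explicit dense Cholesky algebra —
no sparse machinery is warranted. The SE of h² is a delta-method transform
of the finite-difference observed information in `(Va, Ve)`; the 95% CI is
`h2 ± 1.96 se`, intentionally allowed to exceed [0, 1] as variance-component
software reports it. Designs in which no two phenotyped individuals are
related raise an explicit unidentifiability error rather than returning a
number.

### Parent–offspring regressions

Mid-parent values (mean of the two parents) are regressed on mid-offspring
values (mean over the pair's expressing offspring, all clutches pooled,
families unweighted); the slope estimates h² directly. Sire-only and
dam-only regressions estimate h²/2; following the convention that the
plotted slope is reported as the heritability estimate, `h2_reported` is the
raw slope in all modes and the classical doubling is an explicit opt-in
(`double_single_parent = TRUE`). Cross-trait variants (parent orange vs
offspring yellow and vice versa) probe genetic covariance between the two
colours.

### Sex-linkage ANCOVA

Pooling sire and dam pairs, `offspring ~ parent * parent_sex` with a random
clutch intercept tests whether maternal and paternal slopes differ — the
signature of sex linkage. Two statistical caveats are implemented
explicitly rather than hidden:

* when each clutch contributes a single shared mid-offspring value to both
  halves, the clutch intercept absorbs the response exactly and the mixed
  fit degenerates; the function detects this and falls back to the
  fixed-effects ANCOVA with a note;
* parent values are constant within clutches, so the random-clutch form is
  conservative (the co-parent's unmodelled contribution inflates the clutch
  variance and shrinks the interaction). `random_clutch = FALSE` gives the
  classical fixed-effects test; the interaction F uses df = (1, n − 4).

## The simulator as a stated world

`simulation_config()` defaults describe the reference breeding design: 23
sires and 17 dams (morph margins of the adult frequency table), 25 clutches,
58 offspring over two cohorts with a mild male bias (0.58), founder allele
frequencies backed out of the adult morph fractions under HWE, and female
expression multipliers of 2/3 (orange) and 1/2 (yellow) applied on the
proportion scale (the scale on which reduced female expression was
described). Genotypes are transmitted by exact Mendelian segregation, ZW
aware; morphs are the phenotype of the genotype.

Quantitative variation is simulated on the transformed scale, where the
additive model is assumed: founder breeding values `N(0, h2 Vp)`, offspring
= mid-parent + Mendelian-sampling deviate of variance `Va/2` (parental
inbreeding ignored by default in these founder-heavy designs), plus
residual `N(0, (1 - h2) Vp)`. Defaults `Vp = 0.02` rad² and means of 0.55
(orange) / 0.90 (effective yellow) correspond to roughly 27% and 61%
coverage with sd ≈ 0.14 rad — within the range real morphs display. The
effective-yellow mean must sit well above orange plus the yellow threshold,
because in an OY animal visible yellow surrounds the orange patch; draws
violating that geometry (a few percent) are clamped to the threshold. The
simulator models no maternal effects, no environment beyond residual noise,
no zygosity-dependent expression (co-dominant dosage), and no hormone
dynamics — so green recovery tests establish correctness of the estimators
under the additive model, not realism of those omitted features.

`make_paper_like_fixture()` is a deterministic structural stand-in for the
unpublished pairing table: exact published morph margins (parental 7/4/8/4
males, 2/5/6/4 females; 58 offspring with the published per-cohort counts),
pseudo-random pairings. Pairing-dependent published numbers (expected
frequencies, the 17/58 and 7/14 exclusion counts, empirical slopes) are
deliberately *not* reproducible from it.

## Parameter recovery at study scale

Two acceptance criteria are left red by design of the world, not by defect:

* **REML mean recovery within ±0.05.** At study-scale information (~58
  records, ~25 families) the sampling sd of ĥ² is ≈ 0.25, and with true
  h² = 0.84 about 28% of replicates hit the ĥ² = 1 boundary. The
  constrained estimator's mean is therefore biased low by ≈ 0.04–0.07 —
  confirmed with a pure multivariate-normal generative check that bypasses
  the phenotype pipeline entirely. Medians are essentially unbiased; the
  mean criterion cannot be met at this design size.
* **Model-selection power ≥ 90% at n = 58.** Data simulated under
  model3/equal yield the largest p for that exact row in only ~60% of
  replicates: the threshold scheme's deterministic per-parent assignments
  produce sharper expected counts that fit a 58-offspring sample better by
  chance about a third of the time. The true *model* (model3 under any
  scheme) wins essentially always, and the equal row dominates as n grows.

## Paternity module

The exclusion rule is implemented as stated operationally: with the dam
assumed true, a locus mismatches when no assignment of the offspring's two
alleles to maternal/paternal origin is compatible with both genotypes;
candidates with at most one mismatch (allowing a mutation) are acceptable
and the unique minimum is assigned, ties flagged. Loci with missing calls
are skipped and calls with fewer than five typed loci are marked unreliable.
Likelihood-based (LOD) assignment, HWE exact tests and null-allele
estimation are out of scope. Marker summaries report Ho, unbiased He
(`2N/(2N-1)` gene-copy correction) and PIC.

## Numerical choices and degenerate inputs

* Genotype-distribution and cross vectors must sum to 1 within 1e-12.
* REML convergence tolerance 1e-8 on the ratio scale; boundary solutions
  (ĥ² of 0 or 1) are legal outcomes; a failed information matrix flags
  `converged = FALSE` instead of fabricating an SE.
* Proportions are validated into [0, 1] with `prop_orange + prop_yellow <= 1`;
  effective yellow is clipped at 1 as a guard.
* G tests with expected = 0 and observed > 0 report infinite G with an
  incompatibility flag.
* CSV round-trips write doubles at full precision (`%.17g`) so
  `read(write(p))` is exact.

## Known limitations

* No bivariate animal model, maternal-effect components, or Bayesian
  samplers; genetic covariance between colours is addressed only through
  cross-correlations.
* The exclusion logic and expected-frequency machinery assume morphs are
  measured without classification error.
* The threshold zygosity scheme's reference means default to pedigree
  founders; the original analysis used an external adult-male panel, so
  numeric agreement with published expected counts is not expected.
* Deep (multi-generation) pedigrees are supported structurally but tested
  only to four generations.
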