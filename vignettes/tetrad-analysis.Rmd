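---
title: "Testcross crossover analysis: models, estimators and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testcross crossover analysis: models, estimators and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiocross)
```

## The observable and its model

The package analyses multi-marker testcross data from *Drosophila* female
meiosis. The mother is heterozygous over a chromosome arm carrying `k`
ordered recessive markers (the worked map is *net ho dp b pr cn* on arm
2L, `k = 6`, five scoring intervals); the father is homozygous recessive,
so each progeny's phenotype vector *is* the maternal chromatid. Scoring
is therefore deterministic: interval `i` carries a crossover call iff the
states at its flanking markers differ. This is the minimal-crossover
interpretation — an even number of exchanges inside one interval cancels
and is invisible. All downstream statistics are functions of the
per-interval calls and of the gamete crossover classes `a_j` (the number
of progeny chromosomes with `j` observed crossovers).

Three estimator families sit on top:

1. **Maps.** A map unit is defined as crossovers per 100 progeny per
   interval — a raw frequency, deliberately not Haldane/Kosambi
   transformed, because at these interval sizes the community quotes raw
   testcross frequencies as map units and they add along the arm.
   Genotype-level totals are reported two ways — the unweighted mean of
   per-cross totals and the pooled-count frequency — because with
   unequal cross sizes the two differ slightly and published totals do
   not always say which was used. Comparisons use the equal-variance
   Student *t* on per-cross values (`welch = TRUE` is available);
   replicate crosses, not progeny, are the units of inference.

2. **Patterning.** Crossover placement is separated from rate by the
   profile `p_i = crossovers_i / total crossovers`, summarised by its
   range (max − min). Heterogeneity between genotypes is tested by
   Pearson χ² on the 2×(k−1) table of interval *counts*, not
   proportions, so df = k−2 and the sampling variance is well defined;
   no continuity correction and no multiplicity adjustment, matching the
   single planned comparisons this design uses.

3. **Tetrads.** Under no chromatid interference each exchange in a
   tetrad is carried by the recovered chromatid with probability 1/2,
   giving the mixing kernel `a_j = Σ_{n≥j} C(n,j) 2^{−n} E_n`. The
   Weinstein inversion implemented here is the closed form
   `E_n = 2^n Σ_{j≥n} (−1)^{j−n} C(j,n) a_j`, verified in the tests
   against direct numerical inversion of the kernel matrix for ranks up
   to 10 and exact to 1e−12 on round trips. The maximum rank is the
   highest supplied gamete class, because the triangular system is only
   determined that far. Negative class estimates — a known feature of
   this moment-style estimator on noisy data — are *reported* with a
   warning flag, not truncated, so the default output matches the
   classical method; `constrain_nonnegative()` gives the clipped,
   mass-preserving variant for display.

## Dispersion and interference

The dispersion test compares inferred tetrad-class counts (class
frequency × number of progeny, one sampled tetrad per progeny) to a
Poisson with the same mean, pooling top classes until every expected
count is at least 1 and using df = classes − 1. Because the Poisson mean
is estimated from the same data this df is mildly anticonservative; the
class count and df are reported with every run so the construction is
auditable. Direction (under/over) is called from the relative variance.

Interference uses the classical coefficient of coincidence for two
disjoint regions, with the expected doubles computed from the same
sample's single-region frequencies (`exp = n f₁ f₂`). Regions may be
merged runs of scoring intervals; merging is recomputed per progeny from
the flanking markers (parity-aware), never by summing interval counts, so
a double crossover inside the merged region correctly scores zero. The
"two largest adjacent regions" comparison is read as the pair
(*ho–b*, *b–pr*) with *ho–b* = *ho–dp* + *dp–b*. Pooled `I` is quoted per
genotype; between-genotype comparison is a two-sided Mann-Whitney on
per-cross `I`, dropping (and counting) crosses where a zero single-region
frequency leaves `I` undefined.

## The simulator and what it does and does not emulate

`simulate_experiment()` draws, per tetrad: an exchange count (explicit
`E` vector, Poisson, or counting model), interval positions, an optional
Poisson number of class II exchanges placed uniformly, then the recovered
chromatid (each exchange kept with probability 1/2) and the emitted
genotype. A truth log records every tetrad's exchanges, the chromatid
hits, and hidden intra-interval doubles.

Design choices made where the design was genuinely open:

- **Interval-resolution positions.** Every downstream statistic is
  interval-based, so continuous cM positions would add machinery without
  adding testable behaviour; positions are interval indices drawn from
  the intensity profile.
- **One interference mechanism.** The counting model (retain every
  (m+1)-th event of an underlying Poisson process along the
  profile-warped axis, stationary random phase, rate scaled so retained
  events hit the target mean) is the single built-in interference
  mechanism; `m = 0` recovers Poisson. Gamma-renewal alternatives are
  out of scope. Note the explicit-`E` model reproduces count-level
  regulation (assurance, under-dispersion) but places exchanges
  independently, so positional interference — and hence the full
  magnitude of observed `I` — is only generated by the counting model.
- **Assurance as conditioning.** The assurance flag resamples
  zero-exchange draws, i.e. draws from the count distribution
  conditioned on ≥ 1 exchange (closed form for Poisson, renormalised
  classes for explicit `E`).
- **Determinism.** One integer seed; each cross uses a substream derived
  from (seed, cross index) by a fixed LCG-style map kept below 2^31, so
  experiments are reproducible cross-by-cross.
- **Cross sizes.** `progeny_per_cross` accepts a fixed size, a per-cross
  vector, or a range sampled uniformly to emulate unequal cross sizes;
  tests use fixed sizes for determinism.

Defaults in the analysis scripts emulate the benchmark transgene study
design: 13–14 replicate crosses of roughly 100–190 progeny; exchange
distributions for the four genotypes taken from `reference_tetrads()`
(the published class frequencies); intensity profiles from
`reference_intensity()`, calibrated so the simulated patterning ranges
match the reported 0.44 (mel-like, medially concentrated) and 0.24
(pse-like, flatter); the vir-like genotype uses the mel profile (its
patterning is reported comparable to mel) and fewer progeny per cross
(reduced fecundity); the null uses a uniform profile (class II
crossovers lack spatial patterning). What the simulator does **not**
emulate: gene conversion, viability and nondisjunction effects on
recovery, chromatid interference, scoring error, and continuous-position
interference — so passing tests validate the estimators under the stated
model, not the biology of any particular cross.

## Numerical and degenerate-input policy

Inversion is exact closed-form algebra, no tolerance knobs. Profiles are
undefined (an error, not NaN) at zero crossovers; relative variance is
`NA` at mean zero; `I` is `NA` when a single-region frequency is zero;
rows with unscoreable states are rejected at load and counted, never
imputed, because classical scoring cannot phase a gap. χ² comparisons
pool sparse top classes until expected counts reach 1; the patterning χ²
attaches a warning rather than pooling, since its five intervals are the
object under test. Fold-differences are signed with magnitude ≥ 1
(`+x/y` or `−y/x`) and undefined on nonpositive entries. Display rounding
(3 dp in `tetrad_class_table(digits = )`) is separate from stored full
precision.

## Problem sizes used in validation

The test suite validates the scoring against exhaustive enumeration of
all 64 six-marker genotypes; inversion against matrix algebra to rank
10; parameter recovery at 1,400 and 200,000 progeny (the latter for the
tight class-frequency check, with delta-method standard errors for the
inverted classes); null calibration of the four test families at 300
replicate pairs of 13-cross experiments; and counting-model interference
detection at 100 replicates of 1,000 progeny. These sizes give
Monte-Carlo error comfortably below the assertion tolerances while
keeping the default run quick.

## Known limitations

- Weinstein point estimates carry no uncertainty; bootstrap intervals
  over crosses are possible with the existing per-cross machinery but
  are not built in.
- The dispersion χ² df convention differs across the classical
  literature (whether the estimated mean costs a degree of freedom);
  we report the construction per run rather than claiming a canonical
  choice.
- Published summary tables rounded to 3 decimals reproduce moments only
  to ±0.001–0.002 (e.g. a class vector summing to 1.001 shifts a
  recomputed mean from 0.909 to 0.911); the tests treat these as
  printed-value tolerance, not disagreement.
- With dominant markers a testcross row can be unscoreable in principle;
  the loader assumes all markers scoreable and rejects anything else.
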