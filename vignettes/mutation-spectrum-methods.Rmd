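---
title: "Dose-response fitting and mutation-spectrum analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-response fitting and mutation-spectrum analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutaspec)
library(dplyr)
```

mutaspec supports a common experimental design in physical mutagenesis of
crops: seeds are irradiated with two mutagens of very different linear
energy transfer (LET) — here a carbon-ion beam (high LET) versus gamma
rays (low LET) — the first generation (M1) is scored for survival,
fertility and yield over a dose series, phenotypic mutants are screened in
M2, and a panel of confirmed M3 mutant lines is whole-genome resequenced
to profile the induced mutation spectrum. The package covers the two
quantitative halves of that design: dose-response modelling and the
variant-level spectrum pipeline.

## The single-hit multitarget model

Survival and fertility dose-response curves of seed-irradiated plants
show a shoulder: rates stay near 1 at low doses and then decline
steeply. The single-hit multitarget (SHMT) model captures this with

$$ R(D) = 1 - \left(1 - e^{-D/D_0}\right)^m $$

where $D$ is the absorbed dose (Gy), $D_0$ the dose conferring a 37%
($e^{-1}$) effect, and $m$ the extrapolation number. The quasi-threshold
or *shoulder dose* is $D_q = D_0 \ln m$; $m = 1$ gives a pure
exponential with no shoulder ($D_q = 0$). `shmt_rate()` evaluates the
curve, `fit_shmt()` fits it, and `dose_at_rate()` inverts it for
readouts such as the 50%-effect dose.

### Fitting choices

* **Least squares on the rate scale.** The assayed quantity is an
  averaged effect *rate* per dose (replicate rates are averaged before
  fitting), so the fit minimises squared residuals of rates, not a
  binomial likelihood of counts. With roughly equal numbers of units
  per dose the two are nearly equivalent, and the rate-scale objective
  is what the shoulder-dose readout is defined on.
* **Reparameterisation.** The optimiser works on $(\log D_0, u)$ with
  $m = 1 + e^{u}$, which enforces $D_0 > 0$ and $m \ge 1$ (hence
  $D_q \ge 0$) without a constrained solver.
* **Multi-start Nelder-Mead.** Shouldered curves produce local minima
  where a too-large $m$ trades off against a too-small $D_0$. The fit
  therefore seeds Nelder-Mead from the best cells of a coarse
  $(D_0, m)$ grid spanning $D_0 \in [D_{max}/10, D_{max}]$ and
  $m \in [1, 20]$. The test suite checks the result against a dense
  200 x 200 grid-search oracle, and noiseless generate-then-fit
  recovery is required to better than 1% in $D_0$ and 5% in $m$.
* **Curve inversion by bisection.** `dose_at_rate()` bisects the
  monotone fitted curve to an absolute tolerance of 0.01 Gy (the
  closed-form inverse exists and is used as an oracle in the tests; the
  bisection keeps the code path identical for any monotone extension).
  A flag switches to linear interpolation of the raw averaged rates for
  users who prefer a model-free readout.
* **Yield is never SHMT-fitted.** Yield declines too slowly and shows
  low-dose stimulation; `yield_half_dose()` only interpolates the first
  downward crossing of relative yield through 0.5.

Relative biological effectiveness is the dose ratio at a matched
endpoint, `rbe() = reference_dose / test_dose` (low-LET reference over
high-LET test). It is reported to 2 decimals, as is conventional. Note
that when RBE is recomputed from *printed* endpoint doses (rounded to
whole Gy), the last digit can differ from an RBE computed from the
unrounded fit: 376/142 = 2.648, for example.

## The mutation-spectrum pipeline

Input calls are the output layer of a resequencing toolchain: small
variants (substitutions and INDELs <= 50 bp) carry an alternate allele
frequency (AF); structural variants (deletions/duplications > 50 bp and
breakends) carry a diploid genotype string. `run_mutation_pipeline()`
applies, in order:

1. **Quality filter** — calls below a quality threshold are dropped
   (default 20, the usual Phred-scaled floor; the threshold is
   configurable because callers differ). Calls with no quality value
   are kept and flagged.
2. **Control subtraction** — keys common to the unirradiated control
   (CK) individuals are pre-existing background. The default subtracts
   the *intersection* of the CK call sets (a variant must be common to
   the CK individuals to count as background); a stricter union mode is
   available.
3. **Shared-line exclusion** — a key detected in two or more mutant
   lines cannot be an independent induced event and is removed from
   every line. The comparison runs across all supplied lines by
   default, regardless of mutagen group.
4. **Scaffold SV filter** — SVs with either locus (record, END side or
   breakend mate) on a non-chromosome sequence are split off; soybean's
   1171 unassembled scaffolds make such calls unreliable.
5. **Zygosity classification** — small variants: AF >= 0.75 homozygous,
   0.25 <= AF < 0.75 heterozygous. The published band edges overlap at
   75%; the homozygous rule is the one stated inclusively, so 0.75 is
   homozygous. Below 0.25 the call is too weakly supported to genotype
   and is discarded (configurable). SVs: a genotype with exactly one
   reference allele is heterozygous, none homozygous; `0/0` and missing
   genotypes leave the analysis set.
6. **MNV merging** — maximal runs of single-base substitutions at
   strictly consecutive positions (gap 0, the same convention SnpEff
   uses internally) merge into one multinucleotide variant. The merged
   AF is the mean of the constituents (order-independent; no published
   rule exists) and is re-classified. Constituents are consumed, so
   Ts/Tv ratios never count them.

Every stage's removals are recorded in a provenance table;
`raw - retained` always equals the summed removals, which is what makes
the planted-background tests exact.

Cross-sample SV equality uses exact breakpoints by default
(`sv_tolerance = 0`); a bp-binning tolerance is available but
approximate, trading a reproducible exact rule for fuzzy matching.

### Categories and summaries

Retained calls are classified as SBS, INDEL (deletion/insertion,
<= 50 bp), MNV, or SV (DEL_SV/DUP_SV over 50 bp, BND_SV). Length
classes split INDELs at 1 bp versus >= 2 bp and MNVs at 2 bp versus
>= 3 bp (the 2 bp class is reported separately in practice, so the
split is placed there). `aggregate_spectrum()` totals counts per
category over a group of lines in either zygosity scope (homozygous
only, or homozygous + heterozygous); `spectrum_from_counts()` applies
the same proportions arithmetic to ready-made count tables such as the
bundled `soybean_spectrum_counts()`.

### Statistics conventions

* Chi-squared: uncorrected Pearson test on the r x c table
  (`chi_squared_test()`), significance at 0.05.
* t test: pooled-variance Student's test on per-line values
  (`two_sample_t_test()`), Welch by flag; flags at 0.05/0.01/0.001.
* Error bands: mean ± 1.97 x sample SD (`error_band()`) — implemented
  exactly as stated by the reporting convention it mirrors, without
  reinterpreting the 1.97 as a t or normal quantile.
* No multiple-testing correction is applied across summaries, matching
  the reporting practice the package mirrors.

## The synthetic-data generator

`simulate_mutant_lines()` exists so that every pipeline stage can be
tested against known ground truth without any sequencing data. Its
defaults are the study conditions of the design it emulates: 16 lines
per mutagen group; expected per-line category counts equal to the
bundled group totals divided by 16 (`mutagen_profile()`); homozygous
fractions of about 0.205 (carbon) and 0.371 (gamma); homozygous AFs
uniform on [0.9, 1.0] and heterozygous AFs uniform on [0.35, 0.65] —
windows strictly inside the classification bands so intended zygosity
is unambiguous (an adversarial mode samples within 0.01 of the 0.25 and
0.75 boundaries instead); 25 CK-shared and 10 cross-line-shared
background keys; 2% of SV loci on scaffolds. Counts are drawn Poisson
around their expectations (the simplest model consistent with
independent induction events) and placed uniformly along the genome
model.

The default genome model is deliberately desk-scale: twenty 1 Mb
chromosomes plus ten scaffolds. Positions are allocated with a 1 bp
margin and are unique across all samples of one simulation, so adjacent
SBSs occur only where an MNV run was planted and identical keys occur
only where background sharing was planted — this is what lets the tests
demand *exact* filter attribution rather than statistical agreement.

What the generator does **not** emulate: read-level errors and
coverage-dependent AF noise, aligner artefacts, repeat-driven position
biases, caller-specific quality distributions, linked inheritance of
nearby mutations, and realistic chromosome sizes. Passing tests
therefore demonstrate that the *pipeline logic* is correct under the
stated statistical structure, not that the end-to-end toolchain would
behave identically on real reads.

`simulate_dose_response()` draws binomial counts
(`n_effect ~ Binomial(n_units, R(D))`) on the study's dose grids with
about 20 seeds per replicate; the test suite requires the median
relative error of the recovered shoulder dose over 200 such replicates
to stay below 15%, and `run_full_analysis()` wires all stages into a
reproducible report bundle with a JSON manifest (seed, configuration,
per-stage counts, output checksums).

## Bundled reference tables

`soybean_phenotype_counts()`, `soybean_spectrum_counts()`,
`soybean_impact_counts()`, `soybean_effect_counts()` and
`soybean_endpoint_doses()` carry the printed count tables of a
published carbon-ion versus gamma-ray soybean mutagenesis experiment.
They serve as real-data inputs for the summary statistics (totals,
homozygous fractions, SV proportions, missense/silent ratios,
phenotype-class shares, RBE) and as the source of the simulator's
default expectations. Two printed values in that experiment's
gene-effect section are internally inconsistent with their own counts
(the missense/silent ratios of the two groups appear transposed);
`functional_class_ratio()` implements the plain quotient and the
package only asserts the internally consistent pairs.

## Problem sizes and runtime

The test suite runs at desk scale by choice: 16-line simulations
(~10,000-15,000 calls per group), 200-replicate dose-response recovery,
200 x 200 grid-search oracles, and 500-variant Ts/Tv fixtures. The full
suite completes in about a minute on a single core.

## Known limitations

* The SHMT fit reports no parameter uncertainty (no profile likelihood
  or bootstrap); `r_squared` is the only goodness measure, as that is
  the readout convention it reproduces.
* Breakend pairs are joined by `MATEID` only; unpaired breakends are
  kept as single-locus calls.
* Multi-allelic records are split into biallelic calls; phasing and
  gVCF blocks are out of scope.
* The SV positional tolerance is a binning approximation, not interval
  clustering.
* Annotation consumption is label-level: the package tallies
  region/impact/class labels but never re-predicts effects from gene
  models.
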