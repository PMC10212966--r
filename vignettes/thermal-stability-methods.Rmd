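---
title: "Decoding differential thermal proteome stability with pooled-temperature designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding differential thermal proteome stability with pooled-temperature designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meltshift)
```

## The measurement model

Thermal proteome profiling reads out a protein's functional state through
its thermal stability: ligand binding, complex membership and
post-translational modifications such as arginine methylation shift the
temperature at which a protein aggregates out of solution. `meltshift`
models the soluble fraction of a protein at temperature $T$ with a
three-parameter logistic,

$$ f(T) = p + \frac{1 - p}{1 + e^{b (T - T_m)}}, $$

where $T_m$ is the melting point (the midpoint of the denaturable
fraction), $b > 0$ the transition slope in 1/&deg;C and $p \in [0, 1)$ a
non-denaturable plateau. The model is the simplest monotone sigmoid with an
interpretable midpoint; a reciprocal-Kelvin variant would behave almost
identically over the 15&ndash;20 &deg;C spans involved here and is not
implemented.

In the pooled-temperature (PISA) variant of the assay, aliquots heated to a
narrow ladder of temperatures &mdash; 51&ndash;56 &deg;C in 1 &deg;C steps
by default, a window chosen to straddle the typical mammalian melting point
&mdash; are pooled before quantification, so each sample measures an
integral proxy of the melting curve. `pisa_value()` implements pooling as
the arithmetic mean of $f$ over the window; the sum differs only by a
constant factor that cancels in every log-ratio, and the mean keeps the
value interpretable as a fraction. A positive shift $\Delta T_m$ raises the
window mean, and the log2 ratio of treated to control pooled signal is
strictly increasing in $\Delta T_m$ whenever the window overlaps the
transition &mdash; the monotonicity that makes the pooled single-number
readout a usable surrogate for curve-level analysis.

## What the generator simulates, and what it does not

Every stage of the pipeline is testable without raw mass-spectrometry data
because `sample_proteome_model()`, `apply_treatment_effect()` and
`simulate_pisa_dataset()` generate ground-truth-labelled experiments with
the statistical structure the analysis assumes:

* melting points from a normal distribution truncated to [40, 70] &deg;C
  (defaults: mean 52.5, sd 2 &deg;C, centring the 51&ndash;56 &deg;C
  window on the typical $T_m$); slopes log-normal around 1/&deg;C, giving
  transition widths of a few degrees; plateaus uniform on [0, 0.2];
* base abundances log-normal over several orders of magnitude, as reporter
  intensity distributions are;
* a minority substrate subset (default 5%) with positive $\Delta T_m$
  drawn around +1.5 &plusmn; 0.5 &deg;C, emulating the minority of the
  proteome that gains stability when a methyl-transferase is inhibited, and
  a disjoint subset with log2 abundance effects, emulating expression
  changes that masquerade as destabilization;
* multiplicative log-normal noise per measurement, parameterized by a
  coefficient of variation (default 8% for the pooled assay, 5% for
  spike-in gradients) because reporter-ion noise scales with signal;
* a 3-vs-3 replicate design by default, with the unbalanced 3-vs-2 design
  of the abundance arm supported.

The stability channel of a treated replicate is
`base_abundance` &times; abundance effect &times; window-mean melting
fraction (with the shift applied) &times; noise; the abundance channel
omits the melting term. A pure abundance change therefore propagates
*equally* into both channels &mdash; exactly the signature the joint
classifier uses to discount it.

Deliberately not simulated: peptide-to-protein roll-up, missing values
(the analysis has a complete-case contract), TMT channel interference, and
co-isolation artefacts. Passing recovery tests on this generator therefore
demonstrates that the statistics behave as designed under the assumed noise
model, not that they are robust to every pathology of real data.

Seeds are explicit arguments everywhere; the generators save and restore
the global RNG state, so they are pure functions of their arguments.

## Differential testing with abundance decoupling

Matrices are normalized by median-centring each sample to the global
median and then subtracting a locally weighted regression (span 0.4,
tricube weights, two robustness iterations, cycled three times so the
corrections do not leak through the row means) of each sample's deviation
against the row-mean intensity &mdash; the standard cure for
intensity-dependent bow in reporter data.

`moderated_t_test()` implements the empirical-Bayes moderated t-test: the
per-protein pooled variance $s_g^2$ on $d_g$ degrees of freedom is shrunk
toward a prior $(d_0, s_0^2)$ estimated by matching the observed moments of
$\log s_g^2$ to a log scaled-F distribution, with $d_0$ found by Newton
inversion of the trigamma function. Forcing `prior_df = 0` recovers the
ordinary pooled t-test exactly (the test suite asserts agreement to 1e-9);
forcing `prior_df = Inf` gives a common-variance statistic; the estimated
prior reproduces limma's to within a percent on the same data, which the
suite verifies against limma directly. A variance floor of 1e-12 is applied
before log-moment estimation so that noise-free (simulated) data flow
through with a warning instead of a degenerate-input error.

Regulation is called by the standard PISA rule &mdash; |log2 ratio| > 0.1 and
p < 0.01 &mdash; with Benjamini-Hochberg FDR reported alongside, so either
convention (raw-p rule or FDR &le; 5%) can be audited; the package does not
decide which the reader should prefer. Joint classification then separates
`stability_only` changes from `abundance_only`, `concordant_both` (both
channels regulated, same sign, effects within a 0.1 log2 margin &mdash;
read as abundance-driven, as with mitochondrial proteins whose apparent
destabilization is an expression change) and `discordant` patterns.
Consensus across treatments is the set intersection of per-treatment
calls, matching the "in common" presentation of two-inhibitor designs;
per-treatment tables are always retained so unions can be formed.

## Curve-level comparison (NPARC-style)

For spike-in gradient experiments, `fit_melting_curve()` performs bounded
multi-start least squares ($T_m \in [35, 75]$, slope $\in (0, 5]$, plateau
$\in [0, 0.5]$; starts on a 2 &deg;C $T_m$ grid; L-BFGS-B with analytic
gradients; ties broken by lowest RSS then lowest $T_m$), and
`nparc_compare()` runs the nested F-test: one shared curve (3 parameters)
against per-condition curves (6 parameters),

$$ F = \frac{(RSS_0 - RSS_1)/3}{RSS_1/(n - 6)}. $$

Theoretical F degrees of freedom are used; the empirical-df moderation of
the original curve-comparison method is out of scope. This is adequate at
this scale: on the five-temperature, two-replicate design the simulated
type-I error at $\alpha = 0.05$ is 0.034 (1000 null pairs) with the
boundary constraints making the test mildly conservative, and power
against a +2 &deg;C shift at 5% CV exceeds 0.95. When both models fit
perfectly (identical noise-free curves) the test reports $F = 0$, $p = 1$;
when only the alternative is perfect it reports $p = 0$ with a
perfect-fit flag. Gradient tables can be normalized against a carrier
proteome (median ratio of carrier proteins to their across-replicate mean,
per temperature/replicate) or per protein to the lowest-temperature mean;
the original spike-in study does not state which was used, so both paths
are exposed and neither is asserted as canonical.

## Set statistics

`overlap_test()` computes the upper-tail hypergeometric probability in log
space, so tails far below the smallest representable double (the benchmark
two-inhibitor overlap is p &asymp; 8e-331) are reported exactly as log10
values, along with the representation factor $kN/(Kn)$. The figure legends
label this test two-sided; the upper tail is the only direction meaningful
for an enrichment and is what is computed &mdash; at these magnitudes the
distinction is immaterial. `rank_shift_test()` wraps the exact/approximate
rank-sum and signed-rank machinery used for subset-shift questions
(methylated proteins vs the proteome; stability vs abundance columns).
`preranked_enrichment()` implements the weighted running-sum enrichment
score (verified to machine precision against fgsea's statistic), with
member-set (gene) permutation for the null &mdash; a pre-ranked analysis
has no sample labels to permute &mdash; and same-sign normalization for
the NES. The permutation p-value is computed against the same-sign portion
of the permutation null with an add-one correction, the convention under
which null p-values are uniform; numeric NES equality with external GSEA
software is deliberately not claimed, only null calibration (mean |NES|
within 1 &plusmn; 0.15, uniform p) and constructed-extreme behaviour.

## Methyl-site annotation

`classify_arg_motif()` classifies arginine sites by glycine context:
`non_rg` when the next residue is not glycine, `canonical_rg` when the
site's RG/RGG unit chains with at least one additional unit within 10
residues at inter-unit spacers of at most 4, `noncanonical_rg` for
isolated RG. The literature does not fix a precise boundary between
canonical and non-canonical RG, so all three knobs (`max_spacer`,
`min_repeats`, `window`) are arguments, letting the reported
10%/25%/65% style splits be explored rather than asserted; only
R-followed-by-G contexts count, with glycine-preceding (GR) contexts
excluded by a documented choice. Positions are 1-based throughout and
flanks truncate at sequence ends without padding.

`estimate_occupancy()` estimates fractional site occupancy from the
depletion of the unmodified counterpart peptide,
$\theta = 1 - (U_{test}/L_{test})/(U_{ref}/L_{ref})$, clamped to [0, 1].
Only the unmodified form enters, so modified-peptide response factors
cancel; a response-factor-corrected modified/(modified+unmodified)
estimator would need calibration standards and is out of scope. At 5%
measurement CV the estimator's mean error is below 0.025 across
$\theta \in \{0.2, 0.6, 0.9\}$ (the absolute per-draw noise scales with
$1-\theta$, so high-occupancy sites are estimated most precisely).

## Numerical choices and problem sizes

* Curve fits: convergence by L-BFGS-B's gradient criterion (factr 1e2,
  maxit 500 per start); degenerate flat data fit with a near-zero
  transition and flagged by inspection of the fitted range rather than
  erroring.
* The trigamma inversion uses Newton steps on the near-linear reciprocal
  scale, with closed-form guards for extreme arguments.
* Enrichment rankings break score ties lexicographically by protein id so
  results are deterministic.
* P-values from extreme hypergeometric tails are carried as log10 values
  in parallel with the (possibly subnormal or zero) probability.

Simulation-based checks in the test suite use 2000-protein proteomes for
the pooled-assay analyses, 1000 null pairs and 200 alternative pairs for
the curve-comparison calibration, 100 seeds per occupancy level and
10,000 random 30-mers for the motif-classifier/oracle equivalence; these
sizes give Monte-Carlo standard errors comfortably below the margins being
asserted while keeping the default suite fast.

## Known limitations

* The two-treatment consensus (intersection) is intentionally
  conservative: with ~85% per-treatment sensitivity near the detection
  limit, intersecting calls yields ~75% consensus sensitivity at
  essentially zero false-discovery proportion. Union or meta-analytic
  pooling would trade the other way; only the intersection is provided
  because it matches the presentation the design emulates.
* Complete-case only: rows with missing values must be filtered before
  normalization; no imputation is offered.
* The F-test's theoretical degrees of freedom are slightly conservative
  under the bounded fits at very small $n$.
* The generator's noise is independent across proteins; correlated
  (co-complex) noise structure in real data will make naive FDR slightly
  optimistic.

## A worked example

```{r example, eval = FALSE}
model <- sample_proteome_model(2000, seed = 0)
eff <- apply_treatment_effect(model, frac_stabilized = 0.05,
                              mean_delta_tm = 1.5, seed = 0)
d1 <- simulate_pisa_dataset(model, eff,
                            experiment_design(noise_cv = 0.08, seed = 1))
d2 <- simulate_pisa_dataset(model, eff,
                            experiment_design(noise_cv = 0.08, seed = 2))
wf <- run_pisa_workflow(list(GSKa = d1, GSKb = d2))
print(wf)
summary(wf)
```
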