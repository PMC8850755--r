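---
title: "Targeted plasma lipidomics around myocardial reperfusion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted plasma lipidomics around myocardial reperfusion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidflux)
```

## The problem

In patients with ST-segment elevation myocardial infarction (STEMI),
restoring coronary flow by percutaneous coronary intervention (PCI) sets
off large, fast shifts in the circulating lipidome. Quantifying those
shifts — and asking which lipid species track the magnitude of myocardial
injury — requires a chain of computations: targeted multiple-reaction-
monitoring (MRM) peak areas must be turned into semi-quantitative
concentrations, cleaned of instrument drift, filtered for reproducibility,
and only then fed into repeated-measures and regression statistics.
`lipidflux` implements that chain as a tested pipeline, together with a
synthetic study generator that emulates the acquisition design closely
enough that every downstream stage can be validated without access to any
deposited patient data.

The study design the package assumes: STEMI subjects sampled pre-PCI (t0),
2 h post-PCI (t1) and 24 h post-PCI (t2), a subset followed to 48 h (t3)
and 30 days (t4); a control group sampled once; myocardial injury
summarized per subject as delta troponin, the peak minus baseline cardiac
troponin T over the serial draws.

## Semi-quantitation

Each lipid class carries a spiked internal standard (ISTD) that is not
present endogenously (odd-chain or short-chain species). Quantitation is
the ratio rule

$$ c_{s} \;=\; \frac{A_{s}}{A_{\mathrm{ISTD}(\mathrm{class}(s))}}
   \cdot c_{\mathrm{ISTD}} \;/\; \mathrm{CF}(s) \;/\; \mathrm{RF}(s), $$

with two class-specific corrections:

* **Acyl-chain correction factors (CF)** for DG/TG, whose ammoniated
  adducts fragment by acyl loss. A species with $k$ distinct, equally
  likely acyl losses retains only a fraction of its signal in the single
  monitored transition: CF = 0.5 for DG with two distinct chains, 0.33 for
  TG with three distinct chains, 0.66 for TG with exactly two identical
  chains, and 1 otherwise. The measured ratio is **divided** by CF. The
  source convention ("a correction factor was applied") does not state
  multiply-vs-divide; division is chosen because it makes CF = 1 the no-op
  and scales split-signal species *up*, which is the physically coherent
  direction. `quantify()` exposes `cf_overrides` so a user can assert
  chain-resolved factors for species reported at sum-composition level.
* **Response-factor lines (RF)** for cholesteryl esters, fitted on an
  equimolar calibrant mixture and selected purely by double-bond count:
  saturated $y = 0.13x - 0.71$, monounsaturated $y = 1.13x - 0.23$,
  polyunsaturated $y = -0.07x + 1.54$, with $x$ the fatty-acyl chain
  length. The lines are used exactly as printed. Two caveats are inherent
  to them: the monounsaturated line yields far larger factors than the
  saturated one at equal $x$ (possibly a transcription artifact in the
  source; we do not second-guess it), and the polyunsaturated line is
  non-positive at $x \ge 22$, so `ce_response_factor()` raises an error
  there and the packaged panel contains no polyunsaturated CE species with
  chains of 22 or more carbons.

**Deisotoping.** Within a class, the M+2 isotopologue of a species
co-elutes with the monoisotopic peak of the species with the same carbon
count and one fewer double bond. With $C$ the full molecular carbon count
(total acyl carbons plus a per-class backbone contribution, packaged as
configuration) and $a = 0.0107$ the natural ¹³C abundance, the interfering
fraction is $p_2 = \binom{C}{2} a^2$. Species are processed in decreasing
double-bond order so that each interferent has already been corrected when
it is subtracted; negative corrected areas are clipped to zero and
flagged. The recursion is verified in the tests against an independent
matrix solve of the same linear system.

**Fatty acids** are monitored by two transitions differing only in
collision energy; the qualifier/quantifier area ratio is a per-species
constant established on pooled-QC injections, and `fa_qualifier_check()`
flags measurements deviating more than ±50% (relative) from it.

## Drift normalization and QC filtering

Each analytical batch contains 60 study samples, 20 pooled-plasma QCs
(PQC), 6 matrix-free technical QCs, 4 reference-material injections and 12
blanks; ten PQCs open each batch and the remainder are interleaved at one
PQC per ten study samples. `serrf_normalize()` removes injection-order and
batch effects with a QC-anchored random forest: per species, a forest
(default 500 trees) is trained on the PQC injections to predict log
concentration from injection order, batch, and the log concentrations of
the `k = 10` most PQC-correlated other species; the fitted systematic
component scales every injection by `median(PQC)/predicted`, and PQC
medians are preserved exactly afterwards.

One implementation detail matters a great deal: companion-species features
are standardized **separately within the PQC stratum and within the
remaining injections** before training and prediction. Without this, the
forest learns the drift co-movement on PQCs but, applied to study samples,
tracks their shared biological shifts (e.g., a whole class moving between
timepoints) and divides part of the real signal away — we measured 30–65%
attenuation of planted class-level effects. With stratified scaling only a
companion's position within its own stratum (its drift component) enters
the prediction, and planted effects pass through essentially
unattenuated. A deterministic per-species/per-batch loess fit against
injection order (`loess_normalize()`) implements the same contract and is
the automatic fallback when a batch has fewer than five PQCs.

After normalization, a species is **retained** only if its coefficient of
variation across PQCs is below 20% and its highest sample-type mean is not
in the blank extracts (`qc_filter()`; the filter is monotone in the
threshold). `pca_qc()` projects the run onto two principal components and
reports the within-type dispersion of replicate injections relative to the
overall dispersion — tight PQC/SRM clustering is the criterion for a
usable run. The CoV is computed on normalized values (the filter follows
batch correction in the workflow); a pre-normalization CoV can be obtained
simply by calling `qc_filter()` on the unnormalized table.

## Temporal statistics

Concentrations are natural-log transformed before testing (non-positive
values get half-minimum imputation per species); percent differences are
reported on the raw scale as $100 (\bar c_b - \bar c_a)/\bar c_a$ with a
subject-bootstrap SEM (2000 draws, seeded). Per species,
`rm_anova_gg()` runs the one-way within-subject ANOVA: F from the standard
decomposition, sphericity handled by the Greenhouse–Geisser
$\hat\varepsilon$ estimated from the sample covariance matrix of the
timepoint measurements (clamped to $[1/(k-1), 1]$), p-value from
$F(\hat\varepsilon(k-1),\ \hat\varepsilon(k-1)(n-1))$. Pairwise
timepoint contrasts are paired t-tests with Bonferroni correction.

The Bonferroni family is the set of pairwise comparisons *within a
species* (m = 3 for three timepoints) — the reading most consistent with
"pairwise comparisons after Bonferroni correction"; a study-wide family
(multiplying additionally by the number of species) would conflate the
per-species repeated-measures question with discovery-set control and is
deliberately not the default. This is the most consequential analysis
ambiguity in the pipeline and is therefore stated loudly here. Complete
cases only, per species; no imputation of missing timepoints.

Composition analysis (`within_class_log_ratio()`) normalizes each species
to its per-sample class total and reports log2 ratios of mean shares
against t0 — base 2 chosen as the field's convention for fold displays.
Heatmap data use Euclidean distance with complete linkage on log rows, the
defaults of the clustering tool the field reaches for.

## Injury associations

`delta_troponin()` is peak minus baseline over the serial draws (peak
includes the baseline, so the value is never negative; an optional window
restricts the peak search, default unrestricted).
`adjusted_regression()` is OLS of delta troponin on one log lipid plus
age, sex (0/1), BMI, current smoking (0/1), diabetes history (0/1) and
ischemic time in minutes; it reports the unstandardized coefficient B with
t-based 95% CI and flags condition numbers above $10^8$. **No
multiplicity correction is applied across species in this screen** — it
reports raw p-values, in deliberate contrast to the corrected
repeated-measures screen. Tertile stratification puts boundaries at the
empirical 33.3/66.7 percentiles, compares top vs combined middle+bottom,
and assigns boundary ties to the lower group (80 distinct subjects split
27 vs 53). Group contrasts are log2 fold changes of raw-scale means with
Student's unpaired t-test on logs. Late-phase trajectories run the
five-timepoint repeated-measures ANOVA on the followed subset with
baseline-anchored Bonferroni pairwise stars (m = 4, thresholds
0.05/0.01/0.001).

## The synthetic study generator

The generator is first-class, tested code; its defaults *are* the study
conditions everything else is validated under.

* **Cohort**: 80 STEMI + 50 control subjects, 30 followed late; covariates
  drawn to match the cohort profile (age ≈ 64 ± 12, two-thirds male,
  BMI ≈ 28, smoking 27.5% vs 12%, diabetes 20% vs 14%, ischemic time
  log-normal around 150 min).
* **Concentrations**: per-species base levels spread log-normally
  (sdlog 0.8) around class means and rescaled so class totals implement
  the plasma abundance ranking (top: CE > PC > PC(O) > LPC > SM; bottom:
  acylcarnitine < Hex3Cer < LPC(O) < GM3 < PE(P)). Between-subject CV 30%
  and residual within-subject CV 10% are assumptions (the source states no
  inter-subject variance) and are exposed as `ground_truth()` arguments.
* **Planted temporal effects** mirror the reperfusion phenotype: most
  classes ×0.8 at t1; DG ×0.70 at t1 then ×1.64 from t1 to t2;
  TG ×0.76 then ×1.59; FA falling to ×0.255 by t2; OxPL ×1.3 at t1;
  acylcarnitine and LPC reaching a nadir at 48 h. Phospholipid classes
  remain at ×0.8 at t2 while PC/CE/sphingolipid classes return to
  baseline, so 175/322 ≈ 54% of species are genuinely altered between t0
  and t2.
* **Planted injury associations**: delta troponin is simulated as a
  baseline plus planted coefficients times centered log baseline lipid
  levels plus Gaussian noise (acylcarnitine 18:2 +1800, TG 51:0 −1500,
  LPC 17:1 −1400 ng/L per log-unit, several smaller effects, noise sd
  900 ng/L). These magnitudes are a design condition: they place the
  marker associations in the $|t| \approx 2\text{–}3$ regime that
  significant findings in an 80-subject cohort imply, so that sign
  recovery across seeds is a meaningful property rather than a coin flip.
  MACE is sampled with probability increasing in standardized delta
  troponin; STEMI-vs-control folds (acylcarnitine class ×1.5, LPC class
  ×1.3, markers higher still; TG 51:0 deliberately at ×1, as a marker
  that does *not* separate the groups) are planted on the baseline draw.
* **Acquisition**: areas are the exactly invertible image of the true
  concentrations (`conc / ISTD_conc × base × CF × RF`) times a per-batch
  smooth logistic drift over injection order (amplitude 0.3 by default,
  class-correlated with per-species jitter, plus per-batch-and-species
  offsets) times multiplicative log-normal noise (CV 15%). PQCs are the
  pooled mean of all study samples; TQCs carry only ISTDs; SRM injections
  use a fixed reference profile; blanks carry 0.5% carryover. M+2
  interference is added between same-class species one double bond apart,
  and explicit M+2 rows are emitted for the most abundant fifth of the
  panel. With drift amplitude and noise both zero the full
  quantify∘deisotope pipeline reproduces the ground truth to within 1e-9
  relative — the identity contract the tests pin.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: chromatographic peak shape and integration
error, retention-time drift, ion suppression by co-eluting matrix,
isomeric overlap within a sum-composition species, non-multiplicative
(saturation) detector behavior, missing clinical covariates, and
correlated biology across species beyond the class-level planted effects.
All randomness flows from one master seed through named streams
(`stream_seed()`), so stages can be re-run independently and a fixed seed
gives bit-identical tables.

## Numerical choices and degenerate inputs

Zero within-subject variance returns F = 0, p = 1 rather than 0/0; fewer
than three complete subjects flags `insufficient_n` instead of erroring;
an all-tied tertile split is flagged `degenerate`; a missing or zero ISTD
area makes that sample's class concentrations missing and flagged — never
silently dropped; t-tests on degenerate (constant) groups return NA
p-values. Half-minimum imputation is applied only immediately before
log-transformation for statistics, never stored back into concentration
tables. The packaged m/z values are approximate configuration data and
take no part in any computation.

## Problem sizes used in validation

The test-suite simulations are sized to give stable answers at interactive
runtimes: the full default study (80+50 subjects, 322 species, 6 batches)
is generated and pushed through the complete pipeline once per run; the
null calibration of the repeated-measures pipeline uses 1000 replicates at
n = 20, k = 3; the regression parameter-recovery simulation uses 500
replicates at n = 80; sphericity behavior uses 20 replicates at n = 200;
marker sign-recovery is checked over 12 generator seeds at the
latent-state level (with measurement noise applied) plus the full-pipeline
run. Per-seed sign recovery of all three planted markers in both the
regression and tertile analyses is by design a ≈90% event, so the
single-seed end-to-end check requires at least five of the six sign
comparisons to agree while the multi-seed rate is asserted separately.

## Known limitations

Semi-quantitation is relative to class ISTDs, not absolute
external-calibration quantitation. The packaged panel is a representative
reconstruction (25 classes, 322 species, the named species of interest
included); it is not a verbatim copy of any instrument method, and its
class membership — not its m/z values — is what the pipeline consumes.
The headline numbers of the original deposited dataset (291 species
retained, 56% altered within 24 h, the class-level percent differences)
require the MetaboLights download and are encoded as accession-gated
regression tests (`LIPIDFLUX_MTBLS3839_DIR`); the synthetic study
reproduces their *shape*, not their values. Mixed-effects longitudinal
modeling, survival analysis and any causal interpretation are out of
scope.
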