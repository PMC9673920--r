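---
title: "Glycoform-resolved pharmacokinetics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glycoform-resolved pharmacokinetics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycopk)
```

## The method

Glycoform-resolved PK analysis multiplies, per animal and time point, the
compositional glycosylation profile of the circulating antibody by its
total serum concentration,

$$C_g(t) = f_g(t)\, C_\mathrm{total}(t),$$

and evaluates each glycoform's concentration-time series by
non-compartmental analysis (NCA). Since $\sum_g f_g = 1$ by construction,
glycoform concentrations conserve the total exactly, and with the linear
trapezoid rule the glycoform AUCs add up exactly to the total AUC — two
identities the test suite asserts to machine precision.

Clearance uses glycoform-specific dose adjustment: the glycoform's share of
the injected dose is taken from the profile measured in serum spiked with
the dosing material (10 µg/mL), so that

$$\mathrm{dose}_g = \mathrm{dose}_\mathrm{nominal}\cdot f_g(\mathrm{standard}),
\qquad
CL_g = \frac{\mathrm{dose}_g}{\mathrm{AUC}_{\infty,g}/24}
\ \left[\mathrm{mL/day/kg}\right].$$

After subcutaneous (SC) dosing only the apparent clearance $CL/F$ is
identifiable ($F$ = bioavailability); the package reports it in the same
column with a `clearance_label` of `"CL/F"` and never attempts to resolve
$F$ itself.

Two statistical layers sit on top:

* **Clearance contrasts.** Within one experimental group every glycoform is
  compared with a reference glycoform (default G0F) by a two-sided *paired*
  t test across animals — pairing by animal cancels the large
  inter-individual PK variability. Benjamini–Hochberg step-up control at a
  5% FDR is applied per experimental group (one preparation × route), the
  family being all contrasts computed in that group. Significance stars use
  the conventional tiers (`**` p < 0.01, `***` p < 0.001, `****`
  p < 0.0001), awarded only to FDR-significant contrasts.
* **Serum-profile comparisons.** At a fixed time point (default 24 h, the
  SC Tmax) glycoform fractions are compared between groups by unpaired
  Welch t tests, BH-adjusted across glycoforms. A parallel comparison of the
  spiked standards measured with each batch screens out analytical batch
  effects: a glycoform is flagged *PK-specific* only when the serum
  comparison is significant and the standard comparison is not, and
  *batch-effect* when both are.

### Assumptions

* Profiles are compositional and reliable above ~1 µg/mL total antibody
  (`profile_loq_ug_ml`); below that, or below the ELISA LLOQ, points are
  excluded rather than imputed.
* The analysis window (default 240 h) exists to avoid anti-drug-antibody
  interference appearing after about a week; later samples are dropped
  even if quantifiable.
* NCA is model-free: no compartmental structure is assumed beyond a
  log-linear terminal phase for extrapolation.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `reference_glycoform` | G0F | — | dominant agalactosylated fucosylated glycan of CHO material; present in every animal |
| `analysis_window_h` | 240 | h | 10-day window avoiding anti-drug antibodies |
| `background_fraction` | 0.3 | — | fraction of the reported LC-MS background subtracted in addition to the automatic subtraction; calibrated on spiked dilution series to remove concentration-dependent inflation of minor glycoforms |
| `lloq_ng_ml` | 7 | ng/mL | ELISA lower limit of quantitation |
| `profile_loq_ug_ml` | 1 | µg/mL | lowest total concentration with reliable glycosylation profiles |
| `fdr` | 0.05 | — | BH false discovery rate per experimental group |
| `trapezoid_rule` | linear | — | preserves exact glycoform additivity of AUC; `lin-up-log-down` available |
| `lambda_z_min_points` | 3 | — | minimum terminal points for the λz fit |

## The synthetic study generator

`generate_study()` emulates a minipig single-dose experiment: 5 animals per
group, IV bolus sampled at 0.08–168 h or SC first-order absorption sampled
at 2–240 h, one glycoform mixture injected per group.

**Kinetics.** One-compartment disposition with glycoform-specific
elimination $k_g = CL_\mathrm{ref}\, m_g / V$. The defaults,
$V = 50$ mL/kg and $CL_\mathrm{ref} = 0.9$ mL/day/kg at a 0.5 mg/kg dose,
give an initial IV concentration of 10 µg/mL and an SC Cmax near 5 µg/mL at
24 h ($k_a = 6$/day, $F_\mathrm{base} = 0.5$) — the magnitudes a minipig
mAb study shows. Clearance multipliers $m_g$ default to the field's
qualitative ordering: oligomannose 1.20, monoantennary 1.08,
monogalactosylated 0.92, fully galactosylated or sialylated 0.85. The
one-compartment choice buys exact closed-form oracles
($\mathrm{AUC}_\infty = F_g\,\mathrm{dose}_g / CL_g$) for every recovery
test; it deliberately omits the distribution phase of real antibody
kinetics (see Limitations).

**SC absorption bias.** Serum profiles after SC dosing are shifted toward
galactosylated glycoforms around Tmax. The generator implements the simplest
mechanism consistent with that observable, a galactose-dependent
bioavailability
$$F_g = \min\!\left(1,\ F_\mathrm{base}\,(1 + \beta\, n_\mathrm{gal}(g)/2)\right),$$
rather than a tissue-clearance mechanism — the two are indistinguishable
from serum data. The default $\beta = 0.46$ was solved analytically so that
the default CHO-like formulation shifts serum galactosylation by ≈3.5
percentage points at 24 h: with formulation galactosylation 0.175, requiring
$(0.175 + 0.1125\beta)/(1 + 0.175\beta) = 0.210$ gives $\beta = 0.462$.

**Observation noise.** ELISA error is mean-preserving multiplicative
log-normal with CV `elisa_cv` (default 0.10, a typical immunoassay
proportional error); concentrations below 7 ng/mL are censored. LC-MS
signals get proportional noise with CV `intensity_cv` (default 0.05, chosen
so replicate serum profiles scatter on the percentage-point scale that
published serum-profile comparisons show at n = 5) plus a planted background
interference: a fraction (default 0.3) of the per-analyte background leaks
into each signal, and the background is reported alongside, exactly the
situation `correct_background()` addresses. The generator's spiked-standard
replicates are measured with the same LC-MS noise, so dose adjustment and
batch-effect screening inherit realistic uncertainty.

**What it does not emulate.** No inter-animal variability in CL or V (all
structure is observational noise), no target-mediated (nonlinear)
elimination, no anti-drug-antibody time course, no multi-dose designs, no
isotopologue-level spectral artifacts. Passing recovery tests therefore
demonstrate correctness of the computation, not robustness to biological
model misspecification.

## Numerical choices

* **λz window selection.** Candidates are the last $k$ points,
  $k \ge 3$, among points at/after Tmax (strictly after Tmax for SC data);
  non-positive concentrations are excluded, windows with non-negative slope
  are invalid, and the window with the highest adjusted $R^2$ wins, ties
  going to the longer window — the documented "best fit" convention of
  standard NCA software.
* **AUC.** Linear trapezoid by default (exact glycoform additivity);
  lin-up/log-down optional. For SC series a (0, 0) anchor is prepended
  (concentration is zero at the moment of dosing); for IV the curve is not
  back-extrapolated before the first sample (0.08 h ≈ 5 min post-bolus,
  negligible area). `AUC∞ = AUC_last + C_last/λz`; series with more than 20%
  extrapolated area are flagged with a warning, not an error.
* **Background correction** clamps at zero: `max(0, I − 0.3·B)`.
* **Profile scales.** Percent-scale profiles (per-sample sums near 100) are
  detected and rescaled; every profile is renormalized to sum exactly 1, and
  per-sample sums outside [0.95, 1.05] (or [95, 105]) are errors, since they
  indicate missing or duplicated glycoforms rather than rounding.
* **Degenerate statistics.** Zero-variance paired differences yield a
  flagged degenerate result (p = NA), never p = 0; untestable contrasts
  (fewer than 2 paired animals with estimable clearance) are reported with
  NA and excluded from the BH family rather than aborting the group.

## Design choices on genuinely open points

* **Trait formulas.** Galactosylation and sialylation are computed per
  antenna ($\sum_g f_g\, n_{gal}(g)/2$) over *all* quantified glycoforms,
  oligomannose species included in the denominator. This inclusive
  convention reproduces the published percentage scale for CHO-type
  profiles; revisit against per-animal supplementary data if those are
  loaded.
* **H6N4F1S2** is registered by composition only (treated as diantennary,
  digalactosylated, disialylated, fucosylated); its structural assignment is
  unresolved and the attributes are provisional.
* **"Total" clearance** is computed from the unsplit total concentrations
  with the full nominal dose (a dose-weighted combination of glycoform
  results is the alternative; the two coincide exactly under the linear
  trapezoid when no profile is missing).
* **Star tiers** are interpreted as p below the cutoff (0.01, 0.001,
  0.0001); published footnotes sometimes print the inequality inverted.
* **Two-sided tests** throughout, since glycoform effects run in both
  directions.
* The **command-line interface** is a thin `Rscript`
  (`inst/cli/glycopk.R`, subcommands `simulate`, `run`, `report`) over the
  exported functions `cmd_simulate()`, `cmd_run()`, `cmd_report()`; the R
  functions are the tested surface.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles: hand
trapezoids and closed-form exponential integrals, quadrature
(`stats::integrate`) against the analytic SC AUC, brute-force paired/Welch
t statistics via the incomplete-beta tail, exhaustive BH threshold search,
and truth tables of noise-free synthetic studies (recovery to < 0.5%).
Simulation-based checks use 50 replicate studies for multiplier recovery,
200 for error control (FDR under the global null, power for a planted 1.2×
multiplier), 20 IV/SC study pairs for the serum-profile shift, and 1000
draws for noise-calibration and λz-bias checks — sizes chosen so the whole
suite completes in minutes while keeping Monte-Carlo error well below the
tolerances tested.

## Known limitations

* **Extrapolation-dominated AUC at realistic antibody kinetics.** With
  CL ≈ 0.9 mL/day/kg and V ≈ 50 mL/kg the half-life is about 38 days, so
  ~87% of AUC∞ lies beyond a 7–10-day sampling window and per-animal
  clearance rests almost entirely on $C_\mathrm{last}/\lambda_z$. The
  terminal decline inside the window (~12%) is then comparable to a single
  10% assay error, λz is barely identifiable per animal, and best-fit
  window selection inflates it; per-animal glycoform clearances and their
  ratios become imprecise and biased. The acceptance script quantifies
  this honestly: noise-free recovery is essentially exact, while mean
  multiplier recovery and contrast power at 10% assay noise fail their
  nominal targets. Real studies escape this regime because actual antibody
  kinetics are multiphasic (concentrations halve within the first day via
  distribution/target-mediated disposition), concentrating information in
  the observed window — exactly the structure the one-compartment generator
  omits.
* Compositional profiles mean only *relative* glycoform information enters;
  an effect shared by all glycoforms is invisible.
* Bioavailability is never resolved after SC dosing; SC/IV clearance
  comparisons confound clearance and absorption.
* The batch-effect screen requires standards measured in the same
  analytical batches as the samples; without them every significant serum
  difference is reported unscreened.
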