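# glycopk

Glycoform-resolved pharmacokinetics (PK) of therapeutic monoclonal
antibodies.

## The problem

The Fc N-glycan of an IgG antibody influences how fast the antibody is
cleared from circulation: oligomannose glycoforms (e.g. Man5) clear faster
than complex-type glycoforms, monoantennary glycoforms moderately faster,
and galactosylated/sialylated glycoforms can clear more slowly. Detecting
these effects from total drug concentrations alone is nearly impossible
because inter-animal variability in clearance dwarfs the glycoform effect.

Glycoform-resolved PK solves this by combining two measurements of the same
serum samples:

* the **relative glycosylation profile** of the circulating antibody
  (LC-MS glycopeptide quantification; compositional fractions
  `f_g(t)` summing to 1), and
* the **absolute total antibody concentration** `C_total(t)` (ELISA).

Their product gives per-glycoform concentration-time curves

```
C_g(t) = f_g(t) · C_total(t)
```

which are evaluated by standard non-compartmental analysis (NCA): terminal
slope λz by best-fit log-linear regression, `AUC∞ = AUC_last + C_last/λz`,
and clearance with glycoform-specific dose adjustment from a spiked serum
standard:

```
dose_g = dose_nominal · f_g(standard)          [µg/kg]
CL_g   = dose_g / (AUC∞,g / 24)                [mL/day/kg]
```

(CL after IV bolus; apparent clearance CL/F after subcutaneous dosing).
Because all glycoforms of one preparation travel in the same animal,
within-animal ratios `CL_g / CL_reference` and paired t tests across animals
cancel inter-individual variability. Benjamini–Hochberg adjustment at a 5%
FDR controls multiplicity per experimental group. Serum profiles at a fixed
time point are compared between routes with Welch t tests, using spiked
standards measured in each batch to screen out analytical batch effects.

The package also ships a synthetic single-dose study generator
(one-compartment IV bolus and first-order SC absorption, glycoform-specific
clearance multipliers, galactose-biased SC bioavailability, ELISA and LC-MS
noise with background interference, LLOQ censoring) so that every stage of
the pipeline can be validated against known truth.

## Worked example

Simulate a noise-free IV study at the default study conditions (5 animals,
0.5 mg/kg, sampling 0.08–168 h, CHO-like formulation: G0F 60%, G1F 25%,
G2F/Man5/G0F-N 5% each) and run the full analysis:

```r
library(glycopk)

study <- generate_study(
  study_design(route = "IV"),
  pk_parameters(),
  noise_model(elisa_cv = 0, intensity_cv = 0, background_level = 0,
              background_cv = 0, interference_fraction = 0, seed = 1)
)
res <- nca_study(study$profiles, study$concentrations, study$dose, quiet = TRUE)
res[res$animal_id == "A01", c("glycoform", "cmax_ug_ml", "half_life_h",
                              "auc_inf_ug_h_ml", "extrap_percent",
                              "clearance_ml_day_kg")]
#>   glycoform cmax_ug_ml half_life_h auc_inf_ug_h_ml extrap_percent
#> 1 Total         10.00         937.          13521.           88.3
#> 2 G0F            6.00         924.           8000.           88.2
#> 3 G0F-N          0.500        856.            617.           87.3
#> 4 G1F            2.50        1005.           3623.           89.1
#> 5 G2F            0.500       1087.            784.           89.8
#> 6 Man5           0.500        770.            556.           86.0

summarize_normalized(normalize_to_reference(res, "G0F"))
#>   group  glycoform     n  mean    sd ci95_low ci95_high
#> 1 SYN-IV G0F           5 1         0    1         1
#> 2 SYN-IV G0F-N         5 1.08      0    1.08      1.08
#> 3 SYN-IV G1F           5 0.920     0    0.920     0.920
#> 4 SYN-IV G2F           5 0.850     0    0.850     0.850
#> 5 SYN-IV Man5          5 1.20      0    1.20      1.20
```

Reading the output: the initial total concentration is `dose/V = 10 µg/mL`;
each glycoform's Cmax is its formulation fraction times that. The
G0F-normalized clearances recover the planted clearance multipliers exactly
(Man5 1.20, monoantennary G0F-N 1.08, G1F 0.92, G2F 0.85) — the ordering
reported for IgG1 Fc glycoforms. The high `extrap_percent` (~88%) is a
genuine property of these study conditions: an antibody with CL ≈ 0.9
mL/day/kg and V ≈ 50 mL/kg has a multi-week half-life, so most of the AUC
lies beyond a 7–10-day sampling window; see the methods vignette for what
this means for precision once assay noise is present.

The same analysis runs from the command line on delimited tables:

```sh
Rscript inst/cli/glycopk.R simulate --out study/ --seed 1
Rscript inst/cli/glycopk.R run \
  --profiles study/profiles.csv --concentrations study/concentrations.csv \
  --doses study/doses.csv --standard-profile study/standard_profile.csv \
  --out results/
Rscript inst/cli/glycopk.R report --out results/
```

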