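# thyrostasis

Calculated structure parameters of thyroid homeostasis and the nonlinear
pituitary–thyroid feedback model they derive from.

Interpreting thyroid labs one hormone at a time discards the physiology
that links them: TSH drives thyroidal T4 secretion through a
Michaelis–Menten transfer, peripheral deiodinases convert T4 to T3, and T4
feeds back on the thyrotrophs through central type 2 deiodination. For
clinical researchers and laboratory scientists working on that axis, this
package turns a (TSH, FT4, FT3) panel into *structure parameters* — organ
constants obtained by inverting the feedback model at equilibrium — and
provides the forward model itself for simulation and for constructing
joint reference regions.

## What it computes

For a panel with TSH in mIU/L and free hormones in pmol/L (unit conversion
helpers included):

* **SPINA-GT**, the thyroid's secretory capacity (pmol/s):
  `GT = βT (DT + [TSH]) (1 + K41[TBG] + K42[TBPA]) [FT4] / (αT [TSH])`
* **SPINA-GD**, the sum activity of peripheral step-up deiodinases
  (nmol/s):
  `GD = β31 (KM1 + [FT4]) (1 + K30[TBG]) [FT3] / (α31 [FT4])`
* **SPINA-GTS** = GT per mL of thyroid volume; molar **T3/T4** and
  **T3/rT3** ratios
* **TSH index** `TSHI = ln[TSH] − β[FT4]` (β = −0.1345 per pmol/L) and its
  standardised form `sTSHI = (TSHI − 2.7)/0.676`, markers of thyrotropic
  pituitary function
* **TTSI** `= 100 [TSH][FT4]/lu`, a screening index for thyroid hormone
  resistance
* **repeatability** `e = var_inter/(var_intra + var_inter)` for
  repeated-measures cohorts (one-way random-effects method of moments)

Around the calculators: an equilibrium solver and RK4 simulator for the
feedback loop (including a shipped critical-illness scenario of central
hyperdeiodination), a pulsatile + circadian TSH generator with a pulse
detector, a kite-shaped bihormonal TSH–FT4 reference region with a
homeostatic classifier, and a synthetic-cohort generator with ground-truth
tables.

## Worked example

```r
library(thyrostasis)

panels <- tibble::tibble(subject_id = 1:3,
  tsh = c(1.8, 6.2, 0.4), ft4 = c(14.5, 9.8, 11.2), ft3 = c(4.2, 3.1, 3.0),
  volume = c(12, 8, NA))
calc_panels(panels, lu = 21)[, c("subject_id", "gt", "gd", "gts",
                                 "ttsi", "tshi", "stshi")]
#>   subject_id   gt   gd   gts  ttsi tshi  stshi
#> 1          1 2.78 26.8 0.232 124.3 2.54 -0.240
#> 2          2 1.07 29.2 0.134 289.3 3.14  0.655
#> 3          3 6.70 24.8    NA  21.3 0.59 -3.121
```

Subject 1 is unremarkable: a secretory capacity of 2.8 pmol/s and a
deiodinase activity of 27 nmol/s are mid-range euthyroid values. Subject 2
has a failing gland — GT of 1.1 pmol/s is low despite a TSH of 6.2 mU/L.
Subject 3's thyroid is intact (GT 6.7 pmol/s) but the TSH index of 0.59
(sTSHI −3.1) flags deficient thyrotropic drive. The bihormonal region
reads the same three pairs jointly:

```r
region <- build_region()
classify_panel(panels$tsh, panels$ft4, region)
#> [1] "euthyroid"                   "primary-hypothyroid-pattern"
#> [3] "central-hypothyroid-pattern"
```

Note that a TSH of 6.2 mU/L with FT4 13 pmol/L would still be classified
euthyroid — outside the univariate TSH band but inside the kite — whereas
the same TSH at FT4 9.8 is primary hypothyroidism.

The forward model is calibrated so its euthyroid equilibrium sits at the
reference pair, with the estimators as exact inverses:

```r
solve_equilibrium(feedback_parameters())
#> <equilibrium_point> TSH 1.5 mU/L  FT4 15 pmol/L  FT3 4.056 pmol/L
```

See `vignettes/thyroid-homeostasis-modelling.Rmd` for the model equations,
every calibration decision, and the known limitations.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package: the TTSI of a subject
whose FT4 sits exactly at the assay's upper reference limit at TSH
1 mU/L; the mean true TSH pulse amplitude over 1000 independently seeded
simulated days under the default euthyroid pulse model; and the log-linear
model coefficient recovered by finite differences from the TSH index. The
results are written as JSON to the `--out` path.
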