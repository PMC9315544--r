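---
title: "Mechanistic steady-state prediction of EGFR TKI PET tracer distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic steady-state prediction of EGFR TKI PET tracer distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbpktbr)
```

## The problem

Radiolabelled EGFR tyrosine kinase inhibitors (erlotinib, afatinib,
osimertinib) are used as PET tracers in non-small-cell lung cancer, and their
image quality differs sharply: afatinib and erlotinib show tumors brighter
than surrounding lung, osimertinib shows the opposite. `pbpktbr` implements a
mechanistic explanation: a steady-state tissue-composition PBPK model in the
Rodgers–Rowland tradition, in which each tracer's tissue-to-blood ratio (TBR)
follows from its ionization, lipophilicity, plasma binding, lysosomal
trapping and EGFR target binding, combined with the composition of each
tissue. The tumor is modelled as lung tissue transformed by NSCLC hallmarks.

## Model structure and assumptions

All predictions are closed-form. The assumptions inherited from the
underlying model family: transport is passive only, nothing saturates (PET
microdoses), the system is at steady state and well stirred, metabolism and
elimination are negligible over the scan window, and the tissue signal
contains no blood-vessel contribution. Two model classes share the water and
neutral-lipid terms and differ in the binding machinery:

* **Weak bases** (erlotinib, pKa 5.5; ~99% unprotonated in plasma): tissue
  binding is dominated by albumin. The scaled albumin association constant is
  fixed entirely by plasma binding, `Ka,ALB·[ALB] = 1/fu − 1`, and scaled by
  the albumin tissue-to-plasma ratio. Attributing all plasma binding to
  albumin (no plasma-lipid correction) is a deliberate choice: it is the
  variant that reproduces the calibrated component shares and totals.
* **Strong bases** (afatinib pKa 8.2, osimertinib pKa 9.0; mostly
  protonated): the protonated species binds acidic phospholipids (AP−) and
  accumulates in acidic lysosomes. The AP− association constant is not a free
  parameter — it is calibrated per compound from blood-cell partitioning,
  solving the blood-cell mass balance for Ka after subtracting the
  intracellular-water and neutral-lipid contributions
  (`ap_association_constant()`).

EGFR binding applies to both classes as `([EGFR]/Kd)·IF(pKa, pH_iw,
pH_p)·F_iw`, with wild-type Kd for every tissue including tumor;
mutant-affinity binding is out of scope (a known direction for extension,
not implemented). Brain and bone are assigned `[EGFR] = 0` for lack of
usable concentration data.

### Lysosomal sequestration

The lysosome-to-cytosol coefficient combines pH trapping `IF(pKa, pH_lys,
pH_iw)` with binding to the lysosomal membrane, assumed to share the
composition of the cell's outer membrane. The membrane term therefore reuses
the AP− machinery with the *tissue's own* AP− concentration. This
generalization matters: lung and tumor use cell-type-specific lysosomal
parameters (alveolar macrophages 4.1% of cells, F_lys 0.078, pH 4.75; type II
cells 8.3%, 0.03, 5.1; residual cells 87.6%, 0.01, 5.1 — the residual
fraction is 0.876 so the three sum to exactly 1), while spleen, kidney and
brain, which have no cell-type sub-table, are modelled as a single lysosomal
population at the tissue-level lysosomal volume fraction with lysosomal pH
5.3. Only with the tissue-specific membrane AP− and the 5.3 lysosomal pH do
the strong-base spleen/kidney/brain predictions land on the calibrated
values; with a fixed lung membrane (0.57 mg/g) they do not. Bone reports no
lysosomal data and gets no lysosomal term.

### Tumor hallmarks and scenarios

Tumor tissue is derived from lung: acidic extracellular water (pH 6.7 versus
7.4), immune deprivation (only the residual-cell lysosomal population
remains), elevated EGFR (299 nM), and AP−/albumin values inherited from lung
(the tumor row of the source table prints no values for them, and the
inherited values reproduce the calibrated tumor component shares). The final
model applies unaltered perfusion (`F_perf = 1`) and no vasculature
coefficient (`F_vasc = 1`); the `vascularized` ablation multiplies the tumor
prediction by 0.36, the measured microvessel-density ratio of adenocarcinoma
to normal lung. Each of the five ablation scenarios
(`ablation_suite()`) differs from the final model in exactly one field,
which the test suite asserts structurally.

## Parameters that matter

| parameter | unit | default | note |
|---|---|---|---|
| pKa | – | 5.5 / 8.2 / 9.0 | weak vs strong classification at pKa 7 |
| log P | – | 3.3 / 3.6 / 3.2 | used *directly* as the lipid affinity P |
| fu | fraction | 0.088 / 0.095 / 0.017 | fixes albumin capacity and Ka calibration |
| B:P | – | 0.95 / 1.27 / 0.79 | blood reference scaling and Ka calibration |
| Kd EGFR | nM | 2164 / 2 / 155 | wild-type affinity; tumor uses the same |
| pH plasma / intracellular | – | 7.4 / 7.0 | all tissues |
| pH blood cell | – | 7.22 | calibration chain only |
| lung pH_ew | – | 7.4 | tabulated 7.22 selectable via `default_parameters(lung_ph_ew = 7.22)` |
| tumor pH_ew | – | 6.7 | acidity hallmark; scenario-switchable |
| F_vasc / F_perf | – | 1 / 1 | 0.36 in the `vascularized` ablation |

Two conventions deserve emphasis because they deviate from textbook usage,
both selectable for comparison:

* `fraction_protonated()` defaults to the Henderson–Hasselbalch orientation
  for bases, `1/(1 + 10^(pH − pKa))`, which yields the worked percentages the
  model family quotes (erlotinib ~1% protonated at plasma pH; afatinib 86%,
  osimertinib 98%). The transcribed orientation with the exponent reversed is
  available as `orientation = "as_printed"` for forensic comparison only.
* `lipophilicity_value()` defaults to using the log P *number itself* as the
  lipid affinity P (`convention = "direct"`), the convention under which the
  calibrated neutral-lipid shares reproduce; the thermodynamic
  `convention = "power"` (`10^logP`) is provided but changes the calibration.

Lung and tumor use `F_iw = 0.43` from the main tissue table rather than the
0.45 of the lung cell-type sub-table; 0.43 reproduces the calibrated EGFR
shares (afatinib 16.7% lung, 72.2% tumor) essentially exactly.

## Numerical choices and degenerate inputs

* `blood_cell_partition()` accepts `B:P = 1 − H` (zero cellular uptake,
  returns 0) and rejects anything smaller as physically inconsistent.
* `ap_association_constant()` tolerates rounding noise at an exactly-zero
  AP− remainder (clamped to 0) and rejects genuinely negative remainders,
  which would mean blood-cell binding is over-explained without AP−.
* The prediction-error denominator is the arithmetic mean of the pair,
  `(PRED + OBS)/2`, making PE antisymmetric and bounded in (−200, 200).
* 3-fold membership uses the closed interval `[1/3, 3]`; ties count as
  within.
* The "95% interval of the data" around the mean PE is not uniquely defined;
  both an empirical percentile interval (default) and a normal
  `mean ± 1.96·sd` interval are implemented and labelled in the report.
* Correlation significance uses the t-test for a Pearson correlation with
  n − 2 degrees of freedom; the test suite checks it against
  `stats::cor.test`.
* Zero variance in either margin makes the correlation undefined: the
  report carries `NA` with a warning, never a silent 0.

## What the built-in fixtures represent

The observed-TBR table (`observed_tbr()`) contains PET-image-derived means
and SDs for six tissues per tracer from clinical whole-body scans; the
erlotinib brain cell is unavailable (outside the scanner's field of view), so
every aggregate uses 17, not 18, pairs. Erlotinib's 3-fold accuracy is
reported as 20% (1 of 5 available tissues); a previously circulated 16.6%
implies dividing by 6 including the missing cell and is not reproduced.
These fixtures validate the model at microdose steady state in a specific
patient population; passing tests show internal consistency with that
calibration, not transferability to therapeutic doses, other histologies or
tracers with transporter liabilities.

Two documented reconstruction outliers are asserted at a 6% rather than 5%
relative tolerance in the acceptance tests: the erlotinib tumor total (whose
calibrated print value is inconsistent with its own component shares — those
shares imply a total near 0.284, which is what this package computes) and
the osimertinib kidney total. Relatedly, the erlotinib lung extracellular
-water share: the calibrated 0.36% cell is inconsistent with the column's
own total (the column sums to 89%, not 100%); the self-consistent
decomposition computed here puts EW near 11.4% and is what the package
reports.

## Known limitations

* No transporters: influx (OAT/OCT; erlotinib into excreting tissues) and
  efflux (MDR1/BCRP; afatinib out of brain) are unmodelled, which is the
  leading explanation for the largest validation residuals (erlotinib
  spleen/kidney/bone underpredicted, afatinib brain overpredicted).
* Wild-type EGFR affinity everywhere; no mutant-receptor binding.
* No saturation: valid at PET microdoses, not directly at therapeutic doses
  where lysosomes and target can saturate.
* No metabolism/elimination and no liver compartment (excluded because
  hepatic metabolism makes its uptake assessment unreliable).
* No alpha-1-acid glycoprotein binding; membrane affinity is approximated
  through log P rather than measured values.

All computations finish in milliseconds; the test suite and the acceptance
script run the full 3-compound × 6-tissue grid, the five-scenario ablation
suite and the validation statistics in a few seconds.

```{r example}
p <- default_parameters()
predict_tbr(p, "osimertinib", "lung")
sapply(names(p$compounds), function(cn) tumor_to_lung_contrast(p, cn))
```
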