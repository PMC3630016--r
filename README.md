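# smartdesign

Simulation and evaluation of experimental-design strategies for
conveyor-greenhouse (Smarthouse) phenotyping experiments.

Plants in such facilities sit in carts on a grid of lanes (south to north)
and positions (west to east). Microclimate varies across the grid — a
west-to-east trend away from the air conditioners, and depressed growth in
northern lanes shaded by adjoining imaging equipment — so a naive experiment
confounds line differences with location. Two remedies compete: physically
relocating plants during the experiment so all of them sample many
microclimates, or keeping plants fixed and removing spatial effects by
blocking and trend modelling. This package simulates uniformity trials with
the relevant variance structure, implements four relocation tactics (bench,
same-lane, half-lane, next-lane) with exact exposure accounting, constructs
the standard design menu (CRD, RCBD, resolved incomplete-block, resolved
row-column, and (nearly) trend-free designs with their restricted
randomizations), and compares strategies by two criteria:

* **relative precision** of a blocking arrangement on uniformity data:
  100 × (no-blocking error variance) / (arrangement's error variance);
* **relative efficiency** of a proposed design/analysis (PDA):
  `RE_PDA = 100 × AP_CRD / AP_PDA`, where
  `AP = F(1, d, 1 − α) × mean variance of all pairwise treatment-prediction
  differences` is a modified A-optimality criterion (α = 0.05), estimated by
  Monte-Carlo sampling of each design's randomization distribution with a
  mixed-model (REML/GLS) fit per randomization.

## Worked example

```r
library(smartdesign)
lay <- grid_layout(3, 24)                      # one zone: 72 carts
uni <- simulate_uniformity(make_field(lay, field_params(pos_slope = 1.67)),
                           seed = 2026)        # strong west-east trend
res <- compare_designs(uni, design_menu(36, lay), n_samples = 300,
                       seed = 2026)
res
```

```
       design re_percent   ap mc_se n_samples mean_df
1         CRD      100.0 1932  0.00         0      36
2     CRD+Adj      128.7 1501 14.52       300      35
3         TFD      134.7 1434 22.22        60      35
4        RCBD      123.2 1569 15.53       300      35
5    RCBD+Adj      127.8 1511 15.67       300      34
6  TFCBDEqLin      130.9 1476 25.14        60      34
7        RRCD      103.7 1862 15.76       300       9
8     RIBD3x1      114.2 1692 16.56       300      13
9     RIBD1x4      124.3 1555 15.89       300      19
10    RIBD3x6      124.2 1555 14.37       300      33
```

`re_percent` above 100 means the strategy beats a completely randomized
design; above 110 it is worth adopting. On this strongly trended zone the
trend-aware analyses (TFD, TFCBDEqLin, CRD+Adj) and the small-block resolved
designs deliver 14–35% gains, while the row-column design is held back by
its small containment degrees of freedom (`mean_df`), which the F-quantile
factor in AP penalizes.

The `analysis/` directory holds the numbered workflow the package supports:

1. `01_simulate_uniformity.R` — uniformity datasets (calibrated zone,
   strongly trended zone, shaded 24-lane house) and their CV summaries;
2. `02_tactic_schedules.R` — tactic schedules, exposure tables, and the
   deterministic demonstrations that equal exposure nullifies a lane trend
   under next-lane while a position trend survives half-lane;
3. `03_blocking_precision.R` — relative precision of the 21 standard
   blocking arrangements (three series of seven);
4. `04_compare_designs.R` — the Monte-Carlo efficiency table above.

Each writes CSV/JSON outputs under `results/`.

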