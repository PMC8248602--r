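# occmot

Dopamine-receptor **occ**upancy and **mot**ivation modeling in R.

`occmot` is for researchers quantifying how pharmacological blockade of
dopamine D1-like and D2-like receptors alters benefit- and cost-based
motivation in nonhuman primates. It links two kinds of measurements:

1. **PET receptor occupancy.** Dynamic PET time–activity curves (TACs) are
   reduced to regional binding potentials (BP_ND) with the simplified
   reference tissue model (SRTM, cerebellum reference), occupancy is
   estimated either per region as

   Occupancy(%) = (1 − BP_ND,treatment / BP_ND,baseline) × 100

   or across regions as the slope of a Lassen (occupancy) plot, and the
   treatment → occupancy mapping is calibrated with a one-parameter Hill
   dose model, Occ(%) = 100·Dose/(ED50 + Dose), or an exponential washout
   model, Occ(%) = Occ_Day0·exp(−λ·Day).

2. **Operant refusal-rate models.** In bar-release tasks the refusal rate
   E (early plus late releases over presentations) indexes motivation.
   The package fits the inverse reward-size model E = 1/(aR) + e over
   reward sizes R ∈ {1, 2, 4, 8} drops, the linear cost-discounting model
   E = k·CU + E0 over remaining cost units CU ∈ {0, 1, 2} (workload slope
   k_w and delay slope k_d sharing one intercept E0), and the linear
   relation between mean reaction time and refusal rate. Each model is fit
   under a family of nested condition/subject sharing structures and the
   structure is selected by BIC = p·ln(n) − 2·logL.

A synthetic-data module generates SRTM-consistent TACs, dose/day occupancy
series, and trial-level sessions for both tasks with known ground truth,
so every stage is validated by parameter recovery.

## Worked example

```r
library(occmot)
report <- run_pipeline(default_run_config(seed = 42))
report$occupancy_table
```

The demo configuration simulates a baseline plus moderate- (MO, true 50%)
and high-occupancy (HO, true 80%) PET conditions with mild frame noise,
fits the SRTM per region, and estimates occupancy both ways:

```
  condition       method occupancy_pct         se
1        MO lassen_slope      49.71182 0.08015744
2        MO   per_region      49.64747         NA
3        HO lassen_slope      79.81656 0.09355065
4        HO   per_region      79.77358         NA
```

Occupancy calibrations recover their generative parameters (ED50 = 22.63
μg/kg; Occ_Day0 = 78%, λ = ln(78/48) ≈ 0.486/day):

```
Hill dose-occupancy model: ED50 = 22.999 ug/kg (RSS 85.63, n = 12)
Occupancy washout model: Occ_Day0 = 78.72%, lambda = 0.4947 /day (RSS 72.64)
```

Behavioral fits select the incentive-only structure (model #1, condition-
specific `a`, no intercept) and recover the generative incentive impacts
(truth a = 8, 5.4, 4 for CON, MO, HO):

```
Inverse reward-size model family (binomial likelihood)
  #1 a(cond), e = 0       logL   -1664.13  p  3  BIC    3354.35  <- selected
  #2 a(cond), shared e    logL   -1664.10  p  4  BIC    3363.00
  #3 shared a, e(cond)    logL   -1685.67  p  4  BIC    3406.13
  #4 a(cond), e(cond)     logL   -1661.42  p  6  BIC    3375.03
a: CON=7.696, HO=3.792, MO=5.029
```

`report$incentive_occupancy` joins the two sides: the incentive impact,
normalized to control, falls to 0.65 at 50% occupancy and 0.49 at 80%
occupancy in this run. `write_report(report, "out/")` writes the CSV
tables and a JSON summary; `inst/scripts/occmot.R` exposes
`simulate | fit-pet | fit-behavior | run` as a command line.

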