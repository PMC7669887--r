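# sharkstress

Simulation and analysis of 2x2 temperature x pCO2 multistressor
experiments on neonatal sharks.

Experimental studies of ocean warming and acidification on large,
protected, hard-to-study fishes run small by necessity: a few replicate
holding tanks per treatment, three or four animals per tank, and a dozen
or more derived behavioural and physiological traits per animal.
`sharkstress` is for experimental ecophysiologists and biostatisticians
who design or re-analyse such studies. It implements the full
computational chain — seawater carbonate chemistry, respirometry trait
extraction, behavioural indices, haematology, mixed-model inference, and
Monte-Carlo power analysis — plus a synthetic-data generator with known
ground truth so that every stage is testable by parameter recovery.

## The models at the core

**Trait model.** Each trait y for shark i in tank k is Gaussian:

    y_ik = b0 + bT*T + bC*C + bTC*T*C + u_k + e_ik,
    u_k ~ N(0, sg^2),  e_ik ~ N(0, se^2)

with T, C in {0, 1} the high-temperature and high-pCO2 indicators and
tank (replicate group) the random-intercept unit. Effect sizes specified
as ratios r (treatment/control means, the currency of meta-analyses)
enter additively as (r - 1) * b0. Significance uses 95% percentile
intervals of 1000 draws of the fixed effects from N(b_hat, Vcov(b_hat));
power is estimated by simulate–refit–test Monte Carlo with a
Satterthwaite-df t test (likelihood-ratio optionally).

**Respirometry.** Oxygen uptake per measure phase is
MO2 = |dO2/dt| * V_eff * 3600 / m^0.89 (mg O2 kg^-0.89 h^-1), with
phases failing R^2 > 0.95 dropped and background respiration interpolated
between empty-chamber measurements and subtracted. MO2Min is the Mean of
the Lowest Normal Distribution (BIC-selected Gaussian mixture); MO2Max
the steepest 30-s rolling slope in hour one; AAS = MO2Max - MO2Min;
FAS = MO2Max / MO2Min; EPOC and recovery time come from an exponential
decay a*exp(-k t) + c fitted to the uptake series, integrated in closed
form against MO2Min.

**Carbonate system.** pCO2 is solved from (pH_NBS, A_T, T, S) with the
Mehrbach constants refit by Dickson & Millero (1987), Weiss K0, Dickson
KB/KS, Uppstrom boron, and NBS-to-seawater-scale conversion via the
activity factor fH; total alkalinity comes from open-cell Gran titration,
F = (V0 + V)*10^-pH fitted over pH 3.0–3.5.

**Behaviour.** Lateralisation L_R = (R - L)/(R + L) * 100, L_A = |L_R|;
ODBA is the sum over axes of |raw - 2-s centred running mean|, averaged
over the half-open 11:00–15:00 activity window; hypoxia tolerance is the
% air saturation at the onset of muscle spasms.

## Worked example

```r
library(sharkstress)

# treatment water: pCO2 of the ambient cell from measured chemistry
solve_pco2(28.1, 37, 8.01, 2354)$pco2
#> [1] 653.8328

# a 24-h respirometry trial with known truth, analysed blind
trace <- generate_o2_trace(mass_kg = 1.1, mo2_max = 360.15,
                           mo2_min = 133.69, recovery_k = 0.5)
respirometry_metrics(trace)
#> Respirometry metrics (mg O2 kg^-0.89 h^-1 unless noted)
#>   MO2Min (MLND):  133.70
#>   MO2Max (30 s):  359.69
#>   AAS:            226.00
#>   FAS:            2.690
#>   EPOC:           426.2 mg O2 kg^-0.89
#>   recovery:       5.66 h
#>   determinations: 96 retained, 0 dropped

# a full synthetic study and its per-trait effect estimates
roster <- generate_design(study_design(seed = 7))
truths <- default_trait_truths()
truths$mo2_min$ratio_pco2 <- 1.167          # +22.3 units at high pCO2
tab <- generate_trait_table(roster, truths, seed = 7)
fit <- fit_trait_model(tab, "mo2_min", include_interaction = FALSE)
effect_ci(fit, n_sim = 1000, seed = 7)
#>               term      mean     ci_low   ci_high significant
#> 1        intercept 119.82469 102.863052 137.81055          NA
#> 2        high_pco2  28.88195   7.770272  48.12762        TRUE
#> 3 high_temperature  15.22057  -4.804028  34.73790       FALSE

# how many replicate tanks per cell to detect that pCO2 shift?
spec <- power_spec(133.69, effect_pco2 = 22.3, group_sd = 8,
                   resid_sd = 20.5, effect = "pco2", n_sim = 400, seed = 1)
required_groups(spec, max_groups = 12)$required_strict
#> [1] 4
```

The first block prints the partial pressure (uatm) implied by the
measured water chemistry of the ambient treatment. The respirometry block
shows the pipeline recovering the generator's ground truth (133.69 /
360.15) to within a percent. The inference block recovers a simulated
+22.3-unit pCO2 effect with an interval excluding zero, and the power
block reports the smallest number of replicate tanks per treatment cell
whose simulated power exceeds 80%.

A thin command-line wrapper over the same functions ships in
`inst/cli/sharkstress` (subcommands `carbchem`, `gran`, `respo`, `fit`,
`power`).

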