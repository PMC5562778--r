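# estrapbk

Physiologically based kinetic (PBK) modelling of the bioactivation and
detoxification of estragole — a naturally occurring alkenylbenzene flavour
compound that is genotoxic and carcinogenic in rodents at high doses — in
Chinese and Caucasian populations. The package is aimed at toxicokinetic
modellers and risk assessors who want to reproduce, probe or extend the
inter-ethnic comparison of estragole metabolism from in vitro liver data,
and at anyone who needs a compact, fully tested example of the
in-vitro-to-in-vivo extrapolation (IVIVE) workflow.

## What it computes

Estragole is bioactivated by CYP-mediated 1′-hydroxylation to
1′-hydroxyestragole (the proximate carcinogen), which is either detoxified
by glucuronidation (HEG) and oxidation to 1′-oxoestragole (OE), or
bioactivated further by sulfotransferase-mediated sulfation to the ultimate
carcinogen 1′-sulfooxyestragole (HES). The package implements the full
pipeline:

1. **Michaelis–Menten fitting** — each hepatic conversion is a saturable
   pathway, `v = Vmax·S/(Km + S)`, fitted to microsomal/S9 incubation data
   by bounded nonlinear least squares with a multistart over `Km` guesses.
2. **IVIVE scaling** — in vitro rates in nmol/min/(mg protein) become
   whole-liver rates, `Vmax,L = Vmax·yield·60/1000` µmol/h/(g liver), with
   protein yields of 35 (microsomes) and 143 (S9) mg/g liver.
3. **PBK simulation** — a six-compartment flow-limited model (GI tract,
   liver, fat, rapidly and slowly perfused tissue, blood) with first-order
   oral absorption (`Ka` = 1.0 h⁻¹) into the liver, the five saturable
   estragole conversions and the three 1′-hydroxyestragole conversions in
   the liver driven by venous-equilibrium concentrations `C/P`, integrated
   with a stiff solver. Mass balance holds to solver tolerance.
4. **Sensitivity analysis** — normalized coefficients
   `SC = (C′−C)/(P′−P) · (P/C)` by one-sided +5 % perturbation of every
   scalar parameter, with derived quantities re-derived after each
   perturbation.
5. **Inter-ethnic risk metrics** — dose–response sweeps, fold-difference
   tables, dose equivalence by bracketed root finding on the cumulative
   HES amount, and Margin of Exposure (`MOE = BMDL₁₀/EDI`).

Chinese and Caucasian parameter sets (physiology, tissue:blood partition
coefficients, and kinetic constants measured in pooled liver fractions)
ship with the package, both as in-code tables and as JSON configs under
`inst/extdata/`. A seeded synthetic-data generator emulates triplicate
incubation series with multiplicative noise so the whole pipeline is
testable without external data.

## A worked example

```r
library(estrapbk)

chinese <- pbk_model("chinese")
sim <- simulate_pbk(chinese, dose_mg_per_kg = 0.01)  # realistic daily intake
sim
#> <pbk_simulation> chinese, 0.01 mg/kg bw oral, 24 h (dose 4.049 umol)
#>   AP        0.31441 umol      7.766 % of dose      0.22783 nmol/g liver
#>   EE        0.62884 umol      15.53 % of dose      0.45568 nmol/g liver
#>   HE         1.7214 umol      42.52 % of dose       1.2474 nmol/g liver
#>   HA        0.17143 umol      4.234 % of dose      0.12422 nmol/g liver
#>   M5       0.070215 umol      1.734 % of dose     0.050881 nmol/g liver
#>   HEG      0.032021 umol     0.7909 % of dose     0.023204 nmol/g liver
#>   OE         1.6877 umol      41.69 % of dose        1.223 nmol/g liver
#>   HES    0.00075388 umol    0.01862 % of dose   0.00054629 nmol/g liver
#>   liver 1'-hydroxyestragole: Cmax 0.01917 uM, AUC(0-24 h) 0.0505 uM h
```

Over 24 h, 42.5 % of the dietary dose is 1′-hydroxylated (the proximate
carcinogen), almost all of which is detoxified by oxidation (41.7 % of
dose); only 0.019 % reaches the ultimate carcinogen 1′-sulfooxyestragole.
The Caucasian model forms about four- to five-fold more HES at the same
dose:

```r
ca <- dose_response_sweep(pbk_model("caucasian"), 150, metabolites = "HES")
ch <- dose_response_sweep(chinese, 150, metabolites = "HES")
interethnic_fold(ca, ch, "HES", 150)     # cumulative-amount basis
#> 6.73-fold difference (chinese lower)

margin_of_exposure(3.3, 6.5, 0.01)
#> MOE 330 - 650 (BMDL10 3.3-6.5, EDI 0.01 mg/kg bw/day)
#>   below 10,000: priority for risk management
```

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "estrapbk.R", package = "estrapbk")` with subcommands
`fit`, `scale`, `simulate`, `sensitivity`, `compare`, `moe` and `synth`.

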