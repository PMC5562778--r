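---
title: "Inter-ethnic PBK modelling of estragole: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-ethnic PBK modelling of estragole}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estrapbk)
```

## The problem

Estragole, an alkenylbenzene present in fennel, basil and tarragon, is a
rodent hepatocarcinogen at high doses. Its carcinogenicity requires
two-step bioactivation in the liver: CYP-mediated 1′-hydroxylation to
1′-hydroxyestragole, then sulfotransferase-mediated sulfation to the
DNA-reactive 1′-sulfooxyestragole. Glucuronidation and oxidation of
1′-hydroxyestragole are competing detoxification routes. Because the
kinetic constants of these conversions differ between pooled Chinese and
Caucasian liver fractions, the net bioactivation differs between the
populations — but the individual in vitro differences pull in different
directions and saturate at different substrate levels, so only an
integrated kinetic model can say by how much. That integration is what
this package does.

## Model structure

The model has six compartments — GI tract, liver, fat, rapidly perfused
tissue, slowly perfused tissue and blood — connected by the systemic
circulation. All tissues are *flow-limited*: venous blood leaving a tissue
is in equilibrium with it, at concentration `C/P` where `P` is the
tissue:blood partition coefficient. Oral estragole enters the liver
directly from the GI tract (portal vein) as a first-order process with
`Ka = 1.0` h⁻¹, reflecting fast and complete absorption.

The hepatic estragole balance is

$$\frac{dA_L}{dt} = Ka\,A_{GI} + Q_L\left(C_A - \frac{C_L}{P_L}\right)
  - \sum_{m} \frac{V_{max,L,m}\,(C_L/P_L)}{K_{m,m} + C_L/P_L}$$

with the sum over the five microsomal conversions (4-allylphenol,
estragole-2′,3′-oxide, 1′-hydroxyestragole, 3′-hydroxyanethole and the
minor metabolite M5). 1′-Hydroxyestragole formed in the liver is cleared
by its own three saturable conversions (glucuronide, 1′-oxoestragole,
1′-sulfooxyestragole) driven by its venous-equilibrium liver
concentration, and exchanges with a blood pool through the liver blood
flow. Cumulative formation of every metabolite is tracked as an extra
state, so the 24-h summaries are exact integrals, not post-hoc quadrature.

Three structural choices deserve a note, because only the liver equations
are fully pinned down by the published balance equations:

* **Non-liver compartments** are standard flow-limited balances,
  `dA/dt = Q(C_A - C/P)`. The liver equation's use of venous-equilibrium
  concentrations is the hallmark of a flow-limited model, so the
  reconstruction is forced rather than free.
* **Total blood-side flow** is the sum of the tissue flows derived from
  the printed flow fractions, not the allometric cardiac output itself.
  The Chinese flow fractions sum to 100.15 % (a rounding artifact of the
  source table); using their sum makes the blood balance conserve mass
  exactly, which the tests assert to 10⁻⁶ relative.
* **1′-Hydroxyestragole disposition** is kept hepatic: a liver pool
  (partition coefficient 1.6) exchanging with blood, no extrahepatic
  clearance. Only a liver partition coefficient is available for this
  chemical and all its conversions are hepatic. The 24-h metabolite split
  is insensitive to this choice: in the low-dose limit it converges to the
  ratio of the scaled catalytic efficiencies regardless of the exchange
  structure, which the test suite verifies against the scaled table.

## Parameters

Tunable parameters, units and defaults:

| parameter | default | unit | note |
|---|---|---|---|
| `Ka` | 1.0 | h⁻¹ | first-order oral absorption |
| body weight | 60 / 70 | kg | Chinese / Caucasian |
| cardiac output constant | 15 | L/h/kg^0.74 | allometric |
| tissue fractions | per population | % bw | density 1 kg/L |
| partition coefficients | per chemical | – | liver 6.5, fat 105, rapid 6.5, slow 4.1 (estragole); liver 1.6 (1′-hydroxyestragole) |
| protein yields | 35 / 143 | mg/(g liver) | microsomes / S9; Caucasian yields used for both populations (no Chinese-specific data) |
| `Km`, `Vmax` | per pathway | µM; nmol/min/mg | fitted or bundled |
| MW estragole | 148.20 | g/mol | standard value, configurable |

The models always use *unrounded* scaled rates recomputed from the in
vitro constants; the rounded scaled table is regenerated only as a
printed-table check. This matters: the Chinese sulfation `Vmax` scales to
0.0120 µmol/h/(g liver) but prints as 0.01 — simulating from the printed
value would shift the HES outputs by ~20 %.

## Michaelis–Menten fitting

`fit_michaelis_menten()` minimizes unweighted squared error on replicate
mean rates (SEMs are carried but not used in the loss, matching the
typical reported workflow), with `Km ∈ (0, 10⁷]` µM, `Vmax ∈ [0, 10³]`,
starts at `Vmax₀ = max rate` and `Km₀` interpolated at half-maximum, and a
multistart over `{0.1, 1, 10}·Km₀`. Convergence uses a 10⁻¹⁰ relative
tolerance on the objective. Uncertainties are asymptotic standard errors.
An all-zero dataset returns `Vmax = 0` with `Km` flagged unidentifiable
rather than an error. A property test checks the optimizer beats a
200×200 log-spaced grid search on noisy data.

## The synthetic-data generator

`generate_invitro_dataset()` emulates the incubation design behind the
bundled constants: triplicate measurements on the assay grids (25–1000 µM
for estragole pathways; extended to 8000 µM for the 1′-hydroxyestragole
conjugations so the mM-range glucuronidation `Km` is spanned) with
*multiplicative* Gaussian noise, CV 10 % by default, truncated at −0.99.
Multiplicative noise is chosen because assay scatter scales with signal;
the source data report SEMs but no error model. The generator is
bit-reproducible under a fixed seed and leaves the caller's RNG stream
untouched.

What the generator does *not* emulate: donor-to-donor variability (the
source material is pooled), correlated errors within a run,
heteroscedastic detector floors, and substrate depletion at low
concentrations. Passing the pipeline tests therefore demonstrates
correctness of the estimation machinery under the stated error model, not
robustness to real-assay pathologies.

Noise propagation through the full loop (generate → fit → scale →
simulate) is unbiased but not small for a single triplicate draw: the
weakly identified conjugation constants scatter the minor-metabolite
summaries by 10–20 % per draw, while the average over ten seeds lands
within a few percent of the fixture simulation. The loop-closure test is
therefore asserted on the seed average.

## Numerical choices

* Stiff integration via `deSolve::ode(method = "lsoda")`, `rtol = 10⁻⁸`,
  `atol = 10⁻¹²` µmol; halving tolerances moves no 24-h summary by more
  than 0.1 % (tested).
* Dense output at 0.01 h for Cmax and trapezoid AUC of the liver
  1′-hydroxyestragole concentration; coarser grids are used internally
  where only terminal cumulative amounts matter (root finding, sweeps),
  since the output grid does not affect solver accuracy.
* Dose conversion `µmol = mg/kg · BW / MW · 1000`; liver mass
  `= V_L · 1000` g at density 1 kg/L.
* Dose equivalence uses bisection on log-dose over [10⁻⁶, 10⁴] mg/kg,
  terminating at 0.1 % relative on the matched cumulative amount —
  robustness over speed, since the amount spans decades.
* Sensitivity coefficients default to the one-sided +5 % forward scheme.
  The derivative itself is stable (central differences at 1 % and 5 %
  agree within 0.003 on the bundled models), but the forward scheme
  carries an O(δ) bias up to ~0.04 on the most curved kinetic parameters;
  `side = "central"` is available where that matters.

## Inter-ethnic comparison conventions

Fold-differences can be taken on percent-of-dose or on absolute
cumulative amounts; the two differ exactly by the body-weight ratio
(70/60) since both populations receive per-kg doses. The reported
glucuronide fold-differences follow the percent basis while the reported
sulfation folds follow the amount basis, so `interethnic_fold()` exposes
both, defaulting to `"amount"` for risk comparisons of the ultimate
carcinogen.

Dose equivalence matches the absolute cumulative amount of
1′-sulfooxyestragole over 24 h. In the linear low-dose regime the
equivalent dose is simply the reference dose times the amount
fold-difference (≈5), giving ≈0.05 mg/kg for a 0.01 mg/kg Caucasian
reference. At a 5 mg/kg reference the Chinese 1′-hydroxylation route
saturates over the search span, making the true equivalent dose
(≈33 mg/kg) larger than the ≈25 mg/kg a linear extrapolation suggests;
the package reports the nonlinear root-find.

## Problem sizes

The bundled analyses are desk-scale by construction: a 24-h simulation is
a 16-state stiff ODE solved in ~0.1 s; the full sensitivity sweep is ~100
simulations; Monte-Carlo fitting studies use 200 seeded triplicate
datasets. The whole test suite, including the Monte-Carlo studies, runs in
about a minute.

## Known limitations

* Single oral bolus only; no repeated dosing, no dermal/inhalation
  routes, no enterohepatic recirculation, no urinary-excretion sub-model.
* No downstream chemistry of 1′-sulfooxyestragole (GSH/DNA adducts) and
  no DNA-repair differences — the model stops at the ultimate carcinogen.
* Pooled-sample semantics: no inter-individual variability, no
  SULT1A1/CYP2C19 polymorphism structure, although the genotype frequency
  differences between the populations are a plausible mechanistic reading
  of the kinetic differences.
* BMDL₁₀ values are inputs to the MOE arithmetic, not derived here.
* Partition coefficients are taken as given (log Kow-based estimates from
  the source); no QSPR estimation is included.

```{r example, eval = FALSE}
chinese <- pbk_model("chinese")
sim <- simulate_pbk(chinese, dose_mg_per_kg = 0.01)
sim$summary
sensitivity_sweep(chinese, doses = 0.01, outputs = "HES",
                  parameters = c("vmax.HE", "vmax.OE", "vmax.HES"))
```
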