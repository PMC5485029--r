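---
title: "A coupled kinetic model of CHO fed-batch culture and Fc glycosylation under mild hypothermia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled kinetic model of CHO fed-batch culture and Fc glycosylation under mild hypothermia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The system and the model

Mild hypothermia — dropping the culture temperature from 36.5 °C to
28–34 °C after the exponential growth phase — is a standard lever in
CHO-cell antibody manufacturing: it slows growth, prolongs viability and
usually raises the cell-specific productivity q~mAb~. It also changes the
Fc N-glycan profile of the product, most visibly by reducing
galactosylation. `hypothermAb` implements a coupled kinetic model that
connects these observations mechanistically, as four modules that feed
into one another:

1. **Cell culture dynamics.** Fed-batch growth with Monod limitation by
   glucose, asparagine and glutamate, a lactate term that acts both as a
   secondary carbon source (limitation) and an inhibitor, ammonia and
   lactate growth inhibition, ammonia-driven death
   $\mu_d = \mu_{d,max}/(1 + K_{d,amm}/[\mathrm{Amm}])$, and first-order
   lysis of dead cells. Specific consumption rates combine growth demand
   ($\mu/Y$), maintenance and product incorporation; lactate switches
   from production (stoichiometric to glycolytic flux, $Y_{lac,glc}$) to
   consumption through a saturable transport term.
2. **Antibody synthesis.** A structured transcription → translation →
   assembly model: HC and LC mRNA from effective gene copies with
   first-order decay, mass-action assembly HC+HC→H₂, H₂+LC→H₂L,
   H₂L+LC→H₂L₂ sharing a single constant K~A~, first-order ER export
   (K~ER~) and Golgi-to-medium secretion (K~G~). All per-cell pools are
   diluted by growth.
3. **Nucleotide and NSD metabolism.** Intracellular glucose and
   glutamine pools fed by the specific uptake rates of module 1, de novo
   purine/pyrimidine synthesis with Michaelis–Menten kinetics (ATP, ADP,
   AMP, GTP, UTP, CTP), NSD synthesis (UDP-GlcNAc, UDP-Glc, UDP-Gal,
   UDP-GalNAc, GDP-Man, GDP-Fuc, CMP-Neu5Ac) with product inhibition
   where appropriate, and saturable Golgi transport whose demand is the
   sum of host-cell glycosylation (proportional to growth) and product
   glycosylation (proportional to q~mAb~; two N-glycans per antibody).
4. **Golgi glycosylation.** The Golgi is a single plug-flow reactor
   (cisternal maturation): the mAb traverses z ∈ [0, 1] in residence time
   τ past uniformly distributed enzymes (Man I/II, GnT I/II, GalT, FucT).
   Each reaction rate is Michaelis–Menten in its NSD co-substrate and
   competitive across all substrates of the same enzyme,
   $r_k = k_{cat}[E]\,\frac{[S_k]/K_{d,k}}{1+\sum_j [S_j]/K_{d,j}}\,
   \frac{[\mathrm{NSD}]}{K_m+[\mathrm{NSD}]}$. Cytosolic NSD
   concentrations are used directly (no intra-Golgi transporter
   kinetics), the quasi-steady coupling being evaluated at trajectory
   interval midpoints. Cumulative secreted glycoforms are
   production-weighted averages of per-interval outlet distributions.

A temperature shift is represented by *two complete parameter sets*: the
pre-shift set applies on [0, 144 h), the post-shift set from the shift
instant onward (right-closed). The state vector is continuous across the
shift; only parameters change.

```{r}
library(hypothermAb)
p36 <- defaultParameters("36.5C")
p32 <- defaultParameters("32C")
tr <- integrateCulture(defaultDesign(), p36, p32)
head(trajectoryStates(tr)[, c("Xv", "Glc", "Lac", "Amm", "mAb")])
cumulativeGlycoforms(tr, p36, p32)
```

## Parameters: reported values and reconstructed defaults

The two built-in parameter sets combine the published two-temperature
estimates — growth/death/lysis rates, the lactate yield, the antibody
synthesis constants, the nucleotide and NSD maximum rates, the Golgi
enzyme concentrations and dissociation constants, the host-glycan demand
(1.38×10⁻¹² vs 2.07×10⁻¹² mmol cell⁻¹) — with **reconstructed defaults**
for every constant that only appeared in an online supplement that is no
longer obtainable: amino-acid yields and maintenance coefficients,
nucleotide/NSD saturation constants, stoichiometric demand coefficients,
transporter constants, Golgi turnover numbers and residence time. These
defaults are calibrated to place trajectories in physiological fed-batch
ranges (peak viable cell density ~10¹⁰ cells L⁻¹, glucose 20–40 mM,
lactate tens of mM, ammonia reaching ~10–18 mM, nucleotide pools
10²–10³ µM) and to reproduce the reported qualitative two-temperature
contrasts. `paramUnits()` documents units for every entry.

Three reconstruction decisions deserve emphasis:

* **V_max/K degeneracy.** Several published maximum rates are enormous
  (up to 10¹⁴ mmol L⁻¹ h⁻¹) and only make sense together with their
  (unpublished) saturation constants; the identifiable quantity is the
  ratio. We keep the published V_max verbatim and absorb the scale into
  the reconstructed K, so some K defaults are far above physiological
  concentrations. The kinetic laws are unchanged; only the effective
  linear-regime slope V/K is calibrated.
* **Translation scale.** The published 32 °C translation rates are two
  to three orders of magnitude above the 36.5 °C ones. With plain
  mass-action translation (the reconstructed form; the original
  supplementary equations presumably contain a saturable capacity) this
  exaggerates the post-shift productivity increase. We anchor the
  effective gene-copy scaling (N_H, N_L) so that post-shift q~mAb~ is
  physiological (~4–5 pg cell⁻¹ h⁻¹); the pre-shift productivity then
  comes out low in absolute terms. Every qualitative contrast (higher
  titer and q~mAb~ after the shift) is preserved, and the glycoform
  weighting is scale-invariant, but absolute titers should not be read
  quantitatively.
* **Identifiability of the UDP-GlcNAc maximum rate.** The published 95%
  confidence interval (±13%) shows this V_max was identifiable from
  data; the reconstructed K's were chosen so that the UDP-GlcNAc pool
  retains order-one elasticity to its V_max, mirroring that property.

Other structural choices where the source was ambiguous or silent: the
death rate is implemented as increasing in ammonia (the printed form is
typographically ambiguous; the alternative reading is biologically
inverted); yield terms enter as μ/Y on dimensional grounds; the
glutamine balance's printed supply factor is implemented as uptake
scaled by a glutamine-synthetase fraction (default 0.2); the Golgi
transport demand is divided by the cell volume on dimensional grounds;
the GDP-Fuc synthesis inhibition is substrate saturation times product
inhibition Ki/(Ki+[GDP-Fuc]); the adenylate sub-network conserves
ATP+ADP+AMP apart from de novo input and growth dilution. The
lactate-limitation term implies μ = 0 at exactly zero lactate — a
structural artefact of the published growth expression that we keep
verbatim and note here.

Two published design hooks are exposed but off by default. The Golgi
volume scale factor (`golgi.volumeScale`) divides all enzyme
concentrations; because the built-in 32 °C enzyme concentrations are
already per-regime estimates, applying an additional q~mAb~-proportional
scaling would double-count the volume effect, so the default is 1. The
glycosylation efficiency factor ε₂ (`mab.epsilon2`) routes 1−ε₂ of the
product past the glycosylation reactor with its inlet glycan; defaults
are 1.0 (36.5 °C) and 0.9 (32 °C).

Structural unidentifiability of k~cat~·[E] is honored as published: the
turnover numbers are fixed package defaults and only enzyme
concentrations are treated as estimable.

## The synthetic-data generator

`defaultDesign()` encodes the study conditions: a 14-day, 3.5 L working
volume fed-batch with daily sampling, nutrient-feed boluses (4% v/v)
every 48 h from 72 h, an on-demand glucose bolus (2.5 M stock) when
glucose falls below 20 mM at a daily check, and the temperature shift at
144 h. Feed composition and initial conditions are synthetic defaults —
the study's actual feed recipe was never published. `generateDataset()`
simulates the model, samples at the design's schedule, and applies
mean-one multiplicative log-normal noise with class-specific CVs (10%
extracellular, 15% intracellular and glycoforms by default), so
measurements are non-negative and unbiased with exactly reproducible
seeds.

What passing the recovery suite shows — and what it does not. The
generator draws from the same model family that is fit, so recovery
results demonstrate correctness of the simulator/estimator loop and
identifiability under the stated noise and sampling, *not* robustness to
the structural mismatch, autocorrelated errors, limit-of-detection
censoring or carryover present in real bioreactor data.

## Estimation

`fitParameters()` minimizes a Gaussian negative log-likelihood
(heteroscedastic via the data's sd column, or constant-relative with
10% CV by default) with bound-constrained local optimization
(`nlminb`) from Latin-hypercube multistarts (default 20, seeded).
95% confidence intervals use the observed-information Hessian
(numerical) under the normal approximation; parameters whose variance
estimate is not positive are flagged non-identifiable rather than
silently reported. Fitting follows the staged modular flow: culture
parameters against cell/metabolite data; the intracellular module
against NSD data with recorded culture outputs as forcings
(`simulateIntracellular()`); the Golgi enzyme concentrations against
cumulative glycoform fractions with fixed NSD inputs. No family-wise
error correction is applied across per-parameter intervals.

## Numerical choices

* Stiff adaptive integration (`deSolve::lsoda`), default relative
  tolerance 1e-8 and absolute tolerance 1e-10 for culture runs; species
  are floored at zero when rates are evaluated. Bolus feeds are exact
  algebraic mixing events between solver segments; a continuous-rate
  feeding mode (inlet-flow terms active over a configurable duration) is
  available for fidelity to the flow-rate form of the balances.
* The Golgi PFR is integrated in z with an analytic Jacobian: the
  published dissociation constants span ten orders of magnitude
  (K~d,ManII~ ≈ 10⁻⁶ µM), which defeats finite-difference Jacobians in
  the inlet boundary layer. Conversion reactions conserve total glycan
  structurally, so conservation holds to solver round-off independent of
  tolerance. Default tolerances 1e-8 (relative), 1e-12 (absolute).
* During fitting, forward simulations run at relaxed tolerances (1e-6)
  — two orders below the measurement noise — and the reported optimum is
  refined implicitly by the multistart envelope.
* The glucose feed trigger is evaluated at daily checks rather than by
  continuous root-finding; this is deterministic and matches daily
  fed-batch practice.
* Problem sizes used by the standard recovery studies: daily sampling
  (15 time points), 20 multistarts for the two-parameter growth
  recovery, 12 for the three-parameter lactate recovery, 8 for the
  post-shift window fit, 4 for the single-parameter intracellular fit
  and 2 for the single-parameter Golgi fits — multistart counts scale
  with the dimension of the search space since the single-parameter
  objectives are unimodal in practice, and every single-parameter fit is
  additionally refined by a derivative-free interval search.

## Known limitations

* No pH/DO/gas-phase dynamics, no cell-cycle structure, no perfusion.
* No mannose salvage pathway, so GDP-Man/GDP-Fuc peaks are
  underpredicted by construction; sialylation of the product is not
  modelled (the Fc profiles contain none) although CMP-Neu5Ac synthesis
  is retained because it drains UDP-GlcNAc.
* Cytosolic and Golgi NSD pools are assumed equal.
* Absolute titers are not quantitative across the temperature contrast
  (see the translation-scale note above).
* The measured-vs-simulated glycoform discrepancy check
  (`checkGlycoformDiscrepancy()`) requires a reference table that is not
  deposited with the package; it raises a typed data-unavailable
  condition in that case.
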