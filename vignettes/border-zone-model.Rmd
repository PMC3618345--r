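---
title: "A conservative two-domain electrodiffusion model of the ischemic border zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A conservative two-domain electrodiffusion model of the ischemic border zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

ionbz simulates the first minutes of regional myocardial ischemia as a
problem in ion conservation. Tissue is a two-phase continuum: every point
carries an intracellular and an extracellular compartment (volume fractions
$f_{cyt}$ and $f_e$; mitochondria are inaccessible to the modelled ions and
the sarcoplasmic reticulum enters only through the equilibrium calcium
subsystem) coupled through a membrane of area $\chi$ per unit volume. Eight
species are tracked in both compartments — Na⁺, K⁺, Cl⁻, Ca²⁺, H⁺, HCO₃⁻,
CO₂ and lactate⁻ — each moving by Nernst–Planck electrodiffusion within its
compartment,

$$ J_k = -f_s D_{k,s}\left(\partial_x c_{k,s} +
   \frac{z_k F}{RT}\, c_{k,s}\, \partial_x \phi_s\right), $$

and crossing the membrane through pumps, exchangers, cotransporters and
lumped background channels. The membrane is a capacitor: the transmembrane
potential is an algebraic function of the unbalanced intracellular charge,

$$ V_m = \frac{F f_{cyt}}{\chi C_m}\left(\sum_k z_k c_{k,i}^{tot} +
   Q_{static}\right), $$

and a per-node zero-net-charge-accumulation constraint (the elliptic limit
of charge conservation) determines the extracellular potential up to a gauge.
When concentrations are homogeneous and a single carrier conducts, the
system reduces exactly to the classical bidomain pair — the package tests
assert this equivalence on the discrete operators themselves.

The membrane model is passive (diastolic): no gating, no action potentials.
This is what makes minutes of simulated time tractable and is appropriate
for the quantity of interest, the slow spatial redistribution of ions across
the border zone (BZ) between perfused and ischemic tissue.

### Buffering, pH and calcium

H⁺ (both compartments) and Ca²⁺ (extracellular) bind single rapid immobile
buffer populations; PDEs are solved for total concentrations and free values
are recovered by closed-form inversion of the mass-action relation. CO₂
hydration, $\mathrm{CO_2 + H_2O \rightleftharpoons H^+ + HCO_3^-}$, runs as
a kinetic source in both compartments. Intracellular calcium is an
equilibrium subsystem: free Ca²⁺, buffer-bound Ca²⁺ and SR content (SERCA
uptake with Hill coefficient 1 balanced against a passive leak) partition
the total through a cubic whose constant coefficient is always negative, so
a positive real root always exists; it is evaluated by the trigonometric
closed form and polished by two Newton passes (see *Numerical choices*).

### Transmembrane pathways

NaK (3Na⁺ out : 2K⁺ in), NCX (3Na⁺ : 1Ca²⁺, zero exactly at
$3E_{Na}-2E_{Ca}=V_m$), NHE, CHE, AE and NBC (all electroneutral, each zero
exactly at its equilibrium concentration ratio), MCT1 (1:1 lactate⁻:H⁺
cotransport, saturating), Fickian membrane CO₂ flux, and linear
$(V_m - E_{ion})$ background channels for Na⁺, K⁺, Cl⁻ (with a linear
free-Ca²⁺ activation) and Ca²⁺. The kinetic laws are reduced,
thermodynamically consistent forms — correct stoichiometry, zero at
reversal/equilibrium, saturable — rather than transcriptions of the original
multi-state models, whose full constant sets are not restated in this
package's sources. Each pathway sits behind a single flux interface so a
richer kinetic variant can be swapped in; `validation_grid()` reports the
active variant. Two kinetic dependencies deserve mention because results
depend on them:

* the pump's intracellular-Na dependence uses $K_m = 15$ mM with Hill 1.5,
  the gentle sensitivity measured in intact myocytes; a steeper pump
  over-stabilises Na⁺ and suppresses the extracellular-K⁺ phenotype;
* NHE carries both a steep intracellular-H⁺ activation (pK 6.9, Hill 2) and
  kinetic inhibition by extracellular H⁺ (pK 7.0). Without the latter,
  metabolic acidosis Na-loads the cell far beyond what is observed; with it,
  acidosis alone leaves Na⁺ nearly unchanged, as the component analysis
  requires.

### Gap junctions

All intracellular diffusivities are scaled by a biphasic proton dependence
(activating and deactivating Hill terms in free H⁺, constants representative
of end-to-end cell-pair measurements: pK 7.9/Hill 1.5 activating, pK
6.4/Hill 4 deactivating), normalized to 1 at resting pH 7.1 so that the
calibrated diffusivities are the resting-state effective values.

## Calibration: every density from a zero-net-flux constraint

`calibrate_model()` derives all free parameters from the reference resting
state (Na⁺ 4/140, K⁺ 135/4, Cl⁻ 18/110 mM intra/extra, free Ca²⁺ 100 nM /
1.2 mM, pH 7.1/7.4, $V_m = -80$ mV, 310 K) plus a handful of anchors, in a
triangular chain:

1. CO₂ from Henry's law ($\alpha$ = 0.0308 mM/mmHg, 5% CO₂, 760 mmHg
   → 1.17 mM), equal in both compartments (zero Fickian flux).
2. HCO₃⁻ in each compartment from hydration equilibrium. The hydration
   constants are chosen with equilibrium pK′ = 6.1 (the physiological
   CO₂/HCO₃⁻ constant at 37 °C), giving HCO₃⁻ 11.7/23.3 mM.
3. The extracellular proton buffer by inverting the single-site relation at
   the 39 mM bound-H⁺ anchor with the intracellular-fit affinity (pK 6.5):
   349 mM of sites.
4. Na/K/Cl diffusivities per compartment by inverting the conductivity
   definition at 0.25 S/m (intracellular sum referenced to $f_{cyt}$),
   after fixing Ca²⁺, H⁺ and HCO₃⁻ at literature values: 7.65 and
   12.89 ×10⁻⁷ mm²/ms.
5. SERCA $v_{max}$ and the SR leak from zero net SR flux at rest
   (0.04 µM/ms and 1.0 ×10⁻⁴ /ms).
6. Pathway densities: Na-entry anchors (NCX 2.0, NHE 1.2, background
   1.13 ×10⁻⁸ mM·mm/ms — magnitudes at the cited literature's scale,
   ~1.3 mM/min total resting Na⁺ influx, ~0.25 µA/cm² resting pump
   current); NBC at 0.16 × NHE; NaK balances total Na⁺ influx; CHE balances
   NHE's acid extrusion; AE balances NBC's HCO₃⁻ influx; the Cl⁻ channel
   balances CHE+AE; the K⁺ background balances the pump's K⁺ influx; the
   Ca²⁺ background balances NCX.
7. Static charges pin $V_m = -80$ mV with equal-and-opposite membrane
   charge.

The chain is deterministic and the calibrated state is an exact fixed point:
`resting_flux_residual()` is ~10⁻²³ mM·mm/ms, and both the 0D cell and the
1D strand hold the state indefinitely. Because the chain runs from any
target state, perturbed configurations (say, K⁺ 6 mM) re-calibrate to
stationary parameter sets of their own.

## Ischemia

Four components, applied instantaneously at $t=0$ and multiplied by a shared
spatial severity profile (a Hill ramp with midpoint at the strand centre and
coefficient 60, i.e. a 10–90% transition of ~0.6 mm, consistent with the
sub-millimetre oxygen drop measured across border zones):

* NaK inhibition — density × (1 − severity·fraction);
* K-background activation — density × (1 + severity·(factor − 1));
* respiratory acidosis — an intracellular CO₂ source with no extracellular
  venting;
* metabolic acidosis — an intracellular H⁺ source paired 1:1 with a lactate
  source (electroneutral by construction; MCT1 carries the pair back out).

The component intensities are not directly measurable, so
`tune_ischemia()` sizes them against five-minute physiological targets by
sequential bisection on the closed 0D core: the CO₂ source alone to
extracellular CO₂ 2.34 mM (doubled), the H⁺ source (respiratory acidosis
active) to pH$_i$ 6.6, the pump inhibition alone to Na⁺ 6 mM (the level the
mid-range of the inhibition sweep produces), and the K-background activation
last — with the other three active — to extracellular K⁺ 9 mM. The tuned
values (≈71% inhibition, ≈2.3 ×10⁻⁵ and 6.5 ×10⁻⁵ mM/ms sources) land the
combined core at CO₂ 3.7 mM, pH$_i$ 6.6, Na⁺ ≈7.4 mM, K⁺ ≈8.5 mM and a
membrane depolarised to about −73 mV, with K⁺ rising fast and plateauing while Na⁺ climbs
steadily — the qualitative fingerprint the component analysis expects. The
K-activation bisection is bounded at 30×; with the reduced pump kinetics the
acid-loaded pump re-accelerates strongly, so a much larger activation is
needed to hold elevated K⁺ than the ~2–3.5× a fuller pump model requires.
This is the model's main kinetic-fidelity limitation (see *Limitations*).

## Numerical methods

Cell-centred finite volumes with zero-flux ends give exact discrete
conservation; drift uses the arithmetic-mean interface concentration, and
only free ions move. Time stepping is backward Euler; each step is solved by
Newton with a backtracking line search. The Jacobian is assembled by colored
sparse finite differences (3 node colors × 17 slots = 51 residual
evaluations — the same sparsity an analytic-transport/finite-difference-
membrane split would give, at a fraction of the code), kept factorized and
reused across iterations and steps, and rebuilt only when the residual fails
to decrease or the iteration cap (12) is hit; persistent failure halves the
step. Defaults: dx 0.25 mm, dt 100 ms for production runs (the analyses in
the test-suite use 16 mm strands at dx 0.25–0.5 mm and dt 0.5–1 s, shown
converged by the halve-dx-and-dt comparison).

Numerical choices that matter:

* **Vm in delta form.** $V_m$ multiplies a ~10² mM charge sum by
  ~2×10⁴ mV/mM, so evaluating it from the raw sum leaves ~10⁻⁹ mV of
  roundoff that the drift terms amplify. It is computed from concentration
  *differences* against the calibrated state, which is algebraically
  identical and numerically clean.
* **Polished cubic.** The trigonometric root of the calcium cubic loses
  about half its digits to cancellation when the root (~10⁻⁴ mM) sits far
  below the coefficient scale; two Newton polishing passes restore machine
  precision. Without them the finite-difference Jacobian is too noisy for
  full Newton steps.
* **Scaled convergence norm.** Species rows are $f\,\Delta c$ in mM and are
  held to `newton_atol` (10⁻¹¹) scaled by dt/250 ms, which bounds the
  cumulative mass defect of any run by ~4×10⁻¹⁴ × duration(ms) — below the
  10⁻⁸ mM ledger-closure budget for a five-minute run. The elliptic charge
  rows carry a 1/dx²-growing roundoff floor and are down-weighted 10³ in the
  norm; the implied extracellular-potential error (~10⁻¹⁰ mV) is far below
  anything the fluxes can feel.
* **Degenerate inputs.** Transient negative totals on Newton trial states
  are passed through linear continuations of the buffer inversions, and
  kinetic laws see free concentrations floored at 10⁻¹² mM; neither device
  is active at converged states.
* The gauge pins $\phi_e = 0$ at node 1; tests assert gauge invariance.

## Analyses

* `bz_width_table()` fits $c(x) = base + amp/(1+(x/mid)^n)$ to each ion's
  end-state profile (deterministic quantile-derived starts, Levenberg–
  Marquardt, an interpolated-level fallback for profiles a Hill curve cannot
  start on) and reports the 10–90% transition width; flat profiles return a
  "no BZ" sentinel.
* `flux_decomposition()` closes the per-node ledger of cumulative
  transmembrane, diffusion, drift and source contributions against the total
  concentration change to <10⁻⁸ mM.
* `clamped_potential_experiment()` re-runs the reference simulation with one
  pathway sensing a sharp-transition surrogate potential that preserves the
  true field's extrema at every step, isolating the role of the smooth
  potential gradient in widening the K⁺ border zone.
* `validation_grid()` scores the 0D model's response directions for twelve
  bath-perturbation/inhibition protocols against a reconstruction of the
  experimentally reported directions (see *Limitations*), reporting the full
  confusion table.
* `component_sweep()` runs one ischemic component at five severities and
  returns the banded end-state changes.

```{r example}
library(ionbz)
model <- calibrate_model()
isch <- tune_ischemia(model, midpoint = 8)
mesh <- mesh_1d(16, 0.25)
traj <- run_simulation(model, mesh, isch, duration = 5 * 60 * 1e3,
                       settings = solver_settings(dt = 500))
bz_width_table(traj)
```

## What the synthetic conditions do and do not show

The generator emulates a quiescent, diastolic strand with an instantaneous,
spatially sharp ischemic insult and closed boundaries: no perfusion washout,
no cell swelling, no metabolite dynamics, no action potentials, and a
one-dimensional fibre-direction geometry. Passing tests therefore
demonstrate internal consistency (conservation, calibration fixed points,
operator limits) and the qualitative mechanism structure (voltage-dependent
K⁺ flux widening the K⁺ border zone, drift-driven cyclical K⁺ movement) —
not quantitative agreement with any particular in-vivo preparation.

## Limitations

* The cited multi-state transporter kinetics are replaced by reduced
  thermodynamically consistent laws. The resting calibration is exact by
  construction, but response magnitudes away from rest inherit the reduced
  kinetics; the clearest consequence is the large K-background activation
  the tuning procedure needs, which locally shortens the electrotonic length
  in the core and narrows the simulated K⁺ border zone relative to a fuller
  pump model. The measured Na⁺-to-K⁺ BZ width ratio is correspondingly
  biased high (~0.4 at converged resolution against the ~0.25 a fuller
  kinetic set yields).
* The expected-direction table behind `validation_grid()` is a
  literature-based reconstruction (44 direction cells, 23 without consistent
  data, 5 with no observed change), not a transcription; counts scored
  against it are comparable in structure, not cell-for-cell, with published
  tallies.
* Buffers are single-population, rapid and immobile; mobile-buffer transport
  is folded into effective diffusivities.
* The equations permit 2D/3D anisotropic extension (the discretization is a
  plain finite-volume stencil), but only 1D is exercised.
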