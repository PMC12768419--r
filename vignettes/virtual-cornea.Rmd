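---
title: "A cellular Potts virtual cornea: model, calibration, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cellular Potts virtual cornea: model, calibration, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science inside
`corneasim`: the model and its assumptions, the parameters that matter, the
numerical scheme, the design decisions taken where the design was genuinely
open, and the limitations a user should know before trusting any simulated
number.

## The tissue and its abstraction

The corneal epithelium is a stratified squamous epithelium, 4–8 cell layers
(~50 µm) thick, renewed continuously from limbal epithelial stem cells at the
corneal periphery. Stem cells divide on the limbal basement membrane; their
progeny migrate centripetally as basal cells, detach and differentiate into
wing cells, terminally differentiate into tear-facing superficial cells, and
desquamate into the tear film. Growth-factor signaling (abstracted here as a
single EGF field sourced by the tear film) stimulates proliferation; the
tight-junction barrier formed by superficial cells limits how much EGF
reaches the proliferative compartment, closing a negative feedback loop that
sets tissue thickness: a thinner or wounded epithelium lets more EGF in,
which accelerates proliferation until the barrier is restored.

`corneasim` models a 2-D radial cross-section — 200 × 90 voxels at 2 µm per
voxel (400 × 180 µm), the limbal zone in the first 80 µm — using the cellular
Potts (Glazier–Graner–Hogeweg) formalism. Each cell is a set of voxels
sharing an id; shape and motion emerge from Metropolis-accepted single-voxel
copy attempts biased by an effective energy with adhesion, volume, surface,
apical-link, and chemotaxis terms. One Monte Carlo step (MCS) corresponds to
6 minutes; 240 MCS to one day. A full sweep (one MCS) performs
`width × height` copy attempts, then field updates, then the behavior rules
in a fixed order: growth → mitosis → differentiation → sloughing → chemical
death → fragment culling. Cells created in an MCS are not re-evaluated until
the next.

## Parameters

Constants that the underlying tissue literature pins down directly are fixed
and should not be retuned:

| quantity | value | units |
|---|---|---|
| lattice | 200 × 90 | voxels (2 µm edge) |
| time step | 1 MCS | 6 min (240 MCS/day) |
| initial / division volume | 25 / 50 | voxels |
| EGF half-max, stem / basal | 3.5 / 7.0 | arb. conc. |
| pressure half-max | 125 | arb. pressure |
| Hill exponent | 4 | — |
| max doubling rate δ | 25/80 | voxels/MCS (8-h doubling) |
| basal membrane-contact threshold | 5 | voxels |
| slough probability | 1/720 | per MCS (3-day exposed lifetime) |
| EGF diffusivity (tissue / barrier / limbal membrane) | 186 / 20 / 0 | voxel²/MCS |
| EGF decay | 0.5 | /MCS |
| injury doses (slight/mild/moderate) | 750 / 1500 / 2500 | arb. deposit |

Everything else — the contact-energy matrix, Potts temperature (20),
constraint strengths, the tear-film EGF source level (90 arb. units),
chemotaxis strengths, link constants, post-mitotic size dynamics, and the
injury thresholds — is a calibrated constant, marked `calibrated` in the
config source, chosen once so that the emergent tissue reproduces the
documented tissue-level observables (stratification within a week,
homeostasis within two, ~50 µm central thickness, 7–14-day renewal,
1.75 days/layer transit, dose-graded injury depth) and then frozen. Notable
calibrated choices:

* **Tear-film EGF source = 90 arb. units.** The half-max constants (3.5/7.0)
  and the source level must live on one scale; a source at or below the
  half-max can never stimulate growth, so the source is calibrated well above
  it. Thickness is the most sensitive function of this constant: the
  steady-state EGF penetration depth `≈ sqrt(D/kd)·ln(source/km)` sets where
  basal proliferation stalls.
* **Negative membrane adhesion (−20) for stem–limbal and basal–central
  membrane contacts.** This is the hemidesmosome anchoring analogue: it makes
  the basal monolayer wet the basement membrane and crawl along it, which is
  what lets seven stem cells colonize a 320-µm bare membrane within days.
* **Post-mitotic size dynamics**: wing cells swell toward 150 voxels (large
  transitional cells) and superficial cells condense toward 30-voxel squames.
  In a 2-D section with a fixed desquamation probability, the standing cell
  count per unit thickness sets both the regional turnover time and the
  per-cell transit time; cell sizes are the only free dial that moves both
  into the physiological window simultaneously.
* **Chemotaxis**: basal cells climb EGF gradients (wound-directed migration)
  and descend a limbus-sourced movement-bias field (centripetal drift). Both
  couplings are weak relative to adhesion at homeostasis and matter mainly
  during colonization and wound closure.
* **Toxicant field**: tissue diffusivity 40 voxel²/MCS with the superficial
  barrier at 5 and per-type decay dominated by cellular uptake (0.10 /MCS in
  living cells). Uptake is what makes injury depth dose-dependent: reaching
  deeper layers consumes dose. The cell-death threshold (0.06) and the
  membrane-destruction threshold (0.125) were placed between the measured
  peak exposures of adjacent dose classes, so 750 kills superficial (and a
  few upper wing) cells, 1500 kills through the epithelium with the membrane
  intact, and 2500 also destroys a stretch of basement membrane.

## What the default scenario emulates — and what it does not

The shipped configuration is the package's "synthetic data generator": a
stem-seeded bare membrane (the stem-only start; a `seed_basal` flag
optionally pre-seeds central basal cells, reflecting an ambiguity in how the
day-0 state of such tissues is usually drawn) grown for as many days as the
scenario needs, injured or not. It emulates: stratified architecture with
correct layer ordering, a limbal–central apical-height gradient, EGF-limited
thickness control, stochastic desquamation balanced by proliferation,
dose-graded chemical injury, re-epithelialization, and non-healing erosion
after basement-membrane loss.

It does not emulate: 3-D geometry and circumferential healing fronts, stromal
cellular dynamics or immune response, basement-membrane regeneration,
chemical-specific modes of action, reflex tearing, or receptor-level EGF
kinetics. Passing tests therefore say the rule set reproduces tissue-scale
regularities; they say nothing about molecular mechanism or about phenomena
that live in the third dimension.

## Numerical choices

* **Field solver.** The default scheme is operator splitting: exact
  exponential decay per voxel, then backward-Euler diffusion solved as
  locally-one-dimensional tridiagonal sweeps with harmonic-mean interface
  diffusivities (flux-conserving across the superficial barrier and the
  limbal blocker) and source voxels pinned as Dirichlet nodes inside the
  solves. It is unconditionally stable and positivity-preserving; mass is
  conserved to round-off with no decay and closed boundaries. A
  forward-time central-space (FTCS) reference with automatic substepping is
  also implemented; the test suite shows the implicit scheme converges to
  FTCS within 0.5% as substeps increase. The production substep count (6 per
  MCS for EGF) trades accuracy near source corners for a ~100× speedup over
  stability-limited FTCS at D = 186; the model is calibrated against its own
  discrete field, so this coarseness is part of the model definition, not an
  approximation error on top of it.
* **Boundaries.** Lateral walls are frozen zero-diffusivity agents (no
  flux); the outermost top and bottom rows hold zero concentration.
* **Mitosis tie-break.** Voxels are sorted by signed distance to the
  cleavage plane (ties by coordinates) and split half-and-half, so daughter
  volumes differ by at most one voxel. Both daughters receive fresh ids and
  birth stamps: division consumes the parent. This makes per-cell transit
  times well-defined and regional substitution measure actual cell
  replacement.
* **Connectivity.** Cell connectivity is not enforced (the standard
  neighborhood-order-2 kernel on a square lattice fragments rarely);
  fragments below 3 voxels are culled and logged.
* **Degenerate inputs.** Thickness estimators return `NA` when a layer is
  missing (normal mid-injury); turnover and healing detectors return `NA`
  when a run is too short; the FTCS solver aborts rather than clipping on a
  negative concentration.
* **Randomness.** All stochasticity — copy attempts (via the C++ kernel),
  cleavage angles, sloughing — draws from R's global RNG, so a trajectory is
  a pure function of (config, seed) and `snapshot_state()`/`restore_state()`
  resume bit-identically.
* **Wound-open fraction.** A surface column counts as open if it has no
  superficial cell or if tear film reaches more than 12 voxels below the
  local apical surface; the allowance absorbs the pits left by individual
  squame sloughs, while genuine erosion craters (tear on bare stroma) are
  flagged.

## Design decisions where the rules were open

* **Pressure proxy.** Contact inhibition needs an intracellular "pressure";
  we use `max(0, λ_P (V_target − V))` with λ_P = 25: crowding prevents a cell
  from reaching its target volume, so the volume deficit is exactly the
  crowding signal. Growth acts on the *target* volume; actual volume follows
  through the Potts volume constraint.
* **Wing→super rule.** The transition requires tear contact *and* another
  wing neighbor, with no basal/stem/membrane contact: a lone wing at a wound
  edge does not leapfrog to a squame.
* **Membrane contact area** for the basal rule counts the cell's own voxels
  sharing a face with either membrane zone; the neighbor sets in the other
  rules use the same 8-connected neighborhood as the contact energy.
* **Clamp vs secretion.** The tear film is a fixed-concentration EGF region
  (clamped each substep); no separate secretion term is active when clamping
  is configured.
* **Tear film as a deformable agent.** One tear cell with a volume
  constraint drapes over the apical surface, re-wets wounds (ablated and
  sloughed voxels join it), and sheds excess volume to the medium above, so
  the film tracks the surface at roughly constant thickness.
* **Injury dose semantics.** The printed doses are treated as integrated
  deposits (the Gaussian droplet is normalized to integrate to the dose);
  treating them as peak concentrations would simply rescale the calibrated
  thresholds.
* **Stroma after membrane loss.** Destroyed membrane voxels become stroma —
  a permanent, non-regenerating gap. Bare stroma is tear-wetting and a poor
  cell substrate (high contact energy), so the epithelium above a gap cannot
  re-anchor: cells there differentiate prematurely and the defect persists.

## Known limitations

* **Apical-surface uniformity.** The per-segment apical position fluctuates
  with a pooled SD of roughly 4–5 µm over the stable window — about one
  squame height (2 voxels). The ~2 µm figure reported for this tissue class
  is below the discreteness scale of our calibrated cell sizes, and those
  sizes are pinned by the turnover and transit constraints; we report the
  measured value rather than smoothing it away.
* **Moderate injuries produce persistent defects** rather than discrete
  close-reopen erosion cycles: after membrane loss the wound never satisfies
  the closure-plus-thickness healing criterion within 20 days. Both
  phenotypes are forms of failed re-epithelialization; the model lands on
  the persistent-defect side.
* **Regional turnover is stochastic.** The ≥95% substitution day rests on
  the few longest-lived cells of a ~25-cell limbal census, so it varies by
  several days between seeds.
* **Healing of slight/mild injuries is fast** (typically 1–3 days to
  closure and thickness recovery), at the quick end of the 1–5-day clinical
  window for epithelial injuries.
* The movement-bias field, the link constants, and the contact matrix are
  phenomenological; none should be interpreted as measured mechanical
  quantities.
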