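---
title: "Models and methods: spot size, robustness and interplay in PBS lung plans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: spot size, robustness and interplay in PBS lung plans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the parameters that matter, the numerical choices behind them,
and what the synthetic phantom can and cannot tell you about real patients.

## The question

Pencil beam scanning (PBS) delivers proton dose as a raster of Gaussian
"spots" at discrete energies. The lateral spot width at isocenter — around
3 mm (1σ) on modern dedicated nozzles versus around 8 mm on larger-spot
beamlines, at the highest energy — shapes three things simultaneously: how
steep the achievable dose gradients are (hence robustness to setup and range
errors), how much dose spills into lung, heart, esophagus and cord, and how
sensitive a moving-target delivery is to the interplay between scanning and
breathing. This package builds both machines as two beam models that differ
*only* in lateral width, plans the same synthetic lung case with each, and
compares robustness, radiobiological surrogates and interplay with and
without volumetric repainting.

## Synthetic 4D thorax phantom

The phantom (`generate_phantom()`) is built from analytic primitives: an
elliptic-cylinder body, two ellipsoidal lungs (0.26 g/cc), an ellipsoidal
heart, cylindrical esophagus and spinal cord, and a spherical gross tumor
volume. Breathing moves the tumor along a dominant superior–inferior axis
(with small AP/RL fractions) following a sin² waveform sampled at ten phase
bins; end-exhale (T50) is the rest and reference phase, end-inhale (T0) the
extreme. The union of tumor positions is a capsule — the internal gross
tumor volume (IGTV) — which is overridden to water density on the planning
(reference) grid, and the CTV is the IGTV expanded by an isotropic 5 mm
margin. Defaults: 80³ voxels at 3 mm, 8 mm peak-to-peak amplitude (within
the 2.2–13.2 mm range typical of lung cases planned without gating), 4 s
breathing period with uniform 0.4 s bins. Neither the period nor the
waveform is uniquely "correct" for a synthetic case; both are configuration
with these documented defaults.

The displacement field from the reference phase to phase *p* is rigid
(translation d_p) inside a core radius around the resting tumor sphere and
decays to zero with a cosine taper over a 30 mm annulus — so the *tumor*
moves while the IGTV override stays where planning put it, which is exactly
the override-CT-versus-breathing-anatomy mismatch a real 4D evaluation
probes. Two consequences are worth
stating plainly:

- **Invertibility is guaranteed**, not assumed: the field is a contraction
  whenever amplitude·π/2 < taper width, which the generator enforces. Points
  round-trip through `displace_point()` / `inverse_displace_point()` to
  better than 0.01 mm.
- **Phase densities are the exact pull-back of the reference geometry**
  under this field (the analytic geometry is evaluated at the numerically
  inverted map), so the 4D dose mapping used by the interplay module is
  consistent with the anatomy by construction — unlike image-based
  deformable registration, whose errors would be entangled with the physics
  under test. The radial taper may graze the lung boundary near the chest
  wall; since the field *is* the phantom's ground truth, this is a cosmetic
  blemish, not an inconsistency.

The tumor jitter (±2 mm uniform, seeded) is the only randomness; a fixed
config + seed reproduces the phantom bitwise.

## Analytic pencil-beam dose engine

Each spot deposits `MU × IDD(E, z) × Gaussian(lateral; σ(z))` on the grid,
with z the water-equivalent depth (WED) obtained by straight-ray radiological
path-length tracing along the (axis-aligned) beam direction. Components:

- **IDD**: a power-law Bragg curve (R₀ − z)^{1/p − 1} with range–energy
  relation R₀ = α·E^p (α = 0.022 mm·MeV⁻ᵖ, p = 1.77), smeared by a Gaussian
  combining range straggling (0.012·R₀^0.935 in cm) with a beamline momentum
  spread of 1.5% of range. The momentum term matters: without it the peaks
  are ~2 mm wide (80% width) and no 4 mm-spaced energy ladder can form a
  flat spread-out Bragg peak; with it the achievable ripple is below 1%.
  Nuclear halo and fluence loss are not modelled.
- **Lateral width**: σ(z)² = σ_iso(E)² + (k·R₀·(z/R₀)^1.6)² with k = 0.022 —
  a compact multiple-Coulomb-scattering growth law. σ_iso(E) is anchored at
  3 mm (small) or 8 mm (large) at 226.5 MeV and scales as (E_ref/E)^0.9;
  the shape at other energies is not uniquely determined by the two anchors,
  so it is a configurable default. The two models share IDDs, energy list
  and absolute output exactly.
- **Units**: cGy(RBE) with a constant RBE of 1.1 folded into the output
  (physical-dose mode via `rbe = FALSE`). The absolute MU calibration sets
  the reference-energy IDD peak to 400 cGy·mm²/MU, chosen so realistic plans
  land at a few MU per spot — comfortably above the 0.015 MU deliverability
  floor, which then only binds through explicit repainting fallbacks.

**Scenario semantics.** Range uncertainty is a multiplicative scaling of the
water-equivalent depth (±3.5%), not a CT recalibration. A setup shift
translates the beam apparatus: the lateral components displace the spot
pattern, while the component along the beam axis leaves the dose unchanged,
because in a parallel-beam, surface-referenced model the rays and the
material they traverse are identical. The alternative — shifting the depth origin too, which slides the whole
spread-out Bragg peak by the full 5 mm — collapses worst-case coverage far
out of scale with any clinical robustness analysis; treatment planning
systems perturb the isocenter and recompute, which on slab-like anatomy is
depth-neutral.
The lateral-translation semantics is therefore the deliberate design choice;
the shift-equivalence property (dose translates by the shift) holds exactly
for lateral components and the longitudinal no-op is itself asserted by a
test.

## SFUD planning and robust optimization

`place_spots()` lays a lateral grid of pitch 1.0·σ_iso(E_ref) per energy
layer (layers every 4 mm of water range across the CTV's WED extent ±4 mm),
dilated laterally by 1.5σ for penumbra **plus 5 mm for the setup envelope**.
The second margin is essential and easy to miss: a robust optimizer can only
hold coverage under a 5 mm shift if spots exist where the shifted target
moves; with a σ-proportional margin alone the small-spot machine (4.5 mm)
is structurally unable to cover the scenarios while the large-spot machine
(12 mm) gets the margin for free, which confounds the comparison.

`robust_optimize()` treats each field independently (single-field uniform
dose): nonnegative MU weights minimize a smooth worst case — log-sum-exp
softmax, sharpness 12 in units of the initial loss — over the nominal plus
the same 12 scenarios used for evaluation, of an asymmetric quadratic CTV
term (underdose weighted 4× over overdose, as clinical optimizers do,
because the cold tail sets D99) plus a hinge penalty on overdose to a
6–20 mm normal-tissue shell. L-BFGS-B with analytic gradients and cached
per-scenario influence matrices (C++ kernels) converges in a few hundred
iterations; CTV and shell points are deterministic seeded subsamples (1200 /
800). Weights below half the 0.015 MU floor are dropped, the rest clamped up
to it. `normalize_d99()` then scales all MUs so CTV D99 = 6930 cGy(RBE)
(99% of the 7000 cGy(RBE), 35-fraction prescription); linearity makes the
renormalized D99 exact to interpolation (±1 cGy), and spots pushed below the
floor by a downscale are reported, never silently dropped.

`make_volumetric_repainting()` splits each spot's MU over five full passes;
odd paintings traverse layers distal→proximal, even ones in reverse, so
consecutive paintings meet at the same energy and no switch time is wasted
at painting boundaries. If an even split falls below 0.015 MU the spot's
painting count is reduced to floor(MU/0.015) (at least one), assigned to
the earliest paintings. The last pass carries the floating-point remainder,
so painting MUs sum *bitwise* to the planned MU and the repainted plan's
static dose is identical to the unpainted plan's.

## Metrics, robustness and radiobiology

DVHs are cumulative, 1 cGy bins, with the raw sorted voxel doses retained:
mean dose and D0.03cc are computed on voxels (the latter by nearest voxel
count on the hot tail) to avoid bin-resolution bias; Dx% uses inverse-DVH
lookup with linear interpolation, which can sit up to half a bin above the
exact order statistic — hence the ±1 cGy language wherever D99 is pinned.
Worst-case aggregation over the 12 scenarios takes the minimum for coverage
and homogeneity (HI = D99/D1) and the maximum for hot spots and all
organ-at-risk metrics; the direction is declared per metric rather than
inferred at run time, and the nominal scenario is reported separately, not
folded into the extreme.

EUD/NTCP: organ voxel doses are converted per voxel to EQD2 with the plan's
35 fractions, then power-mean-averaged with the organ's volume-effect
exponent. The organ parameters (a, α/β, TD₅₀, γ₅₀) are *configuration*, not
outputs: the shipped YAML registry uses photon-derived whole-organ defaults
(lung/pneumonitis a = 1.15, α/β = 3, TD₅₀ = 24.5 Gy, γ₅₀ = 2;
heart/pericarditis 2.9/3/48/3; esophagus/esophagitis 16.7/10/68/4). For
validation the package instead *derives* lung parameters from two published
(EUD, NTCP) pairs by the exact two-point solve in log-odds space
(ln((1−N)/N) = 4γ₅₀ ln(TD₅₀/EUD)), giving TD₅₀ ≈ 26.9 Gy (EQD2) and
γ₅₀ ≈ 1.99, and checks the forward model against the remaining printed
values. One printed value (0.03%) sits on a two-decimal rounding boundary:
the exact forward value from the rounded anchors is 0.036%, which rounds to
0.04 — an irreducible consequence of fitting to two-decimal inputs, visible
in the test suite as a known discrepancy.

## Interplay simulation

`build_timeline()` lays out the delivery: 4 ms per MU per spot, lateral
travel at 250 cm/s between spots of a layer, 1 s per energy switch, fields
sequential with a 30 s gap (beamline switch; the value is configuration —
it only offsets the breathing phase at which the second field starts).
Whether the 4 ms/MU includes a fixed per-spot overhead is not specified by
the delivery-parameter convention we follow; we model pure MU-proportional
time. Each spot is assigned *whole* to the breathing phase active at its
start time (spot durations are milliseconds against 0.4 s bins);
the phase of an event at time t is floor(((t + offset) mod T)/(T/10)) with
offset 0 for a T0 start and T/2 for T50. Per phase, the assigned spots'
dose is computed on that phase's density, pulled back to the reference
phase through the analytic displacement field (trilinear, followed by a
global energy renormalization that conserves Σ dose×mass to well under
0.5%), and accumulated. A single *fraction* is simulated — the plan's MU
divided by its 35 fractions sets the spot durations, because that is the
session a real delivery interleaves with breathing — and the accumulated
dose is scaled back to course units (all fractions identical under a fixed
start phase; inter-fraction averaging would only dilute the effect under
study). Getting this timescale right matters more than it looks: delivering
the whole course's MU in one simulated session stretches each painting to a
near-integer number of breathing periods for this plan, and strictly
periodic breathing then *synchronizes* with the alternating paintings — each
pass repeats nearly the same phase pattern and repainting stops averaging
anything. Delivery/breathing synchronization is a real failure mode of
repainting under periodic motion, and the periodic-breathing phantom will
show it whenever painting duration and period are close to commensurate.

With zero amplitude the accumulation reproduces the static dose voxel for
voxel, and forcing all spots to the reference phase reproduces it exactly —
the two identities that anchor the simulation.

## Problem sizes and what passing tests mean

The study conditions are the generator defaults: 80³ voxels at 3 mm, 8 mm
amplitude, seed 7 for the default study phantom; the unit-test phantom is a
44³ miniature with the same structure. These sizes keep the full pipeline —
two models planned, 13 dose recomputations each, and eight interplay
simulations — in the minutes range on one CPU.

What the phantom does *not* emulate: CT-number heterogeneity beyond
piecewise densities (no ribs, no tissue texture), lateral heterogeneity
within a pencil's footprint (WED is traced along the central axis only — a
stated limitation of the engine, adequate for slab-like geometry), irregular
or drifting breathing, rotational setup errors, and anatomies where beam
angles must be individualized. Consequently, passing tests demonstrate that
the *machinery* — worst-case bookkeeping, EUD/NTCP arithmetic, timeline
construction, 4D accumulation — is correct, and that the qualitative
mechanisms (sharper gradients → better worst-case coverage and lower OAR
dose for small spots; broader spots → natural smoothing of interplay;
repainting → recovery of target coverage) operate in the expected
directions. Cohort-scale magnitudes from real patients are outside what a
single synthetic phantom can reproduce, and the package does not claim
them.
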