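---
title: "A lumped-element middle-ear model for bone conduction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lumped-element middle-ear model for bone conduction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcear)
```

## The mechanical model

`bcear` treats the middle ear as six lumped degrees of freedom, all
displacements horizontal along a common axis:

| node | element | inertia |
|------|---------|---------|
| X0 | skull (promontory reference) | `M0` |
| X1 | air column in the ear canal | `M1` |
| X2 | tympanic membrane | `M2` |
| X3 | malleus tip (umbo) | `I3/L3^2` |
| X4 | incus tip | `I4/L4^2` |
| X5 | stapes + entrained cochlear fluid | `M5 + M6` |

The eardrum hangs from the skull (`K1`, `C1`), couples to the canal air
(`K2`, `C2`) and to the umbo (`K3`, `C3`). Malleus and incus are rigid
pendulums hinged to the skull: their suspensions (`Km_t`, `Cm_t`, `Ki_t`,
`Ci_t`) and the incudomalleolar joint (`Kmi_t`, `Cmi_t`) are torsional,
and the small-angle substitution `theta3 = (X3 - X0)/L3`,
`theta4 = (X4 - X0)/L4` turns each torque balance into a force balance on
the tip displacement. Torsional fields carry the `_t` suffix so N/m and
N·m/rad quantities cannot be mixed. The incudostapedial joint (`K6`,
`C6`) drives the stapes, which is suspended in the oval window by the
annular ligament (`K8`, `C8`); the cochlear fluid adds its mass `M6` to
the stapes, a viscous resistance `C9` against the skull, and closes
through the round-window stiffness `K9`.

Assembling the per-node balances gives `(-w^2 M + i w C + K) X = F`. Two
deliberate asymmetries are part of the model, not bugs:

* **Row X0 is pure inertia** (`M0 a0 = F0`). The reaction forces the
  suspended elements exert on a multi-kilogram skull are negligible, so
  column X0 carries coupling terms while row X0 does not, and the 6×6
  `K`/`C` matrices are asymmetric in exactly that column. The package
  asserts the complementary property: the X1…X5 block is exactly
  symmetric.
* **The model is linear.** Velocities are `V = i w X` by construction and
  responses scale exactly with stimulus amplitude; there is no
  large-displacement mechanics.

Because row X0 has no stiffness, the static problem (`f = 0`) is
singular; `solve_response()` therefore requires strictly positive
frequencies rather than special-casing DC.

### Stimulation and outputs

Bone conduction is a harmonic force on X0; air conduction a pressure in
the canal converted by `F1 = p * A_canal` at X1; `stim_node()` places a
force at any node (e.g. an implant actuator on the incus). `A_canal` is
not part of the mechanical fit — it only scales AC results. No canonical
value ships with the fitted set, so the package defaults to
4e-5 m², a typical adult canal cross-section; set it explicitly when
absolute AC levels matter.

The measured quantities the model reproduces are velocity ratios:
relative, `(Vnode - Vprom)/Vprom`, the differential motion that pumps the
cochlea in BC; absolute, `Vnode/Vprom`; and for AC runs `Vnode/Pec`. The
relative and absolute kinds satisfy `absolute = relative + 1` pointwise
in the complex plane, which the tests assert exactly — a useful algebraic
cross-check on the whole pipeline.

## Parameter sets

`builtin_params()` ships the model's fitted set and the three literature
air-conduction sets it was seeded from. Literature sets are incomplete
for this six-node topology; the package fills the gaps explicitly and
records every substitution in the object (and as messages unless
`quiet = TRUE`):

* canal-air mass `M1` absent → taken from the Feng–Gan set;
* skull mass absent from all three → the fitted 5 kg (it only sets the
  rigid-body reference and cancels out of the relative ratios' shape);
* absent stiffness/damping elements → 0;
* the rigid ("fused") incudomalleolar joint of the Rosowski–Merchant set
  → a large finite `Kmi_t`/`Cmi_t`, `fused_scale = 1e6` times the fitted
  joint values. The tests verify a 10× change of this constant moves the
  transfer magnitudes by under 1e-3 dB, so the exact constant is
  immaterial; the resulting stiffness contrast (~1e10) is logged by the
  conditioning monitor but is harmless for a direct 6×6 solve.

One deliberate naming choice: the round-window stiffness is stored as
`K9` alongside the fluid damping `C9`, since it is the same physical
branch (fluid back to skull); some middle-ear circuit diagrams label it
K10.

## The virtual experiments

`apply_perturbation()` implements the seven protocol conditions as pure
parameter edits (stapes glued `K8 := 5e4`; malleus glued `Km_t := 0.8`;
100 mg on the eardrum `M2 += 1e-4`, `C1 := 0.4`; IS joint cut; 20 mg —
or 7.5 mg — on the stapes `M5 += m`; cochlea drained). The
post-separation conditions compose after the joint cut, exactly as the
physical experiments were sequenced.

Two conditions needed an interpretation decision, and both options are
exposed rather than silently chosen:

* **IS-joint cut.** The protocol table's printed rule zeroes the annular
  ligament (`K8`) and the joint damping, which leaves the joint stiffness
  `K6` active — under that rule the stapes keeps a ~2 kHz resonance and
  its motion at 1 kHz *rises* ~3 dB, the opposite of the documented
  observation that separation removes the resonance and reduces stapes
  motion at 1–2 kHz. Zeroing the joint itself (`K6 := 0, C6 := 0`)
  reproduces the observation, and with it the stapes suspension
  (`K8 + K9` on `M5 + M6`) is overdamped (`zeta ≈ 1.2`) — no peak, as
  described. The package default is therefore the `k6` variant; the
  literal printed rule remains available as `isjc_variant = "k8"`.
* **Cochlea drained.** The printed rule zeroes only the fluid resistance
  and round-window stiffness. Keeping the fluid mass, the drained stapes
  curve sits above normal at 1 kHz and never crosses the normal curve;
  removing the entrained mass as well (`M6 := 0`, the physical meaning of
  an emptied cochlea) yields the documented behaviour — suppression below
  ~2 kHz, elevation above, a single resonance from the annular-ligament
  suspension. `drain_fluid_mass = FALSE` restores the literal rule. Note
  the remaining suspension is heavily damped (`zeta ≈ 0.47` from `C8`),
  which pushes the relative-transmissibility peak well above the
  undamped natural frequency `sqrt(K8/M5)/2pi ≈ 3.8 kHz` — the package
  computes the peak near 5.1 kHz, somewhat above the ~4 kHz the
  protocol's reports quote for this condition.

`run_condition_matrix()` executes the full measurement grid — umbo under
five conditions, stapes under seven — returning 12 condition curves in
both kinds with resonance reports, one linear solve per distinct
condition.

## Numerical choices

* **Grid.** 512 log-spaced points over 0.1–10 kHz (`default_grid()`),
  the span middle-ear transfer functions are reported over. The umbo's
  second resonance sits close to the top of that span, so feature
  extraction that needs it (e.g. the acceptance script's second-peak
  report) uses 640 points to 16 kHz; peak-frequency discretisation error
  after refinement is well under 0.5 %.
* **Solve.** Dense complex LU (`solve()`) per frequency — at 6×6 there is
  nothing to precondition. The reciprocal condition number is estimated
  at every frequency and a note is emitted when the worst exceeds 1e10
  (reached only by the deliberately extreme fused-joint constant or
  user-supplied extremes).
* **Peaks.** Strict local extrema of the magnitude curve with
  topographic prominence ≥ 0.5 dB, low enough to keep the genuinely
  shallow resonance of the mass-loaded stapes (~1 dB prominence) and
  high enough to reject grid-level ripple; locations refined by a
  quadratic through the three surrounding samples in log-frequency.
  Verified against the closed-form peak of a one-DOF oscillator to
  within 1 %.
* **Crossovers.** Sign changes of the magnitude difference, interpolated
  linearly in log-frequency (exact for curves linear in `log f`); exact
  zeros count only when the curves actually change sides. Reported
  features use the first crossover above 200 Hz — below that both curves
  ride their numerical floor and sign flips are meaningless.
* **Decibels and phase.** `20 log10 |ratio|`, with exact zeros floored
  at −300 dB; phase unwrapped along increasing frequency and reported in
  cycles.
* **Determinism.** The pipeline has no randomness; property tests that
  draw random parameter sets and states use fixed seeds, and the CLI
  manifest re-runs reproduce outputs byte-identically.

## What the tests do and do not show

The oracle for the assembly and solver is an independent transcription of
the six nodal balances in Newton/torque form (the pendulum substitution
carried out numerically), evaluated on random parameter draws; agreement
is required to 1e-12 (rows) and 1e-10 (solutions). Directional checks —
gluing suppresses, added mass lowers resonances, joint separation leaves
the umbo nearly unchanged — mirror the qualitative experimental findings.
Problem sizes throughout (64–640 grid points, 6×6 systems, 20-draw
property loops) keep the full suite in the tens of seconds.

Passing these tests shows the implementation solves *this* model
correctly and that the fitted parameterisation reproduces the documented
resonance/crossover features. It does not validate the model against
raw measurements: measured mean curves are not shipped (only their
reported features are used), inter-ear variance is outside the model,
and phases of the BC measurements were never reported.

## Known limitations

* Ossicles move only rotationally; translational ligament compliance is
  omitted, so the measured spread of second resonances across ears
  (3–10 kHz) collapses to a single high resonance here.
* The cochlea is a mass + resistance + window stiffness; intracochlear
  pressures and bone-compression pathways of BC are out of scope.
* Parameter fitting is not automated: the fitted set ships as data, and
  `parameter_ratio_report()` only audits it against references (the
  eardrum mass, at 5× its adopted value, is the one standout).
* The AC path's absolute scale depends on the un-fitted `A_canal`.
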