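---
title: "Personalising a 1D/0D model of aortic pulse wave haemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalising a 1D/0D model of aortic pulse wave haemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsewave)
```

## The modelling problem

`pulsewave` simulates blood pressure, flow and luminal area waves in the
upper aorta and its three arch branches (brachiocephalic, left common
carotid, left subclavian), and — just as importantly — calibrates every
material and boundary-condition parameter of that model from the kind of
data a non-invasive clinical study actually produces: gated PC-MRI volume
flow waveforms, cine MRI luminal area waveforms and applanation-tonometry
pressure waveforms, acquired at different times and at slightly different
heart rates.

The arterial domain is a tree of 26 tapered segments
(`upper_aorta_segments()` ships the reference geometry of a young healthy
adult: a 33.6 cm aortic chain plus three arch branches, four terminal
outlets). Each
segment carries one axial coordinate $x$; the unknowns are cross-sectional
area $A(x,t)$, flow $Q(x,t)$ and pressure $P(x,t)$.

## Governing equations

Mass and momentum balance for an incompressible Newtonian fluid in a
deformable axisymmetric vessel:

$$\partial_t A + \partial_x Q = 0, \qquad
  \partial_t Q + \partial_x\!\left(\frac{Q^2}{A}\right)
  + \frac{A}{\rho}\,\partial_x P = -\,\frac{2(\zeta+2)\pi\mu}{\rho}\frac{Q}{A},$$

where $\rho$ is blood density, $\mu$ viscosity and $\zeta$ the polynomial
order of the axial velocity profile (the friction coefficient
$2(\zeta+2)\pi\mu$ follows from that profile; $\mu = 0$ selects the
inviscid model). The system is closed by the elastic tube law

$$P(A) = P_d + \frac{\beta}{A_d}\left(\sqrt{A} - \sqrt{A_d}\right),$$

with $A_d$ the area at the diastolic reference pressure $P_d$ and $\beta$
the wall elasticity parameter. The implied pulse wave velocity is
$c(A) = \sqrt{\beta/(2\rho A_d)}\,A^{1/4}$, so at diastole
$\beta = 2\rho c_d^2 \sqrt{A_d}$: one measured diastolic speed per
location fixes the material law. For a thin membrane of thickness
$h = 0.1\,r_d$, the equivalent Young modulus is
$E = 3\beta/(4\sqrt{\pi}h)$, independent of the radius.

Each terminal vessel discharges into a three-element Windkessel: proximal
resistance $R_1$, then a distal resistance $R_2$ in parallel with a
compliance $C$, emptying at the outflow pressure $P_{out}$ (the pressure
at which microcirculatory flow ceases). The measured ascending-aorta flow
waveform is prescribed at the root, with the outgoing characteristic
absorbed so the inlet does not act as an artificial reflector.

## Estimating pulse wave velocity from data

Two estimators are implemented:

* **foot-to-foot** (`foot_to_foot_speed()`): the wave foot — the
  intersection of the horizontal line through the pre-systolic minimum
  with the tangent through the point of maximum upstroke gradient — is
  detected at two sites, and the speed is the centreline distance over
  the transit time. Waves are first resampled onto a fine periodic-spline
  grid, because signals gated to 40 cardiac phases resolve the foot too
  coarsely. The resulting single speed is mapped uniformly to the whole
  network. On solver-generated data this estimator lands within about 5%
  of the generating speed; the residual bias comes from wave steepening
  and the finite upstroke.

* **QA-loop** (`qa_loop_speed()`): the slope $dQ/dA$ of the flow–area
  loop over the early-systolic limb, where the loop is linear before
  reflections arrive. The fit window runs from the detected foot to the
  time of maximum $dQ/dt$ (a configurable margin can extend it; the
  default margin is zero because reflections from the arch junctions
  reach the ascending aorta within one upstroke) and, among admissible
  windows, the one with the best linear fit is kept. Site estimates are
  condensed into a power law $c = a\,d^{b}$ in the diastolic diameter
  (`fit_speed_diameter_power_law()`; for a uniform $\beta$ the theory
  gives $b = -1/2$), which lets `assign_wave_speeds()` evaluate a local
  speed anywhere in the network. QA-loop estimates are known to be far
  noisier than foot-to-foot ones; on solver-generated data the
  ascending-plane estimate errs by roughly 10%, the distal planes by a
  few percent.

## Calibrating the outlet parameters

`calibrate_windkessel()` runs the full chain:

1. **Outflow pressure.** Either a single assumed capillary pressure
   (default 33 mmHg, configurable), or the asymptote $P_\infty$ of the
   exponential fit $P(t) = P_\infty + (P_0-P_\infty)e^{-(t-t_0)/\tau}$ to
   the late-diastolic pressure decay (`fit_diastolic_decay()`), averaged
   over the available tonometry sites. The fit window ends at the
   pre-upstroke minimum of the next beat; candidate start times are
   scanned over the final 60% of the decay and the best-fitting window is
   kept.
2. **Resistances.** Total resistance $R_T = (\bar P - P_{out})/\bar Q$
   from the mean carotid pressure and mean inflow; per-terminal totals
   $R_{T,j} = R_T/\gamma_j$ from the flow fractions $\gamma_j$.
3. **Compliances.** Total systemic compliance either from the decay time
   constant ($C_T = \tau/R_T$) or, in capillary mode, from the inflow
   extrema and pulse pressure
   ($C_T = (Q_{max}-Q_{min})\,\Delta t/(P_s-P_d)$, with $\Delta t$ the
   cyclic spacing of the extrema — the minimum sits just before the next
   upstroke). Subtracting the conduit compliance of the 1D segments
   ($C_c = \sum_s \int 2A_d^{3/2}/\beta\,dx$) leaves the peripheral
   compliance, split across terminals in proportion to $\gamma_j$ and
   converted to the three-element value $C_j = C_{p,j}(R_{T,j}/R_{2,j})^2$
   (low-frequency equivalence of the RCR circuit to an RC one; the
   identity when $R_1 = 0$).
4. **Proximal resistances.** The supra-aortic branches are matched:
   $R_1 = Z_0 = \rho c_d/A_d$ at each endpoint, which minimises waves
   re-reflected at those outlets. The descending aorta can instead be
   *reflective*: linear wavefront theory attributes the drop from the
   systolic peak $p_S$ to the inflection point $p_I$ on its decay to the
   wave reflected at the aortic outlet, giving
   $R_f = -(p_S-p_I)/(p_S-P_\infty)$ and
   $R_1 = Z_0(1+R_f)/(1-R_f)$. A drooping inflection therefore yields a
   negative reflection coefficient, which lowers reflected pressure and
   raises reflected flow — and is what generates the diastolic pressure
   peak in the carotid wave.

Because the capillary-mode compliance estimator is deliberately crude,
`refine_windkessel()` then iterates the 1D/0D model against the measured
carotid systolic/diastolic pressures: distal resistances are rescaled by
the pressure-level ratio and compliances by the pulse-pressure ratio
applied to the *total* (conduit plus peripheral) compliance; from the
second iteration a secant step on $\log PP$ vs $\log C_p$ replaces the
unit-gain rule, which matters because the pulse pressure responds
sublinearly to the peripheral compliance when the inflow is prescribed.
On self-consistent synthetic data a 35% compliance perturbation is
corrected to sub-1% systolic/diastolic errors in a single iteration, and
the closed calibration loop recovers the generating $R_2$ within 2% and
$C$ within 5% per terminal.

## Reconciling inconsistent measurements

Multi-modal sessions violate simple physics: each acquisition catches a
different heart rate, anatomy scans and dynamic area scans disagree on
diastolic areas, and measured mean flow can *increase* down the aorta.
`pulsewave` mitigates all three:

* `harmonize_heart_rate()` assigns every waveform the equally weighted
  mean heart rate, by affine rescaling of the time axes (cycle means are
  preserved exactly; the operation is idempotent).
* `rescale_geometry()` corrects model radii so diastolic areas match the
  dynamic measurements at the imaging planes, with linear interpolation
  of the area factor between planes, constant extrapolation beyond them
  and the mean aortic factor applied to the arch branches.
* `compute_flow_fractions()` takes the descending-aorta outflow fraction
  as the mean of the four descending-plane mean flows over the ascending
  mean, flagging data where a descending mean exceeds the ascending one
  beyond tolerance; prior weights split the remainder among the branches.

Pulse wave velocity is estimated from the waves *as recorded* (before
harmonization): affine retiming would displace the wave feet and distort
transit times, whereas the recordings themselves carry the propagation
information undistorted.

## The synthetic data generator

Because the package must be testable without any external data, the
`synthetic_data` functions create complete, self-consistent measurement
sessions:

* `make_upper_aorta_network()` builds the 26-segment reference geometry with
  either wave-speed column.
* `make_inflow()` produces a smooth periodic ascending-aorta flow:
  a skewed systolic ejection pulse whose cycle integral equals the stroke
  volume exactly, an optional end-systolic backflow dip (valve closure)
  and a small decaying diastolic flow. Defaults are a heart rate of
  61.2 bpm and a stroke volume of 85 ml (cardiac output ≈ 5.2 l/min,
  typical for a young adult male at rest); the default dip is zero so the
  waveform is non-negative.
* `make_reference_windkessel()` turns nominal circulation targets (mean
  pressure 90 mmHg, decay time constant 1.3 s, outflow pressure 33 mmHg,
  a mildly reflective descending aorta with $R_f = -0.15$) into a
  ground-truth outlet parameter set using the same lumped relations the
  calibration chain uses.
* `generate_self_consistent_dataset()` runs the solver and samples
  P/Q/A at the mapped measurement planes (ascending aorta, four
  descending planes, carotid outlet), optionally gated to 40 cardiac
  phases by bin averaging and perturbed with seeded Gaussian noise scaled
  to each signal's pulse amplitude. Generated area and pressure waves
  satisfy the tube law pointwise.
* `synthetic_session()` then emulates the *session*: the five flow waves
  are retimed to heart rates with mean 61.5 and SD 3.4 bpm, the area
  waves to 65.2 ± 1.5 bpm and the pressure waves to 59.3 ± 2.4 bpm.
  A heart-rate change mostly stretches diastole, so the retiming keeps
  the systolic part of each cycle fixed and stretches the remainder —
  this also reproduces the unphysical mean-flow patterns that motivate
  the reconciliation step, since a shorter cycle with the same stroke
  volume carries a higher mean flow. Brachial and radial tonometry
  traces are emulated from the carotid wave by mild peripheral
  amplification about the fitted asymptote, so all three share one
  diastolic decay.

What the generator does **not** emulate: imaging physics (partial-volume
effects, k-space artefacts), segmentation error structure, breath-hold
motion, oblique measurement planes, or beat-to-beat variability within an
acquisition. Passing tests on these data therefore demonstrate the
internal consistency and numerical fidelity of the pipeline, not its
robustness to every failure mode of real measurements.

## Numerical scheme

The solver (`run_simulation()`, compiled core in C++) advances the
conservative variables with the two-step Richtmyer Lax–Wendroff scheme,
second order in space and time, on per-segment uniform grids (default
target cell 2.5 mm; strongly tapered segments are refined so the radius
changes by at most 2% per cell). Three details matter for accuracy on
tapered, stiffness-graded vessels:

* the momentum source created by axial variation of $A_d$ and $\beta$ is
  discretised with *well-balancing corrections* so that the diastolic
  rest state is an exact discrete equilibrium of both scheme stages;
* boundaries communicate through the diastolic-referenced Riemann
  invariants $V_\pm = u \pm 4(c - c_d(x))$, which vanish at rest; along
  the characteristics they obey
  $dV_\pm/dt = -G - f u/A \pm (u\pm c)(2cb'/b - 4c_d')$ with
  $G = [b'(\sqrt A - \sqrt{A_d}) - b(\sqrt{A_d})']/\rho$, and both the
  foot value and this source are interpolated *quadratically* over the
  three nodes nearest each boundary (property gradients use second-order
  one-sided stencils at the end nodes). Without these corrections the
  characteristic coupling rectifies a spurious mean flow of several
  percent per junction in strongly tapered branches; with them the global
  cycle volume balance closes to well below 0.1%.
* junctions solve, by Newton iteration per time step, exact mass
  conservation plus continuity of total pressure $P + \tfrac12\rho u^2$
  between parent and children, coupled to the incoming characteristics;
  terminal outlets advance the Windkessel compliance node implicitly.

The time step follows a CFL condition on the diastolic wave speeds with a
2 m/s velocity headroom (Courant number 0.5 by default); violation at run
time, a non-positive area, or Newton failure abort with a diagnostic.
Cycles repeat (at least 4, configurable) until the relative L2 change of
the monitored plane pressure between consecutive cycles falls below the
periodicity tolerance (1% by default; the calibration and test harnesses
use 10⁻³–3·10⁻⁴ where mass-balance statements are asserted). Verified
properties include: exact steady states, the Poiseuille-type friction law
within 1%, junction mass residuals below 10⁻¹⁰ of peak inflow, wavefront
reflection/transmission coefficients at area steps within a fraction of a
percent of linearised theory, and the lumped Windkessel ODE limit within
2% RMS for a short stiff segment.

## Scenario presets

`run_scenario()` ties everything together (reconcile → PWV → calibrate →
refine → simulate → score). Two presets differ in exactly one independent
parameter, the outflow pressure:

* **best-area** — capillary $P_{out}$ (not subject-specific), uniform
  foot-to-foot speeds, reflective descending aorta, viscous blood. It
  reproduces aortic area waveforms best.
* **best-pressure** — fitted asymptotic $P_{out}$ (subject-specific),
  otherwise identical. It reproduces the carotid pressure waveform best.

Error metrics (`compute_relative_errors()`) are cycle statistics of
foot-aligned waveform pairs; `avg` and `max` are normalised by the
measured cycle mean for pressure and area and by the measured peak-to-peak
amplitude for flow (whose cycle mean approaches zero in distal vessels),
`sys`/`dias` compare the cycle extrema directly. On the emulated session
the best-area preset keeps average flow errors within 7% and area errors
within 4% at every plane; the best-pressure preset keeps the carotid
pressure error within 4%. Setting $\mu = 0$ on the calibrated best-area
model changes the per-quantity mean of the average errors by well under
0.4 percentage points (the single most sensitive waveform, the most
distal flow with the smallest normaliser, can move by about 0.5 points —
the flow normalisation makes this figure the least robust of the error
summaries).

Directional findings on the emulated subject mirror the physiology: the
reflective aortic $R_1$ carries a negative reflection coefficient and
produces a diastolic carotid pressure peak that a matched outlet
suppresses (the peak needs the valve-closure backflow dip in the inflow
to be visible at all), and distributed QA-loop speeds — biased stiff —
underpredict aortic areas at every plane relative to the uniform
foot-to-foot mapping.

## Problem sizes and determinism

The shipped tests and the acceptance script run the 26-segment network
with roughly 300 axial nodes and time steps of 30–40 µs, simulating 6–24
cardiac cycles per call; a full scenario takes seconds on one core. All
generators are deterministic under a fixed seed; the only randomness is
the optional measurement noise.

## Known limitations

* The wall law is elastic and axisymmetric: no viscoelasticity,
  anisotropy, or 3D membrane mechanics.
* The reflective-$R_1$ formula rests on a single-wavefront linearisation;
  on synthetic data it reproduces the sign and magnitude class of the
  generating reflection coefficient but not its exact value, which is one
  reason the refinement loop exists.
* The exponential decay fit inherits the classic identifiability
  trade-off between $\tau$ and $P_\infty$ over a window shorter than
  $\tau$; its asymptote is reliable only when late-diastolic inflow is
  near zero.
* Flow error metrics at distal planes divide by a small peak-to-peak
  amplitude and should be read with that in mind.
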