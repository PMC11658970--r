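---
title: "Modeling nanoparticle detection with a search coil: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling nanoparticle detection with a search coil: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`searchcoil` models a perivascular diagnostic concept: superparamagnetic
iron-oxide nanoparticles (MNPs) circulate in the bloodstream, an AC drive
coil magnetizes them, and a passive pickup ("search") coil develops an
induced voltage as they pass. The package chains five physical stages —
magnetization, drive field, dipole flux, particle transport, and Faraday
induction — and closes with a detection-limit and dose-safety analysis.
This vignette records the model in each stage, the tunable parameters, the
numerical design choices, and what the synthetic scenarios do and do not
capture.

## Magnetization: Langevin and Jiles–Atherton

A superparamagnetic ensemble magnetizes along the anhysteretic curve
$M_{an}(H_e) = M_s L(H_e/a)$, where $L(x) = \coth x - 1/x$ is the Langevin
function and $H_e = H + \alpha M$ is the effective field including the
mean-field interdomain coupling $\alpha$. Hysteresis enters through the
scalar Jiles–Atherton model, which splits $M$ into a reversible part
$c\,M_{an}$ and an irreversible part $(1-c)\,M_{irr}$ dragged behind
$M_{an}$ by the pinning parameter $k$:

$$\frac{dM_{irr}}{dH_e} = \frac{M_{an}(H_e) - M_{irr}}{k\,\delta}, \qquad
  M = c\,M_{an}(H_e) + (1-c)\,M_{irr},$$

with $\delta = \pm 1$ the sweep direction and the standard clamp that sets
the pinning term to zero when it would push $M_{irr}$ away from $M_{an}$
against the sweep (no negative dissipation). The five parameters
($M_s$, $a$, $k$, $c$, $\alpha$) ship as presets for iron oxide
($2.88\times 10^5$, $10^5$, $5\times 10^5$ A/m, $0.95$, $0.5$) and cobalt
ferrite ($2.40\times 10^7$, $10^5$, $2\times 10^5$ A/m, $0.4$, $1.4$).

**Formulation variant.** The literature carries two common closures:
$M_{irr}$ driven by $H_e$ (above, the default), and the "classic" explicit
ODE in $H$ with denominator $\delta k - \alpha(M_{an}-M_{irr})$. Both are
implemented (`formulation = "effective_field"` / `"classic"`); for the
weakly coupled iron-oxide preset they agree to about 0.2% of $M_s$ at the
operating field. The classic form is undefined when its denominators change
sign, which the cobalt-ferrite parameters trigger almost immediately — the
integrator then fails with the offending field value rather than returning
an unphysical branch.

**Why the integrator marches in $H_e$.** With $M$ an explicit function of
$(H_e, M_{irr})$, the state can be advanced robustly in $H_e$-space and the
applied field recovered as $H = H_e - \alpha M$. Whenever
$\alpha\,dM/dH_e > 1$ (cobalt ferrite: $\alpha M_s/3a \approx 112$), $H$ is
non-monotone in $H_e$ and any $dM/dH$ form diverges; physically the
quasi-static response is a Barkhausen-like avalanche. The marcher resolves
these naturally: it keeps advancing $H_e$ (RK4 substeps, default
$\min(a,k)/40$, a local-susceptibility predictor, and a bisected final
substep to land exactly on each requested waypoint) until $H$ reaches the
target. Loop sampling therefore always returns $M$ at the prescribed,
piecewise-monotone $H$ waypoints. A step-halving check in the test suite
confirms convergence to better than $10^{-4}$ relative.

**Loop phenomenology and thresholds.** The qualitative contrast —
iron oxide superparamagnetic-like, cobalt ferrite strongly hysteretic — is
made testable with explicit thresholds: iron oxide remanence below 5% of
$M_s$, and cobalt-ferrite remanence and coercivity each at least 5 times
iron oxide's. One consequence of the cobalt parameters worth recording: its
coupling field $\alpha M_s \approx 3.4\times 10^7$ A/m dwarfs the
$2\times 10^5$ A/m sweep that saturates iron oxide, so a cobalt loop swept
only that far never reverses (it is a minor loop pinned near $+M_s$). The
loop-shape tests therefore sweep cobalt ferrite to $5\times 10^7$ A/m,
where the full square loop with coercivity of order $3\times 10^7$ A/m
appears.

**Single-particle moments.** Particles are magnetized from rest, so moment
queries evaluate the *initial* magnetization curve at the drive amplitude
and multiply by the sphere volume $(\pi/6)d^3$, capping at $M_s V$. At the
2299.1 Oe operating point this gives $M/M_s \approx 0.62$, and moments of
$1.16\times 10^{-17}$, $2.51\times 10^{-15}$ and $9.31\times 10^{-14}$ emu
for 5, 30 and 100 nm particles — the values `scripts/acceptance.R`
recomputes. Moments scale exactly as $d^3$ at fixed field; treating
magnetization as size-independent is a deliberate simplification (no
size-dependent anisotropy or surface effects), and the relaxation response
is treated as instantaneous (no Néel/Brownian dynamics): magnetization
follows the 50 Hz drive quasi-statically.

## The drive coil

A solenoid of radius $R$, height $h$, wound from wire of cross-section
$A_w$ and resistivity $\rho$, powered at voltage $V$, draws
$I = V A_w / (\rho\, n\, 2\pi R)$ and produces $H = nI/h$ — the turn count
cancels exactly, so the achievable field is set by geometry and wire gauge
alone. The 220 V mains drive is interpreted as RMS. The default wire
cross-section, $4.389\times 10^{-7}\ \mathrm{m}^2$ (≈0.44 mm², between
AWG 20 and 21), is a calibration chosen so the default geometry produces
2299.1 Oe; it is a model choice, not a measured input, and
`calibrate_wire_area()` inverts the formula for any target field. Whether
the operating field is an amplitude or an RMS figure is not determined by
the inputs; the package treats it as the amplitude seen by the particles'
magnetization.

## Dipole flux through the pickup coil

For a moment $m$ at the center of a coil of radius $R$, integrating the
dipole field over the plane outside the loop gives the closed form
$\Phi_0 = \mu_0 m / 2R$. Off-center along the axis,
$\Phi(z) = \mu_0 m R^2 / 2(R^2+z^2)^{3/2}$, which reduces to $\Phi_0$ at
$z=0$ and decays as $1/z^3$. An independent Biot–Savart quadrature oracle
(`flux_numeric_oracle()`: Gauss–Legendre radially × trapezoid in angle over
the coil disk; for an in-plane dipole, over the loop exterior with the
$s = R/u$ substitution, since the disk integrand is then singular while the
net flux through the full plane is zero) verifies both closed forms to 0.1%
across a grid of moments, radii and offsets, and shares no code with them.

**Effective axial offset.** The reference particle model measures particle
distance as $\sqrt{x^2 + (R+y)^2 + z^2}$ — the distance to a point on the
winding rather than to the coil center. Both readings are provided
(`distance_to_center()`, default `"paper_literal"` for reproduction). The
EMF synthesis, however, defaults to the euclidean axial offset, because the
centered-particle limit must recover $\Phi(0) = \Phi_0$ (the literal
reading gives distance $R$ at the center and caps the flux at
$\Phi_0/2^{3/2}$); the literal mode remains available via `dist_mode`.

## Blood rheology and transport

Blood is modeled as a Carreau fluid,
$\eta(\dot\gamma) = \eta_\infty + (\eta_0-\eta_\infty)
[1+(\lambda\dot\gamma)^2]^{(n-1)/2}$, with the standard whole-blood fit
($\eta_0 = 0.056$ Pa·s, $\eta_\infty = 0.0035$ Pa·s, $\lambda = 3.313$ s,
$n = 0.3568$). The steady profile solver uses the exact force balance in a
tube — shear stress $\tau(r) = Gr/2$ — inverting $\eta(\dot\gamma)\dot\gamma
= \tau$ per radius (vectorized bisection; the map is strictly monotone) and
integrating inward from the no-slip wall on a 4097-node grid; the pressure
gradient $G$ is bracketed between the two Newtonian limits and solved so the
area-averaged velocity matches the 7.1 cm/s inlet to $10^{-6}$ relative. In
the Newtonian limit this recovers the Poiseuille parabola (centerline =
2× mean) to better than 0.5%; with the blood parameters the profile is
blunted (centerline/mean ≈ 1.9, consistent with the power-law bracket
$(3n+1)/(n+1) \approx 1.66$ as an order check).

The vessel radius is not determined by the model inputs; the default is
2 mm (forearm-artery scale) and is configurable. Particle transport is
purely kinematic: each particle advects at a constant assigned speed
(0.7 m/s arterial, 0.07 m/s venous), because the induction math needs
position only; optionally particles can draw their speed from the solved
radial profile (`sample_profile_speed()`). No drag, lift, magnetophoretic
force, aggregation, or particle–wall interaction is modeled.

## Induced EMF: carrier and baseband

Each particle contributes a per-turn flux
$\Phi_i(t) = \Phi(z_i(t))\cos(\omega t)$ — the axial closed form at its
current offset, modulated by the drive carrier (the angular factor in the
flux-derivative expression is read as the drive angular frequency
$\omega = 2\pi f$; a static misalignment angle is exposed separately as a
$\cos\theta$ factor). The EMF is the analytic product-rule derivative

$$v(t) = -n \sum_i \left[\Phi'(z_i)\,\dot z_i \cos\omega t
        - \Phi(z_i)\,\omega \sin\omega t\right],$$

verified against a central finite difference of the flux to $10^{-3}$
relative. Superposition is exact by construction; the accumulation over
(particles × samples) is a compiled kernel (with a pure-R reference
implementation cross-checked in the tests), since venous scenarios reach
$10^9$ terms. Sampling must resolve the carrier ($dt \le 1/20f$; default
$1/200f$), and a stationary centered particle peaks at exactly
$n\Phi_0\omega$.

**Why noise comparisons use the baseband component.** The two terms above
play different roles. The carrier term $\Phi(z_i)\,\omega\sin\omega t$ is
proportional to the *total* in-view moment and is phase-coherent across
every particle in the body — arterial and venous alike. A steady venous
stream keeps a roughly constant total flux in view (about
$\mathrm{rate}\times 2R/v$ particle-equivalents), so its carrier-term RMS is
of the same order as an arterial burst peak, and the ratio of the full
traces is near unity regardless of emission schedule — the test suite
asserts this collapse explicitly. The information that distinguishes an
arterial burst from the venous background is carried entirely by the
motion term $\Phi'(z_i)\dot z_i$: it is what survives demodulation in any
lock-in/envelope detection stage, it scales with particle speed, and for a
steady counter-flow stream it averages to zero with only shot-noise
fluctuations. The signal-to-noise analysis (`counterflow_snr()`, default
`carrier = "baseband"`) therefore compares motion-induced EMF, where the
arterial bursts stand two orders of magnitude and more above the venous
background — the separation the concept relies on. Both components are
available for every synthesis function via `carrier`.

**Envelope and SNR definitions.** The envelope is $\sqrt2 \times$ the
moving RMS over one drive period, with full-width windows shifted inward at
the trace edges (shrinking windows bias the edge RMS upward); it is exact
for a pure sinusoid over whole periods. `snr()` is the maximum absolute
signal envelope over the noise-trace RMS.

## Scenarios: what the generator emulates

All stochastic inputs come from seeded `scenario_config` objects; the
generators never touch the global RNG (seeds are restored), and every trace
records its seed, so runs repeat bit-for-bit. Three presets ship as yaml
configs:

* `single_arterial` — one 30 nm particle at 0.7 m/s (signal validation);
* `arterial_pulses` — 1000 particles per pulse at 1 Hz, 0.7 m/s. The pulse
  is not instantaneous: emissions spread uniformly over a 50 ms window with
  a matching axial jitter, giving bursts of finite width. The window length
  is a model choice (the reference simulations show finite bursts but state
  no width);
* `venous_counterflow` — the venous rule of 10× the per-pulse count at a
  tenth the speed, flowing the opposite way, emitted continuously
  (`venous_from_arterial()` encodes the rule for arbitrary arterial
  configs).

**Steady-state lead-in.** A continuous stream switched on at $t=0$ presents
its head to the coil as a one-off flux ramp that a real venous return does
not have; worse, emitting particles at a point the coil can still sense
injects net flux at a constant rate, which shows up as a spurious DC
component of the motion EMF. The venous preset therefore emits from 0.35 m
upstream (where the coil response is $\sim 3\times10^{-3}$ of its peak) and
extends emission over a 10 s lead-in before the analysis window, encoded as
particles already advanced along their trajectories at $t=0$. This puts the
stream in steady state throughout the window while preserving the
configured emission rate. The lead-in defaults to zero in raw
`scenario_config` objects, so the generator's count contract (exactly
`n_particles` over `duration`) holds unless steady state is requested.

What the scenarios do *not* emulate: electronic and thermal noise
(Johnson, amplifier), magnetic shielding, filtering/DSP, pulsatile
(Womersley) flow, vessel branching, particle aggregation, and
bound-vs-unbound discrimination. Passing tests therefore demonstrate the
electromagnetic signal chain and its scaling laws under idealized
transport, not end-to-end detector performance on real blood.

## Dosimetry

Detection planning works from the per-particle signal quantum: a centered
particle's peak EMF $n\Phi_0\omega$ (an RMS metric is available). The
required count is $\lceil \mathrm{sensitivity} / \mathrm{EMF}_1 \rceil$,
which scales as $d^{-3}$ — 8000× between 5 nm and 100 nm diameters (the
instrument-facing API uses diameters throughout; descriptions of the same
sizes as 2.5–50 nm radii are equivalent). Counts convert to mineral mass
with the magnetite density 5180 kg/m³ (configurable; the mineral density is
a model default) and to concentration per regional arterial pulse volume:
stroke volume 5 L/min ÷ 70 bpm = 71.4 mL, times 2.3% (forearm, ≈1.6 mL) or
6.5% (leg, ≈4.6 mL). Because count scales as $d^{-3}$ and per-particle mass
as $d^{3}$, the mass required for detection is diameter-independent at
fixed sensitivity — a strong internal consistency check the tests enforce.

The default dosimetry coil is the 40-turn, 5 cm drive/search geometry; with
it the SQUID-class sensitivity ($10^{-12}$ V) needs on the order of
$10^{-4}$ µg/mL while a $10^{-6}$ V benchtop meter crosses the toxic
threshold. The safety boundaries (safe below 10 µg/mL, toxic above
100 µg/mL) are explicitly placeholder working values — formulation-specific
toxicity is outside the model — and classification is closed on the safe
side at the boundaries. Absolute required counts depend on the coil
configuration, which is a free choice; only the inter-size ratios and
scaling laws are configuration-independent.

## Numerical choices and problem sizes

* Jiles–Atherton: default 1000 waypoints per branch, marcher substep
  $\min(a,k)/40$; loop closure asserted within 1% of $M_s$ over repeated
  cycles; odd symmetry within 1% of $M_s$.
* Anhysteretic solve: bracketed root in $[-M_s, M_s]$ plus Newton polish to
  $10^{-10}$ relative; refuses multivalued mean-field regimes
  ($\alpha M_s / 3a \ge 1$) rather than picking a branch.
* Flux oracle: order-96 radial Gauss–Legendre × 192 angles, with an
  internal 1.5× resolution convergence check at $10^{-6}$.
* Flow solver: 4097-node radial grid, pressure-gradient root bracketed by
  the Newtonian limits, mean-velocity match to $10^{-6}$ relative.
* EMF sampling: $dt = 10^{-4}$ s for 50 Hz carrier work, $10^{-3}$ s for
  baseband analyses (the baseband envelope varies on the transit scale
  $R/v \sim 0.07$ s).
* Scenario sizes in the shipped analyses: 5 s windows, 1000
  particles/pulse, 10,000-particle venous streams (≈30,000 with lead-in) —
  sizes chosen to match the reference scenarios while keeping a full
  multi-seed analysis in the minutes range on one core.
* Degenerate inputs are defined, not errors, where physics says so: empty
  ensembles give zero traces, zero drive gives zero EMF, zero flow
  fractions give zero pulse volume; a zero-RMS noise trace makes `snr()`
  return `Inf` with a warning.

## Known limitations

The magnetization model is scalar and temperature-independent; vector
hysteresis, size-dependent anisotropy and relaxation dynamics are out of
scope. The flux model treats particles as point dipoles on (or effectively
on) the coil axis; off-axis accuracy is bounded by the quadrature oracle
comparisons, not guaranteed. Transport ignores forces on particles. The
dosimetry absolute scale inherits the coil-configuration freedom discussed
above, and the safety thresholds are placeholders. The 2299.1 Oe operating
field is reproduced under a documented wire-gauge calibration, not derived
from first principles.
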