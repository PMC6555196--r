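---
title: "Modelling ephaptic coupling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ephaptic coupling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ephapsis)
```

## The model

ephapsis simulates networks of compartmental spiking neurons together with
the extracellular potentials their transmembrane currents generate, and —
this is the point of the package — lets those potentials feed back into the
membrane dynamics. The electrical state of each compartment (*segment*) $i$
obeys the cable balance

$$C_m \frac{dV_m^i}{dt} + \sum_{\mathrm{ion}} g_\mathrm{ion}^i
(V_m^i - E_\mathrm{ion}) \;=\; \sum_{j \in \mathcal{N}(i)}
\frac{V_m^j - V_m^i}{R^{ij}} \;+\; \sum_{j \in \mathcal{N}(i)}
\frac{V_\mathrm{out}^j - V_\mathrm{out}^i}{R^{ij}} \;+\; I_\mathrm{inj}^i,$$

where the membrane potential is the difference between the intracellular
and extracellular potentials, $V_m = V_\mathrm{in} - V_\mathrm{out}$, and
$R^{ij}$ is the axial resistance between adjacent segments. The second
axial sum — the extra drive produced by *gradients of the extracellular
potential along the neurite* — is the **ephaptic current**
(`ephaptic_currents()`). When $V_\mathrm{out}$ is held at zero this reduces
to the ordinary cable equation (the *open-loop* condition); when
$V_\mathrm{out}$ is generated by the cells themselves the system is
*closed-loop* and must be solved self-consistently.

The extracellular space is an infinite homogeneous isotropic ohmic medium
with conductivity $\sigma$. Under the quasi-electrostatic approximation the
potential solves a Poisson equation whose exterior solutions for the two
compartment shapes are closed forms:

* a cylinder of length $L$ is a uniform line of current (the line-source
  approximation),
  $$V = \frac{I}{4\pi\sigma L}\,
  \ln\left|\frac{\sqrt{h^2+r^2}-h}{\sqrt{l^2+r^2}-l}\right|,$$
  with $r$ the perpendicular distance from the axis, $l$ the signed axial
  distance from the cylinder's beginning and $h = l - L$ from its end;
* a sphere is a point source, $V = I / (4\pi\sigma R)$, clamped to its
  surface value for $R$ below the sphere radius (the exterior solution is
  constant on the surface; the clamp keeps self-coefficients finite).

Because the Poisson equation is linear, superposition holds, and the map
from the $n$ per-segment membrane currents to the $n$ per-segment
extracellular potentials is a dense matrix $T$ (`build_transfer_matrix()`),
each entry a kernel *averaged over the boundary of the target segment*
(default: 5 axial x 8 azimuthal samples on a cylinder's lateral surface, a
ring of 8 points for a sphere; the default rule is within about 1% of a
dense surface average, and the sampling is configurable). $T$ scales
exactly as $1/\sigma$. No finite-element machinery is used or needed —
anisotropic or inhomogeneous media are out of scope.

## Closing the loop

Writing $A$ for the axial conductance matrix (symmetric, zero row sums per
cell) and $I_m$ for the vector of total transmembrane currents, the
algebraic constraint is $V_\mathrm{out} = T I_m$ with
$I_m = A(V_m + V_\mathrm{out}) + I_\mathrm{inj} - I_\mathrm{gap}$. Both
relations are linear in $V_\mathrm{out}$, so the constraint can be solved
exactly:

$$(\mathbb{1} - T A)\, V_\mathrm{out} = T\,(A V_m + I_\mathrm{inj} -
I_\mathrm{gap}) + V_\mathrm{ext}.$$

The default `eliminated_ode` formulation pre-factors
$(\mathbb{1} - TA)^{-1}$ at assembly time and solves the constraint inside
every derivative evaluation, turning the differential-algebraic system into
an equivalent stiff ODE. The alternative `mass_matrix_dae` formulation
keeps $V_\mathrm{out}$ as algebraic variables of a singular-mass-matrix DAE
(solved with RADAU); the two agree to integrator tolerance and this
equivalence is tested. If $(\mathbb{1} - TA)$ becomes numerically singular
(pathological $\sigma$/geometry combinations) assembly fails with a
conditioning error rather than producing garbage.

Bookkeeping conventions worth stating explicitly:

* Field sources are the total transmembrane currents (capacitive + ionic +
  membrane-crossing synaptic). An intracellular electrode's current does
  not cross the membrane and adds no monopole of its own — its return
  electrode is at infinity — but it shapes the field through the membrane
  currents it drives. Gap-junction current flows directly from cytoplasm to
  cytoplasm and is likewise not a field source.
* Stored closed-loop results recompute $V_\mathrm{out}$ and $I_m$ from the
  stored $V_m$ through the same linear solve, so the self-consistency
  residual $\|V_\mathrm{out} - T I_m\|_\infty$ is at machine precision at
  every stored time (tested against the `10 x abs_tol` contract).

## Numerics

The stiff integrator is `deSolve::lsodes` with a user-declared Jacobian
sparsity pattern. After elimination the Jacobian has a dense $n \times n$
membrane block (every segment's field couples to every other's) but purely
diagonal gating blocks, so sparse LU factorization costs roughly the dense
block alone — for the 7-axon bundle (147 segments, 588 states) this is a
~50x saving over a dense factorization and is what makes desk-scale
closed-loop sweeps practical. The right-hand side for the shipped
Hodgkin–Huxley/passive models under DC or sinusoidal drive is compiled
(`src/rhs_fast.cpp`), with the self-consistency operator folded into a
constant matrix; systems with synapses, custom stimuli or user models take
an equivalent R path.

Default tolerances are `rel_tol = 1e-6`, `abs_tol = 1e-8` mV with dense
output every 0.025 ms — tight, because spike-timing validation at the
tens-of-microseconds level is part of the package's acceptance surface.
Event-driven synapses (preset spike times, or presynaptic threshold
crossings located by the integrator's root finder) apply conductance
increments between integration intervals, keeping the right-hand side
continuous — only continuous membrane models are supported, which is why
hybrid resetting models (integrate-and-fire, Izhikevich) are rejected by
design.

The independent accuracy oracle (`reference_solve()`) is a fixed-step
backward-Euler integrator with modified-Newton iteration and an analytic
Jacobian, written in C++ and sharing no time-stepping code with the
adaptive path. At `dt = 1` µs on the same spatial grid it bounds the
open-loop error of either solver: membrane-potential RMS differences stay
well below 0.5 mV and matched spike peaks (parabolic interpolation around
maxima) agree to a few microseconds on the validation geometries. The
post-hoc field path has its own oracle: probe potentials recomputed by
dense numerical quadrature (10,000 point sources per cylinder), which
agrees with the closed-form kernels to a few nano-volts.

## The membrane models

`hh_model()` is the classic squid-axon formulation at 6.3 °C with
$\bar g_{Na} = 120$, $\bar g_K = 36$, $g_L = 0.3$ mS/cm²,
$E_{Na} = 50$, $E_K = -77$, $E_L = -54.3$ mV and the standard
$\alpha/\beta$ rate functions (written singularity-safe around the
removable poles). Its resting potential is within a millivolt of -65 mV.
`passive_model()` is leak-only. User models implement the documented
contract (time, potentials, gating state, parameters in; current density
in µA/cm² and gating derivatives out). Units follow the NEURON-style
convention throughout — µm, ms, mV, nA, µF/cm², mS/cm², Ω·cm, S/m — with
every conversion factor centralized in `eph_units`.

## What the fixtures emulate

`fixture_network()` builds the validation geometries: a straight axon
(1000 µm long, 2 µm diameter, 41 segments), a ball-and-stick cell, a
bipolar cell (two symmetric axons, whose distal recordings must be
identical by symmetry — a tested property), a branched cell, a two-axon
pair, and the hexagonal 7-axon bundle (pitch 5 µm). These are idealized
objects: straight untapered cylinders, isopotential spherical somata, a
uniform infinite medium. Passing validation on them demonstrates the
correctness of the solver and field machinery, *not* fidelity to any real
neuron: real morphologies (importable via SWC) add taper, tortuosity and
boundary effects that the homogeneous-medium kernels do not capture.

Desk-scale problem sizes are deliberate choices, stated here once: the
bundle uses 21 segments per axon (segment length ≈ 48 µm, about one eighth
of the passive length constant λ ≈ 408 µm — coarser than the single-axon
fixtures but sufficient for propagation and locking phenomena, and it keeps
the closed-loop system at 147 segments); bundle output is stored every
0.1 ms (spike binning at 1 ms needs far less). The single-axon validation
fixtures keep 41 segments and 0.025 ms output.

## The bundle experiment

The phase-locking experiment drives each of the seven axons with a DC
amplitude tuned (`tune_bundle_drive()`, a deterministic scan-plus-secant
search on the isolated axon's f–I relation) so that the *isolated* mean
oscillation period is 12.5 ms with a ±8% even spread across axons
(≈ 11.5–13.5 ms; the drive order across bundle positions is fixed). Each
axon starts from a random point on its own limit cycle: it is settled in
isolation for 500 ms, and its full state is sampled at a uniformly random
phase of its final inter-peak period (seeded per run). The bundle is then
integrated closed-loop for 2 s; the last second is analyzed.

Analysis follows the standard spike-train cross-correlation methodology:
spikes are interpolated upward 0 mV crossings with a 2 ms refractory
period, detected at each axon's middle segment, binned into 1 ms windows;
each of the 21 unordered pairs is cross-correlated (Pearson correlation
over overlapping bins — the estimator is not fixed by convention, and the
Pearson form is adopted because it is bounded in [-1, 1] and comparable
across pairs and conductivities) over ±1 mean oscillator period. Because
pairs are unordered, each pair's correlation enters the mean in both lag
orientations, which makes the reported mean function symmetric in
expectation. Peak detection considers interior local maxima only: the
window-edge bins (lag = ±1 period, where the one-period synchronous peak
sits) have no outer neighbour and cannot be certified as local maxima.

At σ = 5·10⁻⁴ S/m the mean pairwise cross-correlation develops local
maxima at lag 0 (synchronous locking) and at ≈ 6 ms, half the oscillator
period (anti-synchronous locking); with the feedback disabled the mean
function is flat and per-pair peaks collapse by an order of magnitude.
Locking strength falls as σ grows, a trend checked (at reduced cost) on a
two-axon pair swept over σ ∈ {5·10⁻⁴, 0.05, 10} S/m.

## Known limitations

* Homogeneous, isotropic, unbounded extracellular medium only; no
  method-of-images boundaries, layered or frequency-dependent media.
* Continuous membrane models only; no temperature scaling or stochastic
  channels.
* The transfer matrix is dense and the closed loop is intrinsically
  O(n²) per evaluation; networks are desk scale (hundreds of segments),
  not thousands.
* Cylinders are untapered; multi-point SWC somata are collapsed to one
  equivalent-area sphere; sphere-cylinder axial coupling uses the
  cylinder's half-segment resistance with the sphere treated as
  isopotential.
* Results are persisted as full-precision CSV plus JSON metadata (a
  documented, lossless, text-only schema).
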