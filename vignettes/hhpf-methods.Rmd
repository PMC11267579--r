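---
title: "Methods: differentiable hybrid particle-field dynamics and chi-matrix learning"
author: "hhpf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differentiable hybrid particle-field dynamics and chi-matrix learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`hhpf` simulates coarse-grained particles whose intermolecular
interactions act through density fields rather than pair potentials.
The Hamiltonian splits into a standard intramolecular part (harmonic
bonds, cosine-harmonic angles) and an interaction functional of the
Gaussian-filtered per-species number densities
$\tilde\phi_t(\mathbf r)$:

$$
W[\tilde\phi] \;=\; \frac{1}{2\rho_0}\int d\mathbf r
\Big[\sum_{l\neq m}\tilde\chi_{lm}\,\tilde\phi_l\tilde\phi_m
\;+\;\frac{1}{\kappa}\Big(\sum_l\tilde\phi_l-a\Big)^2\Big].
$$

The symmetric matrix $\tilde\chi_{lm}$ (kJ/mol) carries all specific
chemistry: it is a Flory–Huggins-style mixing energy between the
densities of species $l$ and $m$, and it is the quantity the optimizer
learns.  $\rho_0$ sets the density of one coarse-grained bead,
$\kappa$ the strength of the incompressibility penalty, and $a$ is a
free calibration density chosen so the simulated system has the right
average density at the state point of interest.  Units are nm, ps,
kJ/mol, u, e, K and bar throughout.

Densities are built by standard particle-mesh machinery: a B-spline
assignment window $P$ deposits each particle onto a regular grid, and a
Gaussian filter $\hat H(k)=e^{-k^2\sigma^2/2}$ applied in Fourier space
gives each bead a physical spread $\sigma$ (0.5 nm by default).  The
per-species *external potential* is the functional derivative of $W$,
filtered back with the same $H$:

$$
V_l = H \star \frac{1}{\rho_0}\Big[\sum_{m\neq l}\tilde\chi_{lm}\tilde\phi_m
+ \frac{1}{\kappa}\Big(\sum_m\tilde\phi_m - a\Big)\Big].
$$

With this double filtering, $V_{\mathrm{cell}}\cdot V_l(c)$ is *exactly*
$\partial W/\partial\phi_l(c)$ for the unfiltered deposited density, a
fact the test suite checks by finite differences and which underpins the
force evaluation below.

## Forces: the exact gradient of the discretised functional

The field force on particle $i$ is computed as the exact position
gradient of the discretised $W$: the window weights are differentiated
analytically and contracted with $V$ on the mesh,
$\mathbf F_i = -\sum_c V_{t(i)}(c)\,\partial w_i(c)/\partial\mathbf r_i$.
Two consequences matter:

* **Finite-difference consistency.** The returned force agrees with a
  central finite difference of $W$ to full precision at any mesh
  resolution.  Every gradient the optimizer uses inherits this property.
* **The window order matters for energy conservation.** With the
  trilinear (cloud-in-cell) window the exact-gradient force is
  piecewise constant along each axis and jumps when a particle crosses
  a cell face; a velocity-Verlet integrator then accumulates a slow
  secular energy drift (we measure roughly 16 kJ/mol per ns on the toy
  bilayer at a 0.1 ps outer step).  The quadratic-spline window
  (`order = 3` in `field_config()`) is $C^1$, its exact-gradient forces
  are continuous, and the same run shows no measurable secular trend
  (drift below 0.2% of the potential-energy fluctuation amplitude over
  $10^4$ steps).  The fixture presets therefore use the quadratic
  window; cloud-in-cell remains the low-level default and is fine for
  thermostatted sampling.

An alternative discretisation interpolates the spectral (ik) gradient
of $V$ at the particles.  At the coarse meshes the toy systems use, the
two differ by tens of percent and the spectral-interpolated force is
not the gradient of any discrete Hamiltonian, so it conserves energy
*worse*; at production-like resolutions ($h \lesssim \sigma/2$) the
filter makes the fields effectively band-limited and the two converge.
`hhpf` uses the exact gradient everywhere.

One caveat is inherited from the energy-conserving formulation itself:
the net field force on the system is not exactly zero.  A rigid
translation changes the deposited density through the window's spectral
aliases, so momentum conservation holds only up to the window's
spectral tail (a few percent of the typical force at a $6^3$ mesh,
decaying roughly like $h^3$ for the quadratic window).  This is the
well-known momentum/energy trade-off of particle-mesh schemes; the
thermostatted and barostatted protocols are insensitive to it, and the
test suite asserts the decay with resolution rather than a fictitious
exact zero.

Smeared-charge electrostatics follows the same pattern: the deposited
charge density is filtered with $H$, Poisson's equation is solved
spectrally with the $k=0$ mode removed (a uniform neutralising
background), the potential is filtered back with $H$, and the force is
the exact gradient of the resulting quadratic form.  Two unit charges
then interact through $\mathrm{erf}(r/2\sigma)/r$, scaled by
$1/(4\pi\varepsilon_0\varepsilon_r)$; the relative permittivity
$\varepsilon_r$ (default 15, a common implicit-screening choice for
coarse-grained electrostatics) is a configuration parameter, never
hard-coded.  The reported energy includes each smeared charge's
self-energy, which is constant and force-free; oracle comparisons
therefore use energy differences of neutral configurations.

## Integration, thermostat, barostat

Time evolution uses the rRESPA splitting: bonded forces advance with
the inner velocity-Verlet step (0.02 ps by default) nested inside
half-kicks of the field and electrostatic forces at the outer step
(0.1 ps, so $n = 5$).  Temperature is controlled by canonical-sampling
stochastic velocity rescaling: one global factor per outer step whose
stationary distribution is the canonical kinetic-energy law with
$N_{df}=3N-3$ (net momentum is zeroed at initialisation and preserved
by the rescaling).  Pressure is controlled by a semi-isotropic
Berendsen barostat: the lateral ($x$, $y$ common) and normal ($z$) box
lengths scale by $\mu=[1-(\Delta t/\tau_P)\beta(P_0-P)]^{1/3}$ with the
matching components of the instantaneous pressure tensor, and particle
coordinates scale affinely.  The compressibility $\beta$ defaults to
$4.5\times10^{-5}\ \mathrm{bar}^{-1}$.  Both couplings default to
0.1 ps.  The barostat acts every outer step, after the thermostat.

The instantaneous pressure tensor combines the kinetic term, the
Clausius virial of bonds and angles, and the field term obtained as the
*analytic* derivative of the discretised $W$ with respect to
anisotropic box scaling at fixed fractional coordinates:
$\partial W/\partial\epsilon_\alpha = W + V_{\mathrm{cell}}\sum_{c,l}
\psi_l(-\tilde\phi_l + G_{l\alpha})$, with
$G_{l\alpha}=\mathcal F^{-1}[\sigma^2k_\alpha^2\hat H\hat\phi_l]$.
This expression is exact for the discretisation (the tests verify it
against $\pm10^{-4}$ box-strain finite differences to better than
$10^{-4}$ relative) and it decomposes cell by cell, which is what the
lateral pressure profile uses.

All stochasticity is drawn from counter-based streams keyed on
`(seed, phase, step)`, so trajectories are bitwise reproducible,
replicas with different seeds are independent, and the traced segment's
noise stream does not depend on how long the equilibration ran.

## Differentiability: tangent-mode sensitivities

The optimizer needs $\partial L/\partial\tilde\chi_{lm}$ where $L$ is a
loss over a short MD trajectory.  `hhpf` computes it by *tangent-mode*
(forward) algorithmic differentiation: alongside the state
$(\mathbf R,\mathbf V,\mathbf L_{\mathrm{box}})$ it propagates, for each
free $\chi$ entry, the exact directional derivative of that state.
Every operation in the traced segment has a hand-derived
Jacobian-vector product: deposition and gathering (including the box
dependence of the fractional coordinates), the Fourier filter (including
the box dependence of the wavevectors), the functional and its virial,
bonds and angles, the kicks and drifts, the thermostat factor (noise
held fixed, so the gradient flows through the kinetic-energy dependence
of the rescaling), and the barostat (through the pressure tensor's full
tangent).  The unit tests verify each piece, and the end-to-end
propagated tangent of positions, velocities and box, against central
finite differences to $10^{-9}$ relative or better.

The published description of this optimization strategy uses
reverse-mode differentiation, which is natural inside a general
autodiff framework.  Here the parameter space is tiny — $S(S-1)/2$
off-diagonal mixing energies, two to six in the toy systems — while the
state is large, so forward sensitivities cost one extra state-sized
tangent per parameter, require no taping, and use constant memory in
trajectory length (the memory blow-up of reverse-mode backpropagation
through MD, and its mitigation, motivate the replica protocol below).
The two modes compute the same derivative; the acceptance tests pin the
value against central finite differences at $\delta\chi=0.01$ kJ/mol
with relative error below $10^{-3}$.

Equilibration is deliberately outside the differentiated region: each
replica runs `n_equil` untraced steps, and tangents start at zero from
the handed-over state.  A finite-difference check of the gradient must
therefore hold the equilibrated state fixed; differentiating "through"
the equilibration would target a different (and, over many chaotic
steps, meaningless) derivative.

## Observables and the loss

The lateral density profile replaces the $z$-histogram with a Gaussian
kernel estimate: each particle contributes a normal kernel of bandwidth
$h$ (default: the bin width), wrapped periodically along $z$, evaluated
at fixed bin centers,
$\rho_T(z_b) = (L_xL_y)^{-1}\sum_{i\in T}\sum_n
\mathcal N(z_b;\,z_i+nL_z,\,h)$.
This is smooth in the coordinates (hence differentiable), integrates to
the particle count to well under 0.5%, and converges to the histogram
as $h\to0$.  Profiles are centered on the lipid midplane (mass-weighted
mean $z$ of lipid beads) before comparison with a reference, so the
loss is insensitive to slow drift of the membrane along the normal;
the centering shift is part of the differentiated path.  When the box
fluctuates under the barostat, profiles are evaluated at the
*reference* bin centers so bins always match.

The area per lipid is $A_L = L_xL_y/(N_{\mathrm{lip}}/2)$, assuming
equal leaflets.  Its dependence on $\tilde\chi$ enters entirely through
the barostat, which is why the barostat sits inside the differentiated
segment whenever the area term is active.

The per-replica loss is

$$
L \;=\; \sum_t \frac{w_t}{n_b}\sum_b
\big(\rho_t(z_b)-\rho_t^{\mathrm{ref}}(z_b)\big)^2
\;+\; w_A\,(A_L - A_L^{\mathrm{ref}})^2
\;+\; \sum_{l\le m}\max(|\tilde\chi_{lm}|-\Delta\chi,\,0)^3,
$$

with defaults $w_t = 1\ \mathrm{nm}^6$, $w_A = 100\ \mathrm{nm}^{-4}$,
$\Delta\chi = 300$ kJ/mol.  The density term divides by the bin count
(so its scale does not depend on the binning); this choice is isolated
in `replica_loss()` and trivially changed.  The cubic confinement is
$C^2$, identically zero inside the admissible box, and its gradient
with respect to the single shared parameter $\chi_{lm}=\chi_{ml}$ is
$3(|\chi|-\Delta\chi)^2\operatorname{sign}\chi$, counted once; the
returned gradient matrix mirrors that value into both symmetric slots.

The lateral pressure profile $\Delta P(z) = P_N(z)-P_L(z)$ is a
validation observable.  Kinetic contributions bin by particle
position; bond and angle virials spread uniformly over the slabs the
minimum-image segment between the interacting particles traverses
(Harasima convention, applied to the two apex-to-end legs for angles);
and the field term uses the per-cell decomposition of
$-\partial W/\partial\epsilon_\alpha$ above.  Slab sums reproduce the
global tensor difference exactly by construction — the tests assert
agreement at $10^{-6}$ — but the *per-slab* field values are one
admissible gauge of an inherently non-unique local stress: only the
total integral is gauge-independent, a caveat shared by every local
pressure decomposition.

## The replica protocol and the optimizer

A single short differentiable trajectory yields a noisy gradient.  The
training driver instead spawns `n_replicas` independent replicas per
system and epoch, each restarted from the *same* initial structure with
a distinct counter-derived seed (restarting from the previous epoch's
end state is known to be less robust), each contributing a loss and a
gradient; the bundle is averaged.  Replicas are embarrassingly
parallel — they communicate nothing but their (loss, gradient) pair —
and the variance of the averaged gradient falls as $1/N_R$ (asserted
empirically by bootstrap in the acceptance tests).  With several
systems sharing one $\tilde\chi$, per-system replica means are averaged
again and a single parameter update follows, which is what makes the
learned matrix transferable rather than overfitted to one system.

Updates use the adaptive "belief"-style rule: first moment
$m\leftarrow b_1m+(1-b_1)g$, second moment of the *residual*
$s\leftarrow b_2s+(1-b_2)(g-m)^2$, both bias-corrected, and
$\chi\leftarrow\chi-\eta\,\hat m/(\sqrt{\hat s}+\varepsilon)$ with
$\varepsilon=10^{-12}$ in the denominator only.  Defaults are
$\eta=0.01$, $b_1=0.1$, $b_2=0.4$ over 600 epochs.  Replica failures
(non-finite states) are tolerated up to 10% per evaluation, then the
epoch aborts; a non-finite averaged gradient always aborts.

## Synthetic systems and what passing means

The fixture module builds everything the tests need at run time.  The
toy lipid is a 4-bead H–T–T–T chain (bonds $r_0=0.47$ nm,
$k=1250$ kJ mol$^{-1}$ nm$^{-2}$; two straight cosine-harmonic angles
at 25 kJ/mol; all masses 72 u, a common coarse-grained convention since
bead masses are rarely specified) arranged as two opposing leaflets
with water beads outside the tail core, plus a charged variant with
anionic heads and counterions.  It deliberately reproduces no published
mapping: it exists to exercise the machinery with bilayer-like
structure.  Two sizing choices keep the physics sane at toy scale:

* the bead density matches the calibration density $a$ (the default
  production value $a = 9.21\ \mathrm{nm}^{-3}$ implies ~1800 beads in
  a 5×5×8 box, far more than a quick test wants, so the presets use
  4×4×5 and 3×3×4.5 boxes at $a = 7\ \mathrm{nm}^{-3}$); with the
  density far below $a$ the incompressibility term would collapse the
  system into a droplet, and under pressure coupling the cohesive
  pressure $\sim a^2/(4\rho_0\kappa)$ must exceed the kinetic pressure
  $\rho k_BT$ or the box expands without bound;
* the starting mixing parameters ($\chi_{HT}=10$, $\chi_{HW}=-5$,
  $\chi_{TW}=30$ kJ/mol) give a stable, layered bilayer with repulsive
  tail–water contacts.

Reference data are generated *self-consistently*: a forward simulation
at a known $\chi^\*$ produces time-averaged profiles and areas, which
are fed back as the optimization target.  Recovery of $\chi^\*$ from a
perturbed start is then a closed-loop correctness test of the whole
chain — dynamics, observables, gradients, averaging, optimizer.  The
acceptance experiment perturbs two off-diagonal entries by
±20 kJ/mol and runs 8 replicas × 50 traced steps for 100 epochs under
the constant-pressure protocol.  For this short budget the learning
rate is raised to $\eta=0.1$: the belief-style update is scale-free
(steps of order $\eta$ times the gradient's signal-to-noise), so
covering a 20 kJ/mol distance in 100 epochs needs a step scale of a few
tenths, while the end-game jitter $\sim\eta$ stays well inside the
2 kJ/mol recovery tolerance.

Passing these tests demonstrates that the machinery is internally
correct and that the estimator chain is differentiated exactly.  It
does *not* demonstrate chemical realism: the toy systems are far
smaller (hundreds of beads, picosecond sampling) than production
membrane parametrisations (tens of thousands of beads, hundreds of
nanoseconds of aggregate replica sampling), the toy lipid is not a real
mapping, and self-consistent references remove all model error by
construction.  Real parametrisation work supplies its own topologies,
reference profiles from mapped atomistic trajectories, and experimental
areas per lipid through the documented file interfaces.

## Numerical choices, degenerate inputs, limitations

* Double precision everywhere; the force/gradient acceptance
  tolerances are unreachable in single precision.
* Minimum-image bonded terms: molecules are never unwrapped, so bonded
  interactions must span less than half the box; angles with a zero
  bond vector raise an error, as does the harmonic-in-theta form at
  collinearity (the cosine-harmonic default is regular there).  Only
  the cosine-harmonic form participates in differentiated segments.
* The Berendsen step is guarded: a scaling factor outside
  [0.9, 1.1] in one step aborts rather than silently deforming the box.
* `wrap_positions()` guarantees $[0, L)$ even for coordinates that land
  exactly on $L$ after rounding; wrapping is idempotent.
* Deposition accepts unwrapped coordinates (indices are taken modulo
  the grid), so the integrator never needs to wrap inside the traced
  loop, keeping the dynamics map smooth.
* The thermostat requires a strictly positive kinetic energy; zero
  temperature input is an error, not a silent pass.
* Known limitations: orthorhombic boxes only; no dihedrals,
  constraints or virtual sites; no Lennard-Jones/Ewald pair paths; net
  field momentum is only approximately conserved (see above); the
  local pressure decomposition is gauge-dependent per slab; replica
  parallelism is expressed as an independent-task contract
  (`lapply`-style) rather than a bundled multi-node backend.

## Problem sizes used by the shipped tests

Unit tests run on systems of 2–600 beads with $4^3$–$24^3$ meshes
(one electrostatics oracle uses $128^3$ for sub-percent window
smearing).  The acceptance suite uses the 560-bead toy bilayer at a
$6^3$ mesh for gradient and conservation checks ($10^4$ outer steps),
a 32-particle ideal gas over $10^5$ steps for thermostat statistics,
and the 284-bead mini bilayer for the 100-epoch recovery and the
48-replica variance scaling.  These sizes were chosen so the whole
suite exercises every code path at full numerical strictness while
remaining comfortable on a single CPU core.
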