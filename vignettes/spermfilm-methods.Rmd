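---
title: "Methods: elastohydrodynamic swimmers in periodic thin films"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: elastohydrodynamic swimmers in periodic thin films}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`spermfilm` simulates suspensions of model sperm cells in a
quasi-two-dimensional liquid film. Each swimmer consists of

* a **flagellum**: an inextensible, flexible beam of length $l$ and bending
  modulus $K_B$, discretized as $N_{\mathrm{flag}}$ spherical segments of
  hydrodynamic radius $b$ at spacing $\Delta s = l/N_{\mathrm{flag}}$, and
* a **cell head**: an oblate spheroid with in-plane semi-axis $a$ and
  height $b = a/3$, attached to the flagellum by a short linkage of length
  $0.1a$, so the overall swimmer length is $d = 2.1a + l$.

The flagellum is driven internally by moments that pull its curvature
toward the travelling wave
$$\kappa_0(s,t) \;=\; K_0\,A(s)\,\sin(k s + \Phi(t) + \phi),
\qquad k = 2\pi/l,$$
where $\Phi$ integrates the (possibly time-varying) undulation frequency,
$\mathrm{d}\Phi/\mathrm{d}t = -\omega$, and $\phi$ is a per-swimmer phase.
The amplitude envelope $A(s)$ equals one along the proximal flagellum and
decays linearly to zero over the final fraction $\gamma_{\mathrm{tip}}$ of
the length, mimicking the reduced beat amplitude seen near real flagellar
tips. The undulation frequency is set through the sperm number
$$\mathrm{Sp} = \left(\frac{4\pi\omega\eta}{K_B}\right)^{1/4} l,$$
the standard measure of viscous versus elastic forces for a driven
filament.

## Discrete balances

Per body the planar configuration is $(x, y, \theta)$. At each interior
joint $j$ the driven elastic moment is
$$m_j = \frac{K_B}{\Delta s}\sin(\Delta\theta_j) - K_B\,
\kappa_0(s_j, t),$$
applied as an equal-and-opposite pair to the adjacent segments. This pair
is exactly the negative gradient of the discrete driven energy
$$E = \frac{K_B}{\Delta s}\sum_j\bigl(1 - \cos\Delta\theta_j\bigr)
 - K_B \sum_j \kappa_0(s_j,t)\,\Delta\theta_j,$$
so a configuration whose discrete curvature $\sin(\Delta\theta)/\Delta s$
matches $\kappa_0$ everywhere is a joint equilibrium (the tests assert the
gradient identity by finite differences). Inextensibility is enforced by
the joint constraints
$$\mathbf{Y}_{n+1} - \mathbf{Y}_n =
\tfrac{\Delta s}{2}\left(\hat{\mathbf{t}}_n +
\hat{\mathbf{t}}_{n+1}\right),$$
with Lagrange multipliers whose forces and torques are the exact
virtual-work conjugates of the residuals; the head is attached by an
attachment-point constraint at distance $1.1a + \Delta s/2$ along the head
axis plus a clamped-tangent constraint. Multi-swimmer runs add a
short-ranged quartic steric barrier between non-bonded bodies,
$$F(r) = F_S\left(\frac{R_{\mathrm{ref}}^2 - r^2}
{R_{\mathrm{ref}}^2 - (a_i + a_j)^2}\right)^4,\qquad
R_{\mathrm{ref}} = \chi (a_i + a_j),\; \chi = 1.1,$$
which equals $F_S$ exactly at contact. Force and torque balances on every
body then define a rigid-particle mobility problem: bending, driving,
constraint and steric loads determine the forces the bodies exert on the
fluid, and the Stokes solution returns their velocities.

## Hydrodynamics: force-coupling method

The mobility problem is solved with the force-coupling method (FCM).
Forces are spread onto a periodic grid with Gaussian envelopes
$\Delta(r) = (2\pi\sigma^2)^{-3/2} e^{-r^2/2\sigma^2}$ with
$\sigma = a_{\mathrm{hydro}}/\sqrt{\pi}$, torques as antisymmetric
(rotlet) dipoles of a second Gaussian with
$\sigma_d = a_{\mathrm{hydro}}/(6\sqrt{\pi})^{1/3}$; these widths
reproduce the isolated Stokes drag $6\pi\eta a$ and rotational drag
$8\pi\eta a^3$ analytically (verified against the periodic-lattice
corrected Stokes law in the tests). The periodic Stokes equations are
solved spectrally,
$$\hat{\mathbf{u}}(\mathbf{k}) = \frac{1}{\eta k^2}
\left(\mathsf{I} - \hat{\mathbf{k}}\hat{\mathbf{k}}^\top\right)
\hat{\mathbf{f}}(\mathbf{k}),$$
and body velocities and spin rates are envelope averages of
$\mathbf{u}$ and $\tfrac12\nabla\times\mathbf{u}$.

The **head** is represented by a single FCM particle whose envelope radii
are effective-sphere radii computed from the classical ellipsoid
resistance integrals: the translational radius reproduces the edgewise
(in-plane) drag of the oblate spheroid and the rotational radius its spin
drag about the symmetry axis ($a_{\mathrm{eff}} \approx 2.16\,b$ and
$2.54\,b$ for the reference head). The steric shape remains a disc of
radius $a$. Only the antisymmetric dipole is included; the symmetric
(stresslet) FCM correction is not.

**Thin film.** The domain is $L \times L_y \times L_z$ with
$L_z = 0.277\,d$, periodic in all directions. Swimmer motion is
restricted to the midplane $z = L_z/2$; by symmetry the planes $z = 0$
and $z = L_z$ behave as free surfaces, the standard construction for a
soap-film-like quasi-2D experiment. The restriction is built into the
state space: bodies carry no out-of-plane degrees of freedom, so the
projection reaction is never added to the fluid.

**Planar collapse.** Because every body lies on the same grid plane, the
triply periodic solve factorizes exactly: spreading and interpolation
Gaussians separate as $g(x,y)\,h(z)$, and the $k_z$ sums
$$K^{cr}_{ab}(k_x,k_y) = \frac{1}{N_z}\sum_{k_z}
\frac{\delta_{ab} - k_a k_b/k^2}{\eta k^2}\,
\hat h_c(k_z)\,\hat h_r(k_z)$$
can be precomputed once per envelope-class pair $(c, r)$. A mobility
solve then costs six 2D FFTs regardless of $N_z$. This is an algebraic
reorganization, not an approximation: the test suite asserts equality
with the plain 3D route to machine precision. The 3D route (pure R)
remains exported for general geometry and serves as the oracle.

## Time integration

Configurations and multipliers are advanced together by an implicit
second-order backward differentiation scheme (backward Euler on the first
step); the stacked nonlinear system (kinematic mismatch plus constraint
residuals) is solved each step with a matrix-free "bad" Broyden
iteration on the inverse Jacobian. The iteration is seeded with a
finite-difference Jacobian — of the full FCM residual for one- and
two-swimmer systems, of the cheap per-swimmer local-drag closure for
suspensions — refreshed every few hundred steps, and rank-one updates are
carried across steps in a sliding window. Convergence requires the
residual norm below $10^{-8}\sqrt{n_{\mathrm{dof}}}$ *and* every joint
residual below $10^{-8}\Delta s$; a non-converged step aborts the run
rather than being accepted silently.

With the reference parameters the implicit scheme is accurate well below
the physics scales at 150 steps per undulation period: halving the step
from $T/150$ to $T/300$ changes the swimming speed by less than one part
in $10^4$, while the formal default in the configuration remains
$T/300$. Desk-scale runs in this package therefore use $T/150$ unless
stated otherwise.

## Resistive force theory backend

To isolate the role of hydrodynamic interactions the mobility solve can
be replaced by local anisotropic drag (RFT): segment velocities follow
from $\xi_\parallel$, $\xi_\perp$ per unit length with no coupling
between bodies. Slender-body values seed the coefficients and
`calibrate_rft()` fits two scale factors so that a solitary RFT swimmer
reproduces the mean speed and beat amplitude of a reference FCM run; the
self-consistency of the fit (recovery of known scales from an RFT
reference) is part of the test suite.

# Analysis statistics

* **Force moments.** From the hydrodynamic loads on the bodies (with this
  sign a pusher has $G_{11} < 0$), the
  in-plane dipole $G$ (symmetrized first moment of
  $\sum F_i r_j$ about the centre of mass) and quadrupoles $K^S$, $K^A$
  (from $\sum F_i r_j r_k$), in the frame whose x-axis is the mean
  swimming direction, normalized by $F_0 d$ and $F_0 d^2$ with $F_0$ the
  in-plane head drag at the mean speed. The instantaneous moments
  oscillate at the beat frequency with amplitudes far above their period
  means, so period averages are extracted by regression on a constant
  plus drive-period harmonics (`period_mean`), which is insensitive to
  window incommensuration. The in-plane trace (pressure
  moment) of a beating swimmer does not vanish, and the two diagonal
  dipole entries carry independent information; components are therefore
  reported without trace subtraction (an option restores strictly
  trace-free tensors); $F_0$ is computed with the same mobility backend
  as the simulation. The antisymmetric dipole (including body-torque
  monopoles) is proportional to the net torque on the fluid and vanishes
  identically for the torque-free swimmer. The quadrupole--dipole
  crossover is estimated from the far-field scaling as
  $r^* = \max_t\lVert K\rVert / \max_t\lVert G\rVert$ using the dominant
  components.
* **Order parameters.** $S_1 = \langle \hat{\mathbf p}_n \cdot
  \hat{\mathbf e}_0\rangle_n$ and the planar nematic order
  $S_2 = \langle 2(\hat{\mathbf p}_n \cdot \hat{\mathbf e}_0)^2 -
  1\rangle_n$. The mean orientation $\hat{\mathbf p}_n$ is the tip-to-head
  end-to-end unit vector, low-pass averaged over one period — robust to
  the beat, and within a few degrees of the alternative definition via the
  period-averaged velocity direction.
* **Spectra.** The fluid energy spectrum is computed from the in-plane
  midplane velocity: 2D transform normalized by the grid size, modal
  energy $\tfrac12\lvert\hat u\rvert^2$, averaged over shells of width
  $2\pi/L$ and over snapshots, so that $\sum_k S(k)\,n_k$ equals the grid
  mean of $\lvert u\rvert^2/2$ (the exact normalization prefactor is a
  convention; slopes and per-swimmer collapse do not depend on it).
  An 8-period running mean (`lowpass_filter`) removes beat-frequency
  content before transforming when the suspension-scale flow is of
  interest. Swimmer-velocity spectra deposit centre-of-mass velocities
  with a Gaussian kernel of width $d/4$ (weight-normalized); their
  sub-flagellum plateau is construction noise and is expected.
* **Clusters.** Swimmers are linked when the minimum body-body distance
  is below $3b$ and mean orientations agree within $30^\circ$; cluster
  sizes are the connected components (checked against an independent
  graph-library implementation). This is a deliberately simple aggregation
  metric defined by this package.

## The uncorrelated-forcing oracle

At in-plane scales below the film thickness crossover $2\pi/L_z$, a thin
film driven by spatially uncorrelated point forces develops an energy
spectrum decaying like $k^{-3}$: the midplane slice sums $1/(\eta k^2)^2$
over incoherent $k_z$ contributions, and
$\sum_{k_z}(k_\parallel^2+k_z^2)^{-2} \sim k_\parallel^{-3}$.
`uncorrelated_forcing_spectrum()` reproduces this numerically (random
regularized forces throughout the film volume, 3D solve, midplane slice),
which pins the sub-flagellum tail seen in suspension spectra on the
random forcing the beating flagella exert on the fluid rather than on any
collective organization. The numerical forces carry a Gaussian
regularization of width $\sigma$, which multiplies the spectrum by the
known factor $e^{-\sigma^2 k^2}$ and steepens the apparent slope near
$k\sigma \sim 1$; the routine divides that factor out by default, and the
power-law fit is taken between the film crossover $2\pi/L_z$ and
$k = 1$.

# Calibration and problem sizes

Two quantities are calibrated once, then frozen:

* $\gamma_{\mathrm{tip}}$, the tip-ramp extent, is chosen so that the
  solitary swimmer advances one flagellum length in 23.7 undulation
  periods under the reference parameters in the $512^2 \times 64$ film;
  the packaged default records the calibrated value
  $\gamma_{\mathrm{tip}} = 0.084$ (periods-per-length is monotone in
  $\gamma_{\mathrm{tip}}$ over the scanned range 0.02--0.45, so the
  choice is unique).
* The RFT scale factors, fit to the FCM reference as described above.

Desk-scale problem sizes used by the tests and the acceptance script
(chosen as reproducible single-CPU configurations; all are stated where
used):

* solitary reference run (calibration and the reproduction script):
  $512^2 \times 64$ grid at $\mathrm{d}x = L_z/64 = 0.3031$ (box
  $2.21d \times 2.21d \times 0.277d$), 150 steps per period, 6 periods
  with a 2-period transient excluded. The moments of the steady solitary
  swimmer are time-periodic, so a 4-period average already matches longer
  windows to well below a percent. The test suite uses a cheaper
  $512 \times 256$ variant of the same film, whose lateral images speed
  the swimmer up by about 3 percent — within the tolerance the tests
  assert, and stated there.
* uncorrelated-forcing spectrum: $256^2 \times 64$, 1000 forces, 20
  draws.
* reduced suspensions: tens of swimmers for a few periods. These retain
  the qualitative contracts (in-phase pair attraction, clustering with
  monodisperse frequencies and its suppression at
  $\sigma_\omega = \omega/5$, backend-dependent order-parameter trends)
  but not the long-time statistics of production-scale suspensions.

# What the generator does and does not emulate

The synthetic configurations (solitary, phase-shifted pairs, polar and
isotropic films) reproduce the study conditions: monodisperse geometry,
uniform phases, lognormal frequency modulation with
$\sigma_\omega/\omega \in \{0, 0.2\}$ redrawn each mean period. They do
not emulate variability in flagellum length or head geometry,
three-dimensional beat components, load-dependent actuation, or walls;
passing tests therefore validate the numerical method and the in-plane
collective phenomenology, not organism-level realism.

# Numerical choices and degenerate inputs

* Gaussian envelopes are sampled on the grid and truncated at $7\sigma$
  (tail mass $<10^{-11}$); envelope supports must fit the grid, which
  bounds the minimum film resolution at $N_z = 64$ for the reference head.
* Spectral derivative factors are zeroed at the Nyquist mode (both
  routes), keeping all transforms Hermitian.
* The $k = 0$ Stokes mode is undefined in a periodic domain; swimmer
  systems are force-free so the mode carries only roundoff, which is
  removed and recorded.
* Steric overlap below $0.1(a_i + a_j)$ clamps the barrier magnitude to
  avoid unbounded forces from pathological inputs.
* Placement modes reject configurations they cannot make overlap-free
  (bounded retries for isotropic starts) instead of silently accepting
  contact forces at $t = 0$.

# Known limitations

* Only planar waveforms; twist elasticity and 3D beats are out of scope.
* The head's FCM representation is an effective sphere; near-field
  head-flagellum hydrodynamics are therefore approximate (the steric
  barrier dominates those encounters).
* The cluster metric is a package-defined substitute for more elaborate
  aggregation statistics.
* Desk-scale boxes leave percent-level periodic-image systematics in
  single-swimmer observables; quantities sensitive to them are reported
  with that caveat.
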