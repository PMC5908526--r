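# spermfilm

Simulation and analysis of sperm-cell suspensions in quasi-two-dimensional
liquid films, for researchers in active matter and biological fluid
dynamics who want flagellum-resolving suspension simulations at desk
scale.

Each swimmer is an inextensible elastic flagellum (bending modulus `K_B`,
length `l`, discretized as constrained spherical segments) driven by a
travelling preferred-curvature wave

    kappa_0(s, t) = K_0 A(s) sin(k s + Phi + phi),   k = 2 pi / l,

attached to an oblate cell head (`d = 2.1 a + l` overall). The undulation
frequency enters through the sperm number
`Sp = (4 pi omega eta / K_B)^(1/4) l`. Hydrodynamic interactions are
resolved with the force-coupling method (FCM): Gaussian force/torque
envelopes on a periodic grid, a spectral Stokes solve, and envelope
averaging back to body velocities — in a thin periodic film
(`L_z = 0.277 d`) whose midplane restriction mimics a free-surface film.
Because all bodies live on the midplane, the 3D solve collapses exactly to
2D transforms with precomputed kz-summed kernels, which is what makes
desk-scale suspension runs tractable; a plain 3D route is exported and the
two are verified equal to machine precision. Time stepping is implicit
(BDF2 with Broyden's method on configurations and constraint
multipliers). A resistive-force-theory backend with calibrated drag
coefficients removes hydrodynamic coupling for comparison. Analysis tools
cover force dipole/quadrupole moments, polar/nematic order parameters,
fluid and swimmer-velocity energy spectra with 8-period low-pass
filtering, pair displacement maps, and cluster statistics.

Reference parameters (simulation units, `eta = b = 1`): `Sp = 12`,
`K_0 l = 12.76`, `K_B = 1800`, `a/l = 0.047`, `N_flag = 29` segments,
steric contact force `F_S = 15 pi d`.

## Worked example: a solitary swimmer

```r
library(spermfilm)

params <- physical_params(steps_per_period = 150)
grid   <- grid_spec(512, 512, 64)          # 2.21 d x 2.21 d x 0.277 d film
cfg    <- suspension_config(N = 1, init_mode = "solitary",
                            grid = grid, params = params)
sys    <- initialize_suspension(cfg, grid, params, backend = "fcm")
traj   <- run_film(sys, n_periods = 6)

speed <- mean(mean_swimming_speed(traj, t_from = 2 * params$T_period))
params$l / (speed * params$T_period)
#> [1] 23.6993

F0  <- f0_normalization(traj, U_mean = speed)
mom <- force_moments(traj, t_from = 2 * params$T_period, F0 = F0)
period_mean(mom$G11, mom$t, params$T_period)
#> [1] -0.137328
max(abs(mom$G11)) / 0.137328   # peak-to-mean ratio of the dipole
#> [1] 25.16
```

The first number says the swimmer needs 23.7 undulation periods to advance
one flagellum length — the speed the tip-ramp fraction `gamma_tip` was
calibrated against (calibrated once at this configuration and frozen; see
the methods vignette). The period-averaged dipole coefficient (in units of
`F0 d`, with `F0` the in-plane head drag at the mean swimming speed) is
negative: the averaged far field is that of a pusher. Its magnitude is a
small residual of beat-scale oscillations twenty-five times larger, which
is why the instantaneous flow field looks nothing like the averaged
dipolar flow and why near- and mid-field interactions are not captured by
a steady-dipole picture.

Suspensions work the same way with `N > 1`, `init_mode = "polar"` or
`"isotropic"`, and `sigma_rel = 0.2` for stochastic lognormal frequency
modulation (redrawn every mean period), which suppresses flagellar
synchronization and with it the hydrodynamic aggregation seen at
`sigma_rel = 0`. Order parameters, spectra and cluster sizes are computed
from the returned trajectory by `order_parameters()`,
`energy_spectrum()` / `com_velocity_spectrum()` and `cluster_sizes()`.

A thin command-line wrapper is installed with the package
(`system.file("scripts", "spermfilm", package = "spermfilm")`) with
subcommands `run`, `analyze`, `calibrate-rft` and `fixture`; configurations
are YAML (`default_config()`, `fixture_config()`).

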