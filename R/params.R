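#' Physical parameters of the model swimmer
#'
#' Builds the full parameter set for an undulatory swimmer in simulation
#' units (viscosity \code{eta = 1}, segment radius \code{b = 1}). The
#' flagellum is an inextensible elastic beam of length \code{l} and bending
#' modulus \code{K_B}, driven by a travelling preferred-curvature wave of
#' amplitude \code{K0} and wavenumber \code{k = 2*pi/l}. The cell head is an
#' oblate spheroid with in-plane semi-axis \code{a} and height \code{b = a/3};
#' the overall swimmer length is \code{d = 2.1*a + l}, the extra \code{0.1*a}
#' accounting for the head--flagellum linkage. The undulation frequency is
#' set through the sperm number \code{Sp = (4*pi*omega*eta/K_B)^(1/4) * l},
#' the ratio of viscous to elastic forces.
#'
#' @param a head in-plane semi-axis (default 3, simulation units).
#' @param l flagellum length (default 63.8).
#' @param K0 preferred-curvature amplitude (1/length; default 0.2 so that
#'   \code{K0*l = 12.76}).
#' @param K_B bending modulus (default 1800).
#' @param Sp sperm number (default 12); the mean undulation frequency
#'   \code{omega_bar = Sp^4 K_B / (4 pi eta l^4)} is derived from it.
#' @param eta dynamic viscosity (default 1).
#' @param sigma_rel relative standard deviation \code{sigma_omega/omega_bar}
#'   of the stochastic frequency modulation (0 = monodisperse, 0.2 = the
#'   polydisperse case).
#' @param FS_over_d steric contact force divided by swimmer length
#'   (default \code{15*pi}).
#' @param N_flag number of flagellum segments (default 29).
#' @param steps_per_period time steps per mean undulation period
#'   (default 300); sets \code{dt = T/steps_per_period}.
#' @param gamma_tip fraction of the flagellum over which the preferred
#'   curvature amplitude decays linearly to zero at the free end. The
#'   default is the value calibrated once so that the solitary swimmer
#'   advances its flagellum length in 23.7 undulation periods.
#'
#' @return An object of class \code{physical_params}: a list with the inputs
#'   plus derived quantities \code{b = a/3}, \code{d}, \code{k_wave},
#'   \code{omega_bar}, \code{sigma_omega}, \code{T_period}, \code{dt},
#'   \code{F_S}, \code{ds = l/N_flag}, and the head effective hydrodynamic
#'   radii \code{a_eff_trans}, \code{a_eff_rot} (see
#'   \code{\link{oblate_effective_radii}}).
#' @export
physical_params <- function(a = 3, l = 63.8, K0 = 0.2, K_B = 1800, Sp = 12,
                            eta = 1, sigma_rel = 0, FS_over_d = 15 * pi,
                            N_flag = 29L, steps_per_period = 300L,
                            gamma_tip = spermfilm_gamma_tip()) {
  stopifnot(a > 0, l > 0, K_B > 0, eta > 0, K0 >= 0, sigma_rel >= 0,
            N_flag >= 2, gamma_tip >= 0, gamma_tip < 1)
  b <- a / 3
  d <- 2.1 * a + l
  omega_bar <- Sp^4 * K_B / (4 * pi * eta * l^4)
  T_period <- 2 * pi / omega_bar
  eff <- oblate_effective_radii(a, b)
  p <- list(
    eta = eta, K_B = K_B, K0 = K0, k_wave = 2 * pi / l,
    omega_bar = omega_bar, sigma_omega = sigma_rel * omega_bar, Sp = Sp,
    a = a, b = b, l = l, d = d,
    F_S = FS_over_d * d, T_period = T_period,
    dt = T_period / steps_per_period,
    steps_per_period = as.integer(steps_per_period),
    gamma_tip = gamma_tip, N_flag = as.integer(N_flag), ds = l / N_flag,
    a_eff_trans = eff$trans, a_eff_rot = eff$rot
  )
  class(p) <- "physical_params"
  validate_physical_params(p)
  p
}

validate_physical_params <- function(p) {
  stopifnot(abs(p$d - (2.1 * p$a + p$l)) < 1e-12 * p$d)
  sp_check <- (4 * pi * p$omega_bar * p$eta / p$K_B)^0.25 * p$l
  stopifnot(abs(sp_check - p$Sp) < 1e-12 * p$Sp)
  stopifnot(abs(p$b - p$a / 3) < 1e-12,
            abs(p$k_wave - 2 * pi / p$l) < 1e-15)
  invisible(p)
}

#' @export
print.physical_params <- function(x, ...) {
  cat("Swimmer parameters (simulation units):\n")
  cat(sprintf("  l = %.4g, d = %.4g, a = %.4g, b = %.4g, N_flag = %d\n",
              x$l, x$d, x$a, x$b, x$N_flag))
  cat(sprintf("  Sp = %.4g, K_B = %.4g, K0*l = %.4g, gamma_tip = %.4g\n",
              x$Sp, x$K_B, x$K0 * x$l, x$gamma_tip))
  cat(sprintf("  omega_bar = %.6g, T = %.6g, dt = %.6g, sigma_omega = %.4g\n",
              x$omega_bar, x$T_period, x$dt, x$sigma_omega))
  invisible(x)
}

# calibrated tip-ramp fraction (see the methods vignette)
spermfilm_gamma_tip <- function() 0.084

#' Periodic thin-film grid geometry
#'
#' Uniform grid for the spectral Stokes solve in a triply periodic box of
#' size \code{L x L x L_z}. The film thickness is small (\code{L_z = 0.277 d}
#' for the reference swimmer) and, with swimmer motion restricted to the
#' midplane, the two free-slip symmetry planes of the periodic continuation
#' mimic a free-surface liquid film.
#'
#' @param N_x,N_y,N_z grid points per axis (even).
#' @param dx grid spacing, identical along all axes (default 19.40/64, the
#'   reference film thickness divided by its grid resolution).
#' @return An object of class \code{grid_spec} with fields \code{L},
#'   \code{L_z}, \code{N_x}, \code{N_y}, \code{N_z}, \code{dx}.
#' @export
grid_spec <- function(N_x = 512L, N_y = N_x, N_z = 64L, dx = 19.40 / 64) {
  stopifnot(N_x %% 2 == 0, N_y %% 2 == 0, N_z %% 2 == 0, dx > 0)
  g <- list(L = N_x * dx, L_y = N_y * dx, L_z = N_z * dx,
            N_x = as.integer(N_x), N_y = as.integer(N_y),
            N_z = as.integer(N_z), dx = dx)
  stopifnot(abs(g$dx - g$L / g$N_x) < 1e-9, abs(g$dx - g$L_z / g$N_z) < 1e-9)
  class(g) <- "grid_spec"
  g
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("Periodic film grid: %d x %d x %d, dx = %.5g, L = %.5g, L_z = %.5g\n",
              x$N_x, x$N_y, x$N_z, x$dx, x$L, x$L_z))
  invisible(x)
}

#' Implicit solver settings
#'
#' @param dt time step; defaults to \code{params$dt} when attached to a
#'   system (one three-hundredth of the mean undulation period).
#' @param broyden_tol residual tolerance per degree of freedom; the stopping
#'   criterion is \code{||residual|| <= broyden_tol * sqrt(n_dof)}.
#' @param broyden_maxit iteration cap per step.
#' @param constraint_tol admissibility tolerance for joint residuals,
#'   relative to the segment spacing \code{ds}.
#' @param jac_refresh rebuild the seed Jacobian every this many steps.
#' @return An object of class \code{solver_settings}.
#' @export
solver_settings <- function(dt = NULL, broyden_tol = 1e-8,
                            broyden_maxit = 100L, constraint_tol = 1e-8,
                            jac_refresh = 40L) {
  stopifnot(broyden_tol > 0, constraint_tol > 0, broyden_maxit >= 1)
  s <- list(dt = dt, broyden_tol = broyden_tol,
            broyden_maxit = as.integer(broyden_maxit),
            constraint_tol = constraint_tol,
            jac_refresh = as.integer(jac_refresh))
  class(s) <- "solver_settings"
  s
}

#' Suspension configuration
#'
#' @param N number of swimmers.
#' @param init_mode one of \code{"polar"} (uniformly placed, all swimming in
#'   the \code{-x} direction), \code{"isotropic"} (random orientations),
#'   \code{"pair"} (two parallel swimmers with a prescribed offset and phase
#'   difference) or \code{"solitary"}.
#' @param phase_seed,freq_seed,placement_seed RNG seeds for the independent
#'   random streams.
#' @param delta_phi imposed phase difference for \code{"pair"} mode.
#' @param pair_offset length-2 vector: initial offset of swimmer 2 relative
#'   to swimmer 1 for \code{"pair"} mode.
#' @param grid a \code{\link{grid_spec}} (used to report the effective area
#'   fraction \code{nu = N d^2 / (4 L^2)}).
#' @param params a \code{\link{physical_params}}.
#' @return An object of class \code{suspension_config}; field \code{nu}
#'   holds the effective area fraction.
#' @export
suspension_config <- function(N = 1L, init_mode = c("polar", "isotropic",
                                                    "pair", "solitary"),
                              phase_seed = 1L, freq_seed = 2L,
                              placement_seed = 3L, delta_phi = 0,
                              pair_offset = c(0, 0.3 * 70.1),
                              grid = NULL, params = NULL) {
  init_mode <- match.arg(init_mode)
  stopifnot(N >= 1)
  if (init_mode == "solitary") N <- 1L
  if (init_mode == "pair") N <- 2L
  nu <- NA_real_
  if (!is.null(grid) && !is.null(params)) {
    nu <- N * params$d^2 / (4 * grid$L^2)
  }
  cfg <- list(N = as.integer(N), init_mode = init_mode,
              phase_seed = as.integer(phase_seed),
              freq_seed = as.integer(freq_seed),
              placement_seed = as.integer(placement_seed),
              delta_phi = delta_phi, pair_offset = pair_offset, nu = nu)
  class(cfg) <- "suspension_config"
  cfg
}

#' Effective hydrodynamic radii of an oblate spheroidal head
#'
#' The head (semi-axes \code{a, a, c} with \code{c < a}) is represented in
#' the mobility solve by a single FCM particle. Its Gaussian envelope radius
#' is chosen so that the isolated particle reproduces the analytic Stokes
#' resistance of the spheroid: the translational radius matches the edgewise
#' (in-plane) drag \code{6 pi eta a_eff U} and the rotational radius matches
#' the torque \code{8 pi eta a_rot^3 Omega} for spin about the symmetry
#' axis. Both follow from the classical ellipsoid resistance integrals
#' \code{chi = int dt / Delta}, \code{alpha_i = int dt / ((a_i^2+t) Delta)}
#' with \code{Delta = sqrt(prod(a_i^2 + t))}: the edgewise drag radius is
#' \code{8 / (3 (chi + a^2 alpha_1))} and the spin radius is
#' \code{(2 / (3 alpha_1))^(1/3)}.
#'
#' @param a in-plane semi-axis.
#' @param c polar (out-of-plane) semi-axis.
#' @return list with \code{trans} and \code{rot} effective radii.
#' @export
oblate_effective_radii <- function(a, c) {
  stopifnot(a > 0, c > 0)
  Delta <- function(t) (a^2 + t) * sqrt(c^2 + t)
  chi <- stats::integrate(function(t) 1 / Delta(t), 0, Inf,
                          rel.tol = 1e-12)$value
  alpha1 <- stats::integrate(function(t) 1 / ((a^2 + t) * Delta(t)), 0, Inf,
                             rel.tol = 1e-12)$value
  list(trans = 8 / (3 * (chi + a^2 * alpha1)),
       rot = (2 / (3 * alpha1))^(1 / 3))
}
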