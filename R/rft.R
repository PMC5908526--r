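# Resistive force theory backend: local anisotropic drag, no hydrodynamic
# coupling between bodies. Used both as a physics backend (to isolate the
# role of hydrodynamic interactions) and, through per-swimmer Jacobian
# blocks, as the preconditioner seed for the implicit solver.

#' Resistive-force-theory drag coefficients
#'
#' Slender-body seed values
#' \code{xi_par = 2 pi eta / (log(l/b) - 1/2)},
#' \code{xi_perp = 4 pi eta / (log(l/b) + 1/2)} per unit length, a segment
#' rotational drag \code{xi_perp ds^3/12 + 8 pi eta b^3}, and head drags
#' from the oblate effective radii. \code{scale_par}/\code{scale_perp}
#' multiply the filament coefficients; \code{\link{calibrate_rft}} adjusts
#' them so that RFT swimming matches a reference FCM run.
#'
#' @param params a \code{\link{physical_params}}.
#' @param scale_par,scale_perp calibration factors for the tangential and
#'   normal filament drag.
#' @return list of coefficients (class \code{rft_coeffs}).
#' @export
rft_coeffs <- function(params, scale_par = 1, scale_perp = 1) {
  lr <- log(params$l / params$b)
  xi_par <- scale_par * 2 * pi * params$eta / (lr - 0.5)
  xi_perp <- scale_perp * 4 * pi * params$eta / (lr + 0.5)
  co <- list(
    xi_par = xi_par,
    xi_perp = xi_perp,
    zeta_rot_seg = xi_perp * params$ds^3 / 12 +
      8 * pi * params$eta * params$b^3,
    zeta_head_t = 6 * pi * params$eta * params$a_eff_trans,
    zeta_head_r = 8 * pi * params$eta * params$a_eff_rot^3,
    scale_par = scale_par, scale_perp = scale_perp
  )
  class(co) <- c("rft_coeffs", "list")
  co
}

#' RFT mobility solve
#'
#' Block-diagonal local drag: each segment's force is decomposed along its
#' tangent, \code{U = F_par/(xi_par ds) + F_perp/(xi_perp ds)}; the head is
#' an isotropic in-plane drag. No coupling between bodies.
#'
#' @param sys a \code{film_system} (any backend).
#' @param F n x 2 in-plane forces.
#' @param Tz out-of-plane torques.
#' @param coeffs an \code{\link{rft_coeffs}} (default: the system's).
#' @return list with \code{U} (n x 2) and \code{Wz}.
#' @export
rft_mobility <- function(sys, F, Tz = rep(0, nrow(F)), coeffs = sys$rft) {
  F <- rbind(F)
  out <- .rft_mobility_cpp(sys$model, sys$q, as.numeric(t(F)), Tz, coeffs)
  list(U = cbind(out$Ux, out$Uy), Wz = out$Wz)
}

#' Calibrate RFT drag coefficients against a reference run
#'
#' Adjusts the tangential/normal filament drag scales so that a solitary
#' RFT swimmer reproduces the mean swimming speed and the flagellar beat
#' amplitude of a reference trajectory (normally a converged FCM run).
#' Deterministic given the reference: Nelder--Mead on the squared relative
#' mismatch of (speed, amplitude RMS).
#'
#' @param reference a \code{film_trajectory} of a solitary swimmer.
#' @param params physical parameters (default: the reference's).
#' @param n_periods length of each trial RFT run.
#' @param start numeric length-2 starting scales.
#' @return an \code{\link{rft_coeffs}} with calibrated scales; the achieved
#'   mismatch is in attribute \code{"objective"}.
#' @export
calibrate_rft <- function(reference, params = reference$params,
                          n_periods = 6, start = c(1, 1)) {
  stats_ref <- solitary_run_stats(reference)
  if (!is.finite(stats_ref$speed) || stats_ref$speed <= 0) {
    stop("reference run has no converged swimming speed")
  }
  trial <- function(sc) {
    cfg <- suspension_config(N = 1, init_mode = "solitary")
    sys <- initialize_suspension(cfg, reference$grid, params,
                                 backend = "rft",
                                 rft = rft_coeffs(params, sc[1], sc[2]))
    tr <- run_film(sys, n_periods = n_periods, record_every = 2L)
    solitary_run_stats(tr)
  }
  obj <- function(sc) {
    if (any(sc <= 0.2) || any(sc >= 5)) return(10)
    st <- trial(sc)
    (st$speed / stats_ref$speed - 1)^2 +
      (st$amplitude / stats_ref$amplitude - 1)^2
  }
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-4, maxit = 60))
  out <- rft_coeffs(params, opt$par[1], opt$par[2])
  attr(out, "objective") <- opt$value
  out
}

# mean speed and beat amplitude (RMS lateral excursion in the swimmer
# frame) over the second half of a solitary run
solitary_run_stats <- function(traj) {
  n <- nrow(traj$q)
  i0 <- max(1, floor(n / 2))
  speed <- mean_swimming_speed(traj)
  bps <- traj$params$N_flag + 1
  cols_x <- seq(1, 3 * bps, by = 3)
  cols_y <- cols_x + 1
  amp <- numeric(0)
  com <- swimmer_com(traj)
  # swimming direction over the window
  dirv <- c(com[n, 1, 1] - com[i0, 1, 1], com[n, 1, 2] - com[i0, 1, 2])
  dirv <- dirv / sqrt(sum(dirv^2))
  for (i in seq(i0, n)) {
    xb <- traj$q[i, cols_x]
    yb <- traj$q[i, cols_y]
    lat <- -(xb - mean(xb)) * dirv[2] + (yb - mean(yb)) * dirv[1]
    amp <- c(amp, sqrt(mean(lat^2)))
  }
  list(speed = mean(speed), amplitude = mean(amp))
}
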