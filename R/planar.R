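# Compiled planar FCM backend. All bodies sit on the midplane z = L_z/2, so
# the triply periodic FCM solve collapses exactly to 2D transforms with
# kz-summed spectral kernels; results are identical (to roundoff) to the 3D
# route in fcm.R for midplane bodies.

#' Build the planar FCM backend
#'
#' Precomputes the kz-summed spectral kernels for the four Gaussian
#' envelope classes (segment/head monopole and rotlet dipole) on the given
#' film grid. The head envelope radii are the effective-sphere radii
#' reproducing the analytic edgewise drag and axial spin drag of the oblate
#' head (see \code{\link{oblate_effective_radii}}).
#'
#' @param params a \code{\link{physical_params}}.
#' @param grid a \code{\link{grid_spec}}.
#' @param nsw number of swimmers the context will serve.
#' @param phases static phase offsets, one per swimmer.
#' @param steric include steric barrier forces in force assembly.
#' @return an opaque backend object (external pointer plus metadata).
#' @export
planar_backend <- function(params, grid, nsw = 1, phases = rep(0, nsw),
                           steric = nsw > 1) {
  env_seg <- fcm_envelopes(params$b)
  env_head_t <- fcm_envelopes(params$a_eff_trans)
  env_head_r <- fcm_envelopes(params$a_eff_rot)
  sigma <- c(env_seg$sigma, env_seg$sigma_dip,
             env_head_t$sigma, env_head_r$sigma_dip)
  model <- model_desc(params, nsw, phases, grid, steric)
  ctx <- .planar_ctx_new(grid$N_x, grid$N_y, grid$N_z, grid$dx, params$eta,
                         sigma, model)
  structure(list(ctx = ctx, sigma = sigma, grid = grid, params = params,
                 model = model),
            class = "planar_fcm_backend")
}

#' Planar FCM mobility solve
#'
#' Maps in-plane forces and out-of-plane torques on midplane bodies to
#' in-plane velocities and spin rates through the periodic thin-film Stokes
#' solution.
#'
#' @param backend a \code{\link{planar_backend}} object.
#' @param pos n x 2 midplane positions.
#' @param F n x 2 in-plane forces.
#' @param Tz out-of-plane torques (length n).
#' @param cls body class per body: 0 = segment envelope, 1 = head envelope.
#' @return list with \code{U} (n x 2) and \code{Wz} (length n).
#' @export
planar_mobility <- function(backend, pos, F, Tz = rep(0, nrow(pos)),
                            cls = rep(0L, nrow(pos))) {
  pos <- rbind(pos); F <- rbind(F)
  out <- .planar_mobility_cpp(backend$ctx, pos[, 1], pos[, 2], F[, 1],
                              F[, 2], Tz, as.integer(cls))
  list(U = cbind(out$Ux, out$Uy), Wz = out$Wz)
}

#' Midplane velocity field for given body forces
#'
#' Evaluates the in-plane fluid velocity at the midplane grid for forces and
#' torques on midplane bodies (the field snapshot used for energy spectra
#' and flow maps).
#'
#' @inheritParams planar_mobility
#' @return list of matrices \code{ux}, \code{uy} (N_x x N_y).
#' @export
planar_midplane_field <- function(backend, pos, F, Tz = rep(0, nrow(pos)),
                                  cls = rep(0L, nrow(pos))) {
  pos <- rbind(pos); F <- rbind(F)
  .planar_midplane_field(backend$ctx, pos[, 1], pos[, 2], F[, 1], F[, 2],
                         Tz, as.integer(cls))
}
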