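#' Preferred curvature wave
#'
#' The flagellum is actuated by internal moments that drive its curvature
#' towards the travelling wave
#' \deqn{\kappa_0(s,t) = K_0 A(s) \sin(k s + \Phi + \phi),}
#' where \code{Phi} is the integrated drive phase (advancing as
#' \code{dPhi/dt = -omega}, so the wave travels from the head towards the
#' free end and the swimmer advances opposite to its tangent) and \code{phi}
#' a static per-swimmer offset. The amplitude envelope \code{A(s)} is 1 over
#' the proximal flagellum and decays linearly to 0 over the final
#' \code{gamma_tip} fraction, reproducing the reduced beat amplitude
#' observed near the tip.
#'
#' @param s arclength, in \code{[0, l]}.
#' @param t time; used only when \code{Phi} is \code{NULL}, in which case
#'   \code{Phi = -params$omega_bar * t}.
#' @param phi static phase offset (radians).
#' @param Phi integrated drive phase (radians), or \code{NULL}.
#' @param params a \code{\link{physical_params}}.
#' @return preferred curvature (1/length), bounded by \code{K0} in absolute
#'   value.
#' @export
preferred_curvature <- function(s, t = 0, phi = 0, Phi = NULL, params) {
  if (any(s < 0 | s > params$l)) {
    stop("arclength outside [0, l]")
  }
  if (is.null(Phi)) Phi <- -params$omega_bar * t
  params$K0 * tip_ramp(s, params) * sin(params$k_wave * s + Phi + phi)
}

# linear amplitude decay over the final gamma_tip fraction of the flagellum
tip_ramp <- function(s, params) {
  s0 <- (1 - params$gamma_tip) * params$l
  a <- rep(1, length(s))
  idx <- s > s0
  a[idx] <- (params$l - s[idx]) / (params$gamma_tip * params$l)
  pmax(a, 0)
}

# ---- planar state representation ------------------------------------------
# The simulation stores each body as (x, y, theta): positions in the
# midplane and the rotation angle about z mapping the body axis e1 onto the
# tangent. Richer state objects with 3-vectors and unit quaternions are
# derived views for analysis and for the documented state API.

#' Build an admissible straight swimmer
#'
#' Places a head at \code{head_pos} with axis angle \code{theta}; the
#' flagellum extends behind the head (the swimmer propels opposite to its
#' tangent): segment n sits at arclength \code{(n - 1/2) ds} measured from
#' the attachment point at distance \code{1.1 a + ds/2} from the head
#' centre. All joint constraints hold exactly.
#'
#' @param params a \code{\link{physical_params}}.
#' @param head_pos length-2 numeric, midplane head position.
#' @param theta orientation angle (tangent direction; the swimmer swims the
#'   opposite way).
#' @param phi static phase offset.
#' @return list with planar coordinate vector \code{q} (3 per body, head
#'   first), \code{phi}, and zeroed multipliers \code{lambda}.
#' @export
straight_swimmer <- function(params, head_pos = c(0, 0), theta = 0,
                             phi = 0) {
  n <- params$N_flag
  off_h <- 1.1 * params$a + params$ds / 2
  tx <- cos(theta); ty <- sin(theta)
  q <- numeric(3 * (n + 1))
  q[1:2] <- head_pos
  q[3] <- theta
  for (j in seq_len(n)) {
    s <- off_h + (j - 1) * params$ds
    q[3 * j + 1] <- head_pos[1] + s * tx
    q[3 * j + 2] <- head_pos[2] + s * ty
    q[3 * j + 3] <- theta
  }
  list(q = q, phi = phi, lambda = numeric(3 + 2 * (n - 1)))
}

#' Swimmer state with positions, quaternions and tangents
#'
#' Expands planar body coordinates into the documented state form: head
#' position/orientation quaternion plus per-segment positions \code{Y},
#' unit quaternions \code{q} (rotation about z), and tangents \code{t_hat}
#' (image of the body axis e1).
#'
#' @param q planar coordinate vector for one swimmer (3 per body).
#' @param params a \code{\link{physical_params}}.
#' @param z midplane height to report for the third coordinate.
#' @param phi,Phi,omega_cur drive phase state to attach.
#' @return object of class \code{swimmer_state}.
#' @export
swimmer_state <- function(q, params, z = 0, phi = 0, Phi = 0,
                          omega_cur = params$omega_bar) {
  n <- params$N_flag
  stopifnot(length(q) == 3 * (n + 1))
  th <- q[seq(3, length(q), by = 3)]
  pos <- cbind(q[seq(1, length(q), by = 3)], q[seq(2, length(q), by = 3)], z)
  quat <- cbind(cos(th / 2), 0, 0, sin(th / 2))
  that <- cbind(cos(th), sin(th), 0)
  st <- list(
    head_pos = pos[1, ], head_q = quat[1, ],
    flagellum = list(N_flag = n, ds = params$ds, Y = pos[-1, , drop = FALSE],
                     q = quat[-1, , drop = FALSE],
                     t_hat = that[-1, , drop = FALSE]),
    phi = phi, Phi = Phi, omega_cur = omega_cur, params = params
  )
  class(st) <- "swimmer_state"
  st
}

#' Elastic bending torques at flagellum joints
#'
#' Discrete bending moments: at joint n (between segments n and n+1) the
#' pair \code{+(K_B/ds) t_hat[n] x t_hat[n+1]} acts on segment n and its
#' negative on segment n+1. This is the exact negative gradient of the
#' discrete bending energy \code{(K_B/ds) sum(1 - t_hat[n].t_hat[n+1])}.
#'
#' @param state a \code{\link{swimmer_state}} (or its \code{$flagellum}).
#' @param params a \code{\link{physical_params}}.
#' @return matrix with one row per joint: the 3-vector torque applied to the
#'   lower-numbered segment (the other segment receives the negative).
#' @export
bending_torques <- function(state, params) {
  th <- state$flagellum$t_hat
  n <- nrow(th)
  j <- seq_len(n - 1)
  cr <- cbind(th[j, 2] * th[j + 1, 3] - th[j, 3] * th[j + 1, 2],
              th[j, 3] * th[j + 1, 1] - th[j, 1] * th[j + 1, 3],
              th[j, 1] * th[j + 1, 2] - th[j, 2] * th[j + 1, 1])
  (params$K_B / params$ds) * cr
}

#' Actuation torques from the preferred curvature
#'
#' Internal driving pairs: at joint n the actuation applies
#' \code{-K_B kappa0(s_n, t) j_hat} to segment n and the negative to segment
#' n+1, with \code{j_hat} the out-of-plane joint binormal. Summed with
#' \code{\link{bending_torques}}, joint moments vanish exactly when the
#' discrete curvature matches the preferred curvature, and the total over
#' the swimmer is always zero (internal actuation).
#'
#' @inheritParams bending_torques
#' @param t time (used when the state carries no integrated phase).
#' @return matrix, one row per joint (torque on the lower segment).
#' @export
driving_torques <- function(state, t = 0, params) {
  n <- state$flagellum$N_flag
  sj <- seq_len(n - 1) * params$ds
  k0 <- preferred_curvature(sj, t = t, phi = state$phi, Phi = state$Phi,
                            params = params)
  cbind(0, 0, -params$K_B * k0)
}

#' Constraint residuals of a swimmer configuration
#'
#' The flagellum is inextensible: adjacent segment centres must satisfy
#' \code{Y[n+1] - Y[n] = (ds/2) (t_hat[n] + t_hat[n+1])}. The head linkage
#' requires the first segment centre at distance \code{1.1 a + ds/2} along
#' the head axis (attachment-point coincidence) and the first tangent
#' parallel to the head axis (clamped end).
#'
#' @inheritParams bending_torques
#' @return list with \code{joints} (matrix, one 3-vector per interior
#'   joint), \code{head} (3-vector linkage residual) and \code{clamp}
#'   (angle mismatch).
#' @export
constraint_residuals <- function(state, params) {
  fl <- state$flagellum
  n <- fl$N_flag
  j <- seq_len(n - 1)
  res <- fl$Y[j + 1, , drop = FALSE] - fl$Y[j, , drop = FALSE] -
    (params$ds / 2) * (fl$t_hat[j, , drop = FALSE] +
                       fl$t_hat[j + 1, , drop = FALSE])
  off_h <- 1.1 * params$a + params$ds / 2
  axis <- quat_axis(state$head_q)
  head_res <- fl$Y[1, ] - state$head_pos - off_h * axis
  clamp <- acos(pmin(1, sum(axis * fl$t_hat[1, ])))
  list(joints = res, head = head_res, clamp = clamp)
}

quat_axis <- function(q) {
  # image of e1 under the unit quaternion (w, x, y, z)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y))
}

#' Constraint forces and torques from joint multipliers
#'
#' Exact virtual-work conjugates of the constraint residuals: with one
#' multiplier 3-vector per interior joint, segment n receives the force
#' \code{Lambda[n] - Lambda[n-1]} (boundary multipliers zero) and the torque
#' \code{(ds/2) t_hat[n] x (Lambda[n] + Lambda[n-1])}; both total force and
#' total torque about any fixed point vanish over the swimmer.
#'
#' @inheritParams bending_torques
#' @param Lambda matrix, one multiplier 3-vector per interior joint.
#' @return list of matrices \code{F} (per segment) and \code{T} (per
#'   segment).
#' @export
constraint_forces <- function(state, Lambda, params) {
  fl <- state$flagellum
  n <- fl$N_flag
  if (!is.matrix(Lambda) || nrow(Lambda) != n - 1) {
    stop("need one multiplier 3-vector per interior joint")
  }
  lam_pad <- rbind(0, Lambda, 0)[, , drop = FALSE] # index n: joint below is n-1
  Fm <- matrix(0, n, 3)
  Tm <- matrix(0, n, 3)
  for (b in seq_len(n)) {
    lam_up <- if (b < n) Lambda[b, ] else c(0, 0, 0)
    lam_dn <- if (b > 1) Lambda[b - 1, ] else c(0, 0, 0)
    Fm[b, ] <- lam_up - lam_dn
    s <- lam_up + lam_dn
    t <- fl$t_hat[b, ]
    Tm[b, ] <- (params$ds / 2) * c(t[2] * s[3] - t[3] * s[2],
                                   t[3] * s[1] - t[1] * s[3],
                                   t[1] * s[2] - t[2] * s[1])
  }
  list(F = Fm, T = Tm)
}

#' Driven discrete elastic energy
#'
#' \code{E = (K_B/ds) sum_j (1 - cos(dtheta_j)) - K_B sum_j kappa0(s_j)
#' dtheta_j}: bending plus the linear actuation potential whose negative
#' gradient with respect to joint angles reproduces
#' \code{\link{bending_torques}} + \code{\link{driving_torques}}.
#'
#' @param theta per-segment tangent angles.
#' @param phi,Phi drive phase.
#' @param params a \code{\link{physical_params}}.
#' @export
driven_elastic_energy <- function(theta, phi = 0, Phi = 0, params) {
  n <- length(theta)
  dth <- diff(theta)
  sj <- seq_len(n - 1) * params$ds
  k0 <- preferred_curvature(sj, phi = phi, Phi = Phi, params = params)
  (params$K_B / params$ds) * sum(1 - cos(dth)) - params$K_B * sum(k0 * dth)
}

#' Build a swimmer with prescribed tangent angles
#'
#' Constructs planar coordinates for a swimmer whose segments have the given
#' tangent angles, with positions chained so that every joint constraint
#' holds exactly (\code{Y[n+1] = Y[n] + (ds/2)(t[n] + t[n+1])}) and the head
#' placed by the linkage constraint with axis equal to the first tangent.
#'
#' @param params a \code{\link{physical_params}}.
#' @param head_pos length-2 head position.
#' @param thetas tangent angle per segment (length \code{N_flag}).
#' @param phi static phase offset.
#' @return list with \code{q}, \code{phi}, zeroed \code{lambda}.
#' @export
swimmer_from_angles <- function(params, head_pos = c(0, 0), thetas,
                                phi = 0) {
  n <- params$N_flag
  stopifnot(length(thetas) == n)
  off_h <- 1.1 * params$a + params$ds / 2
  q <- numeric(3 * (n + 1))
  q[1:2] <- head_pos
  q[3] <- thetas[1]
  x <- head_pos[1] + off_h * cos(thetas[1])
  y <- head_pos[2] + off_h * sin(thetas[1])
  q[4] <- x; q[5] <- y; q[6] <- thetas[1]
  for (j in 2:n) {
    x <- x + (params$ds / 2) * (cos(thetas[j - 1]) + cos(thetas[j]))
    y <- y + (params$ds / 2) * (sin(thetas[j - 1]) + sin(thetas[j]))
    q[3 * j + 1] <- x
    q[3 * j + 2] <- y
    q[3 * j + 3] <- thetas[j]
  }
  list(q = q, phi = phi, lambda = numeric(3 + 2 * (n - 1)))
}

# model description list handed to the compiled kernels
model_desc <- function(params, nsw, phases, grid, steric = TRUE) {
  list(nsw = as.integer(nsw), nseg = params$N_flag, ds = params$ds,
       KB = params$K_B, K0 = params$K0, kwave = params$k_wave, l = params$l,
       gamma_tip = params$gamma_tip,
       off_h = 1.1 * params$a + params$ds / 2,
       FS = params$F_S, chi = 1.1, rad_head = params$a,
       rad_seg = params$b, steric = isTRUE(steric),
       Lx = if (is.null(grid)) 0 else grid$L,
       Ly = if (is.null(grid)) 0 else grid$L_y,
       phase = as.numeric(phases))
}
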