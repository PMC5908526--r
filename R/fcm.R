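# Reference force-coupling-method route on the full 3D periodic grid, in
# plain R via stats::fft. This is the general-geometry API and the oracle
# against which the planar fast path is verified; production stepping uses
# the compiled planar solver.

TRUNC_SD <- 7 # Gaussian truncation radius in standard deviations

fcm_freqs <- function(n, L) {
  idx <- 0:(n - 1)
  f <- ifelse(idx <= n / 2, idx, idx - n)
  2 * pi * f / L
}

# derivative wavenumbers: odd spectral factors vanish at the Nyquist mode
fcm_freqs_deriv <- function(n, L) {
  k <- fcm_freqs(n, L)
  if (n %% 2 == 0) k[n / 2 + 1] <- 0
  k
}

gauss_weights_1d <- function(x, dx, sigma, n = Inf) {
  supp <- ceiling(TRUNC_SD * sigma / dx)
  if (2 * supp + 1 > n) {
    stop("envelope support exceeds the grid extent along one axis")
  }
  i0 <- round(x / dx) - supp
  xi <- (i0 + 0:(2 * supp)) * dx
  w <- exp(-0.5 * (xi - x)^2 / sigma^2) / sqrt(2 * pi * sigma^2)
  list(i0 = i0, w = w)
}

#' Spread body forces (and torques) onto the periodic grid
#'
#' Deposits each force monopole with the Gaussian envelope
#' \code{Delta(r) = (2 pi sigma^2)^(-3/2) exp(-r^2 / 2 sigma^2)}, sampled on
#' the grid and truncated at 7 sigma. Torques, when given, are deposited as
#' the antisymmetric (rotlet) dipole of a second Gaussian of width
#' \code{sigma_dip}, applied spectrally as
#' \code{f_hat += -(i/2) (T x k) Dhat(k)}.
#'
#' @param pos n x 3 body positions (inside the box).
#' @param F n x 3 forces.
#' @param grid a \code{\link{grid_spec}}.
#' @param sigma monopole envelope width(s), recycled over bodies.
#' @param torque optional n x 3 torques.
#' @param sigma_dip dipole envelope width(s) (required with torques).
#' @return a \code{fluid_field} object with force-density component arrays
#'   \code{f[[1..3]]}.
#' @export
fcm_spread <- function(pos, F, grid, sigma, torque = NULL, sigma_dip = NULL) {
  pos <- rbind(pos); F <- rbind(F)
  n <- nrow(pos)
  sigma <- rep(sigma, length.out = n)
  if (any(sigma / grid$dx < 1)) {
    stop("unresolved FCM envelope: sigma/dx < 1")
  }
  dims <- c(grid$N_x, grid$N_y, grid$N_z)
  f <- lapply(1:3, function(i) array(0, dims))
  for (b in seq_len(n)) {
    wx <- gauss_weights_1d(pos[b, 1], grid$dx, sigma[b], grid$N_x)
    wy <- gauss_weights_1d(pos[b, 2], grid$dx, sigma[b], grid$N_y)
    wz <- gauss_weights_1d(pos[b, 3], grid$dx, sigma[b], grid$N_z)
    ix <- (wx$i0 + 0:(length(wx$w) - 1)) %% grid$N_x + 1
    iy <- (wy$i0 + 0:(length(wy$w) - 1)) %% grid$N_y + 1
    iz <- (wz$i0 + 0:(length(wz$w) - 1)) %% grid$N_z + 1
    blob <- outer(outer(wx$w, wy$w), wz$w)
    for (cmp in 1:3) {
      if (F[b, cmp] != 0) {
        f[[cmp]][ix, iy, iz] <- f[[cmp]][ix, iy, iz] + F[b, cmp] * blob
      }
    }
  }
  field <- structure(list(f = f, grid = grid), class = "fluid_field")
  if (!is.null(torque)) {
    torque <- rbind(torque)
    stopifnot(!is.null(sigma_dip))
    sigma_dip <- rep(sigma_dip, length.out = n)
    fh <- lapply(field$f, stats::fft)
    kx <- fcm_freqs_deriv(grid$N_x, grid$L)
    ky <- fcm_freqs_deriv(grid$N_y, grid$L_y)
    kz <- fcm_freqs_deriv(grid$N_z, grid$L_z)
    KX <- array(rep(kx, times = grid$N_y * grid$N_z), dims)
    KY <- array(rep(rep(ky, each = grid$N_x), times = grid$N_z), dims)
    KZ <- array(rep(kz, each = grid$N_x * grid$N_y), dims)
    for (b in seq_len(n)) {
      if (all(torque[b, ] == 0)) next
      dhat <- stats::fft(dipole_blob_field(pos[b, ], grid, sigma_dip[b]))
      tx <- torque[b, 1]; ty <- torque[b, 2]; tz <- torque[b, 3]
      # T x k components
      fh[[1]] <- fh[[1]] - (0.5i) * (ty * KZ - tz * KY) * dhat
      fh[[2]] <- fh[[2]] - (0.5i) * (tz * KX - tx * KZ) * dhat
      fh[[3]] <- fh[[3]] - (0.5i) * (tx * KY - ty * KX) * dhat
    }
    ntot <- prod(dims)
    field$f <- lapply(fh, function(z) Re(stats::fft(z, inverse = TRUE)) / ntot)
  }
  field
}

dipole_blob_field <- function(p, grid, sigma) {
  arr <- array(0, c(grid$N_x, grid$N_y, grid$N_z))
  wx <- gauss_weights_1d(p[1], grid$dx, sigma, grid$N_x)
  wy <- gauss_weights_1d(p[2], grid$dx, sigma, grid$N_y)
  wz <- gauss_weights_1d(p[3], grid$dx, sigma, grid$N_z)
  ix <- (wx$i0 + 0:(length(wx$w) - 1)) %% grid$N_x + 1
  iy <- (wy$i0 + 0:(length(wy$w) - 1)) %% grid$N_y + 1
  iz <- (wz$i0 + 0:(length(wz$w) - 1)) %% grid$N_z + 1
  arr[ix, iy, iz] <- outer(outer(wx$w, wy$w), wz$w)
  arr
}

#' Solve the periodic Stokes equations spectrally
#'
#' \code{u_hat(k) = (1/(eta |k|^2)) (I - k_hat k_hat^T) f_hat(k)} for
#' \code{k != 0}; the \code{k = 0} mode is set to zero. The mean force
#' density must vanish for periodic solvability; any roundoff-level mean is
#' removed and recorded in the \code{"mean_force_removed"} attribute.
#'
#' @param field a \code{fluid_field} holding force densities \code{f}.
#' @param grid a \code{\link{grid_spec}} (defaults to the field's grid).
#' @param eta dynamic viscosity.
#' @return the field with velocity component arrays \code{u[[1..3]]} added.
#' @export
stokes_solve_periodic <- function(field, grid = field$grid, eta = 1) {
  dims <- c(grid$N_x, grid$N_y, grid$N_z)
  fh <- lapply(field$f, stats::fft)
  mean_f <- vapply(fh, function(z) Mod(z[1, 1, 1]) / prod(dims), 0)
  kx <- fcm_freqs(grid$N_x, grid$L)
  ky <- fcm_freqs(grid$N_y, grid$L_y)
  kz <- fcm_freqs(grid$N_z, grid$L_z)
  KX <- array(rep(kx, times = grid$N_y * grid$N_z), dims)
  KY <- array(rep(rep(ky, each = grid$N_x), times = grid$N_z), dims)
  KZ <- array(rep(kz, each = grid$N_x * grid$N_y), dims)
  K2 <- KX^2 + KY^2 + KZ^2
  K2[1, 1, 1] <- 1
  kf <- (KX * fh[[1]] + KY * fh[[2]] + KZ * fh[[3]]) / K2
  uh <- list((fh[[1]] - KX * kf) / (eta * K2),
             (fh[[2]] - KY * kf) / (eta * K2),
             (fh[[3]] - KZ * kf) / (eta * K2))
  for (cmp in 1:3) uh[[cmp]][1, 1, 1] <- 0
  ntot <- prod(dims)
  field$u <- lapply(uh, function(z) Re(stats::fft(z, inverse = TRUE)) / ntot)
  field$u_hat <- uh
  attr(field, "mean_force_removed") <- mean_f
  field
}

#' Average the fluid velocity over body envelopes
#'
#' \code{U_n = int u Delta_n dV}; angular velocities, when requested, are
#' half the spectral curl of \code{u} averaged with the dipole envelope.
#'
#' @param field a solved \code{fluid_field} (with \code{u}).
#' @param pos n x 3 body positions.
#' @param sigma monopole envelope width(s).
#' @param sigma_dip optional dipole widths: also return angular velocities.
#' @return list with \code{U} (n x 3) and, if requested, \code{W} (n x 3).
#' @export
fcm_interpolate <- function(field, pos, sigma, sigma_dip = NULL) {
  grid <- field$grid
  pos <- rbind(pos)
  n <- nrow(pos)
  sigma <- rep(sigma, length.out = n)
  U <- matrix(0, n, 3)
  for (b in seq_len(n)) {
    wx <- gauss_weights_1d(pos[b, 1], grid$dx, sigma[b], grid$N_x)
    wy <- gauss_weights_1d(pos[b, 2], grid$dx, sigma[b], grid$N_y)
    wz <- gauss_weights_1d(pos[b, 3], grid$dx, sigma[b], grid$N_z)
    ix <- (wx$i0 + 0:(length(wx$w) - 1)) %% grid$N_x + 1
    iy <- (wy$i0 + 0:(length(wy$w) - 1)) %% grid$N_y + 1
    iz <- (wz$i0 + 0:(length(wz$w) - 1)) %% grid$N_z + 1
    blob <- outer(outer(wx$w, wy$w), wz$w)
    for (cmp in 1:3) {
      U[b, cmp] <- sum(field$u[[cmp]][ix, iy, iz] * blob) * grid$dx^3
    }
  }
  out <- list(U = U)
  if (!is.null(sigma_dip)) {
    sigma_dip <- rep(sigma_dip, length.out = n)
    dims <- c(grid$N_x, grid$N_y, grid$N_z)
    uh <- field$u_hat
    if (is.null(uh)) uh <- lapply(field$u, stats::fft)
    kx <- fcm_freqs_deriv(grid$N_x, grid$L)
    ky <- fcm_freqs_deriv(grid$N_y, grid$L_y)
    kz <- fcm_freqs_deriv(grid$N_z, grid$L_z)
    KX <- array(rep(kx, times = grid$N_y * grid$N_z), dims)
    KY <- array(rep(rep(ky, each = grid$N_x), times = grid$N_z), dims)
    KZ <- array(rep(kz, each = grid$N_x * grid$N_y), dims)
    ntot <- prod(dims)
    wf <- list(
      Re(stats::fft((0.5i) * (KY * uh[[3]] - KZ * uh[[2]]), inverse = TRUE)) / ntot,
      Re(stats::fft((0.5i) * (KZ * uh[[1]] - KX * uh[[3]]), inverse = TRUE)) / ntot,
      Re(stats::fft((0.5i) * (KX * uh[[2]] - KY * uh[[1]]), inverse = TRUE)) / ntot)
    W <- matrix(0, n, 3)
    for (b in seq_len(n)) {
      wx <- gauss_weights_1d(pos[b, 1], grid$dx, sigma_dip[b], grid$N_x)
      wy <- gauss_weights_1d(pos[b, 2], grid$dx, sigma_dip[b], grid$N_y)
      wz <- gauss_weights_1d(pos[b, 3], grid$dx, sigma_dip[b], grid$N_z)
      ix <- (wx$i0 + 0:(length(wx$w) - 1)) %% grid$N_x + 1
      iy <- (wy$i0 + 0:(length(wy$w) - 1)) %% grid$N_y + 1
      iz <- (wz$i0 + 0:(length(wz$w) - 1)) %% grid$N_z + 1
      blob <- outer(outer(wx$w, wy$w), wz$w)
      for (cmp in 1:3) {
        W[b, cmp] <- sum(wf[[cmp]][ix, iy, iz] * blob) * grid$dx^3
      }
    }
    out$W <- W
  }
  out
}

#' Full FCM mobility solve (reference 3D route)
#'
#' Composition spread -> periodic Stokes solve -> interpolate: maps forces
#' and torques on all bodies to translational and angular velocities. The
#' resulting mobility action is symmetric positive-semidefinite.
#'
#' @inheritParams fcm_spread
#' @param torque optional n x 3 torques.
#' @param eta viscosity.
#' @return list with \code{U} and \code{W} (n x 3 each).
#' @export
fcm_mobility <- function(pos, F, grid, sigma, torque = NULL,
                         sigma_dip = NULL, eta = 1) {
  if (is.null(sigma_dip)) sigma_dip <- sigma / (6 * sqrt(pi))^(1 / 3) * sqrt(pi)
  field <- fcm_spread(pos, F, grid, sigma, torque = torque,
                      sigma_dip = sigma_dip)
  field <- stokes_solve_periodic(field, grid, eta)
  fcm_interpolate(field, pos, sigma, sigma_dip = sigma_dip)
}

#' Spectral divergence of a solved velocity field
#'
#' @param field a solved \code{fluid_field}.
#' @return ratio of the divergence spectral norm to the velocity spectral
#'   norm (zero for an incompressible solve).
#' @export
field_divergence <- function(field) {
  grid <- field$grid
  dims <- c(grid$N_x, grid$N_y, grid$N_z)
  uh <- field$u_hat
  if (is.null(uh)) uh <- lapply(field$u, stats::fft)
  kx <- fcm_freqs(grid$N_x, grid$L)
  ky <- fcm_freqs(grid$N_y, grid$L_y)
  kz <- fcm_freqs(grid$N_z, grid$L_z)
  KX <- array(rep(kx, times = grid$N_y * grid$N_z), dims)
  KY <- array(rep(rep(ky, each = grid$N_x), times = grid$N_z), dims)
  KZ <- array(rep(kz, each = grid$N_x * grid$N_y), dims)
  div <- KX * uh[[1]] + KY * uh[[2]] + KZ * uh[[3]]
  unorm <- sqrt(sum(Mod(uh[[1]])^2 + Mod(uh[[2]])^2 + Mod(uh[[3]])^2))
  kn <- sqrt(mean(KX^2 + KY^2 + KZ^2))
  sqrt(sum(Mod(div)^2)) / (unorm * kn + .Machine$double.eps)
}

#' FCM envelope widths for a hydrodynamic radius
#'
#' Standard force-coupling-method envelopes: the monopole width
#' \code{sigma = a / sqrt(pi)} reproduces the isolated Stokes drag
#' \code{6 pi eta a}, and the dipole width
#' \code{sigma_dip = a / (6 sqrt(pi))^(1/3)} the rotational drag
#' \code{8 pi eta a^3}.
#'
#' @param a hydrodynamic radius.
#' @return list with \code{sigma} and \code{sigma_dip}.
#' @export
fcm_envelopes <- function(a) {
  list(sigma = a / sqrt(pi), sigma_dip = a / (6 * sqrt(pi))^(1 / 3))
}
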