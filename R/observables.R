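# Analysis statistics: force-moment tensors, order parameters, fluid and
# swimmer-velocity spectra, low-pass filtering, pair displacement maps and
# cluster statistics.

#' In-plane force dipole and quadrupole moments
#'
#' From the hydrodynamic loads \code{F^H} on the bodies (the negatives of
#' the forces the swimmer exerts on the fluid; with this sign a pusher has
#' \code{G11 < 0} in the swimming frame), computes per recorded
#' frame the in-plane first moment \code{D_ij = sum_n F_i r_j} about the
#' swimmer centre of mass and the second moment
#' \code{Q_ijk = sum_n F_i r_j r_k}, in the swimmer frame whose x-axis is
#' the mean swimming direction over the analysis window. Reported are the
#' symmetric dipole \code{G}, the (first-two-indices) symmetric quadrupole
#' \code{K_S} and the antisymmetric quadrupole
#' \code{K_A}. The antisymmetric dipole, including the body-torque
#' monopoles, is \code{-(net torque on the fluid)/2} and vanishes for the
#' torque-free swimmer. With \code{F0} supplied (see
#' \code{\link{f0_normalization}}) moments are reported in units of
#' \code{F0 d} and \code{F0 d^2}.
#'
#' The dipole components are the symmetrized first-moment entries; because
#' the in-plane trace (the pressure moment) does not vanish for a beating
#' swimmer, no trace is subtracted from the reported components by default
#' (the two printed diagonal entries carry independent information).
#' \code{detrace = "plane"} subtracts half the in-plane trace when a
#' strictly trace-free tensor is wanted.
#'
#' @param traj a \code{film_trajectory}.
#' @param swimmer swimmer index.
#' @param t_from,t_to analysis window (defaults: second half).
#' @param F0 normalization force; \code{NULL} leaves raw units and flags
#'   the output.
#' @param detrace \code{"none"} (default) or \code{"plane"}: subtract the
#'   in-plane trace from \code{G} and (in the first two indices) from
#'   \code{K_S}.
#' @return object of class \code{moment_set}: data frame with columns
#'   \code{t, G11, G22, G12, A12, K111, K221, K122, K222, KA*}, plus
#'   attributes \code{F0}, \code{frame} (unit vector of the swimmer frame
#'   x-axis).
#' @export
force_moments <- function(traj, swimmer = 1, t_from = NULL, t_to = NULL,
                          F0 = NULL, detrace = c("none", "plane")) {
  detrace <- match.arg(detrace)
  n <- nrow(traj$q)
  if (is.null(t_to)) t_to <- traj$times[n]
  if (is.null(t_from)) t_from <- traj$times[1]
  idx <- which(traj$times >= t_from & traj$times <= t_to)
  bps <- traj$params$N_flag + 1
  cols <- 3 * bps * (swimmer - 1) + seq_len(3 * bps)
  d <- traj$params$d

  # swimmer frame: x-axis along the window-averaged swimming direction
  com <- swimmer_com(traj)
  dirv <- c(com[idx[length(idx)], swimmer, 1] - com[idx[1], swimmer, 1],
            com[idx[length(idx)], swimmer, 2] - com[idx[1], swimmer, 2])
  dirv <- dirv / sqrt(sum(dirv^2))
  ex <- dirv
  ey <- c(-dirv[2], dirv[1])

  fcols <- 2 * bps * (swimmer - 1) + seq_len(2 * bps)
  tcols <- bps * (swimmer - 1) + seq_len(bps)
  out <- data.frame(t = traj$times[idx])
  nm <- c("G11", "G22", "G12", "A12", "K111", "K221", "K122", "K222",
          "KA121", "KA122")
  for (v in nm) out[[v]] <- 0
  for (fi in seq_along(idx)) {
    i <- idx[fi]
    qrow <- traj$q[i, cols]
    xb <- qrow[seq(1, 3 * bps, by = 3)]
    yb <- qrow[seq(2, 3 * bps, by = 3)]
    # hydrodynamic loads on the bodies: negatives of the forces on the fluid
    Frow <- -traj$F_fluid[i, fcols]
    fx <- Frow[seq(1, 2 * bps, by = 2)]
    fy <- Frow[seq(2, 2 * bps, by = 2)]
    tz <- -traj$T_fluid[i, tcols]
    rx <- xb - mean(xb)
    ry <- yb - mean(yb)
    # rotate into the swimmer frame
    r1 <- rx * ex[1] + ry * ex[2]
    r2 <- rx * ey[1] + ry * ey[2]
    f1 <- fx * ex[1] + fy * ex[2]
    f2 <- fx * ey[1] + fy * ey[2]
    D11 <- sum(f1 * r1); D22 <- sum(f2 * r2)
    D12 <- sum(f1 * r2); D21 <- sum(f2 * r1)
    tr2 <- if (detrace == "plane") (D11 + D22) / 2 else 0
    out$G11[fi] <- D11 - tr2
    out$G22[fi] <- D22 - tr2
    out$G12[fi] <- (D12 + D21) / 2
    out$A12[fi] <- (D12 - D21) / 2 - sum(tz) / 2
    Q111 <- sum(f1 * r1 * r1); Q221 <- sum(f2 * r2 * r1)
    Q122 <- sum(f1 * r2 * r2); Q222 <- sum(f2 * r2 * r2)
    Q121 <- sum(f1 * r2 * r1); Q211 <- sum(f2 * r1 * r1)
    Q212 <- sum(f2 * r1 * r2); Q112 <- sum(f1 * r1 * r2)
    # symmetrize in the first two indices
    S111 <- Q111; S221 <- Q221
    S121 <- (Q121 + Q211) / 2
    S112 <- Q112; S222 <- Q222
    S122 <- (Q122 + Q212) / 2
    tr1 <- if (detrace == "plane") (S111 + S221) / 2 else 0
    tr2q <- if (detrace == "plane") (S112 + S222) / 2 else 0
    out$K111[fi] <- S111 - tr1
    out$K221[fi] <- S221 - tr1
    out$K122[fi] <- S122 - tr2q
    out$K222[fi] <- S222 - tr2q
    out$KA121[fi] <- (Q121 - Q211) / 2
    out$KA122[fi] <- (Q122 - Q212) / 2
  }
  if (!is.null(F0)) {
    for (v in c("G11", "G22", "G12", "A12")) out[[v]] <- out[[v]] / (F0 * d)
    for (v in c("K111", "K221", "K122", "K222", "KA121", "KA122")) {
      out[[v]] <- out[[v]] / (F0 * d^2)
    }
  }
  structure(out, F0 = F0, frame = ex, class = c("moment_set", "data.frame"),
            normalized = !is.null(F0))
}

#' Head-drag normalization force
#'
#' \code{F0} is the in-plane drag on the isolated cell head translating at
#' the mean swimming speed, computed with the same mobility backend and
#' envelopes as the simulation.
#'
#' @param traj a solitary \code{film_trajectory} (FCM backend), or supply
#'   \code{U_mean}, \code{params} and \code{grid} directly.
#' @param U_mean mean swimming speed (default: measured from \code{traj}).
#' @return positive scalar force.
#' @export
f0_normalization <- function(traj, U_mean = NULL) {
  params <- traj$params
  if (is.null(U_mean)) U_mean <- mean(mean_swimming_speed(traj))
  if (!is.finite(U_mean) || U_mean == 0) stop("zero mean swimming speed")
  if (traj$backend == "fcm") {
    be <- planar_backend(params, traj$grid, nsw = 1, steric = FALSE)
    pos <- matrix(c(traj$grid$L / 2, traj$grid$L_y / 2), 1, 2)
    mob <- planar_mobility(be, pos, matrix(c(1, 0), 1, 2), 0, cls = 1L)
    mobility <- mob$U[1, 1]
  } else {
    mobility <- 1 / (6 * pi * params$eta * params$a_eff_trans)
  }
  U_mean / mobility
}

#' Quadrupole--dipole crossover separation
#'
#' Far-field estimate of the separation below which the instantaneous
#' quadrupolar flow exceeds the dipolar flow:
#' \code{r* = max_t |K| / max_t |G|}, reported in units of the swimmer
#' length (moments normalized by \code{F0 d}, \code{F0 d^2} make the ratio
#' directly the crossover in units of d).
#'
#' @param moments a \code{moment_set} (normalized).
#' @param dipole,quadrupole column names of the component series to
#'   compare.
#' @return crossover separation in swimmer lengths.
#' @export
singularity_crossover <- function(moments, dipole = "G11",
                                  quadrupole = "K111") {
  gmax <- max(abs(moments[[dipole]]))
  if (gmax == 0) stop("zero dipole maximum: crossover undefined")
  max(abs(moments[[quadrupole]])) / gmax
}

#' Polar and nematic order parameters
#'
#' \code{S1(t) = < p_n . e0 >_n} and \code{S2(t) = < 2 (p_n . e0)^2 - 1 >_n}
#' (planar nematic convention), with \code{e0} the initial swimming
#' direction and \code{p_n} the n-th swimmer's mean orientation: the unit
#' vector from the flagellum tip to the head (the end-to-end axis points
#' where the swimmer swims), low-pass averaged over one undulation period.
#'
#' @param traj a \code{film_trajectory}.
#' @param e0 reference direction (default \code{c(-1, 0)}, the initial
#'   swimming direction of polar starts).
#' @param smooth_window width (in time units) of the orientation average;
#'   default one mean period.
#' @return data frame with columns \code{t}, \code{S1}, \code{S2}.
#' @export
order_parameters <- function(traj, e0 = c(-1, 0), smooth_window = NULL) {
  if (is.null(smooth_window)) smooth_window <- traj$params$T_period
  e0 <- e0 / sqrt(sum(e0^2))
  bps <- traj$params$N_flag + 1
  nfr <- nrow(traj$q)
  px <- matrix(0, nfr, traj$nsw)
  py <- matrix(0, nfr, traj$nsw)
  for (s in seq_len(traj$nsw)) {
    cols <- 3 * bps * (s - 1) + seq_len(3 * bps)
    hx <- traj$q[, cols[1]]
    hy <- traj$q[, cols[2]]
    tx <- traj$q[, cols[3 * bps - 2]]
    ty <- traj$q[, cols[3 * bps - 1]]
    px[, s] <- hx - tx
    py[, s] <- hy - ty
  }
  dt_rec <- if (nfr > 1) traj$times[2] - traj$times[1] else traj$dt
  w <- max(1L, round(smooth_window / dt_rec))
  if (w > 1L && nfr > w) {
    px <- apply(px, 2, running_mean, w = w)
    py <- apply(py, 2, running_mean, w = w)
    tt <- running_mean(traj$times, w)
  } else {
    tt <- traj$times
  }
  nrm <- sqrt(px^2 + py^2)
  cx <- px / nrm
  cy <- py / nrm
  proj <- cx * e0[1] + cy * e0[2]
  data.frame(t = tt,
             S1 = rowMeans(proj),
             S2 = rowMeans(2 * proj^2 - 1))
}

# centered moving average, output length n - w + 1
running_mean <- function(x, w) {
  if (w <= 1) return(x)
  cs <- cumsum(c(0, x))
  (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
}

#' Low-pass filter a time series or field sequence
#'
#' Centered running time-average of width \code{window} (default eight mean
#' undulation periods: long enough to remove the beat-frequency content,
#' short against the suspension evolution). A linear operator; output
#' length is input length minus the window plus one.
#'
#' @param x numeric vector, matrix (rows = time), or list of equal-shape
#'   matrices (field snapshots).
#' @param window filter width in time units.
#' @param dt sampling interval of \code{x}.
#' @return filtered series of the same kind.
#' @export
lowpass_filter <- function(x, window, dt) {
  w <- round(window / dt)
  if (w < 2 || w > (if (is.list(x)) length(x) else NROW(x))) {
    stop("snapshot cadence too coarse for the requested window")
  }
  if (is.list(x)) {
    n <- length(x)
    out <- vector("list", n - w + 1)
    acc <- Reduce(`+`, x[1:w])
    out[[1]] <- acc / w
    for (i in seq_len(n - w)) {
      acc <- acc + x[[i + w]] - x[[i]]
      out[[i + 1]] <- acc / w
    }
    out
  } else if (is.matrix(x)) {
    apply(x, 2, running_mean, w = w)
  } else {
    running_mean(x, w)
  }
}

#' Fluid energy spectrum from midplane velocity snapshots
#'
#' For each snapshot of the in-plane velocity at the film midplane, computes
#' the 2D discrete Fourier transform normalized by the number of grid
#' points, the modal energy \code{(1/2) |u_hat|^2}, and averages over
#' wavenumber shells of width \code{2 pi / L} and over snapshots. With this
#' convention \code{sum_k S(k) n_modes(k)} equals the grid average of
#' \code{|u|^2/2} (Parseval).
#'
#' @param snapshots list of lists with matrices \code{ux}, \code{uy} (as
#'   returned by \code{\link{planar_midplane_field}}), or a single such
#'   list.
#' @param grid a \code{\link{grid_spec}} (or any list with \code{L} and
#'   \code{N_x}).
#' @return data frame with columns \code{k}, \code{S_k}, \code{sd},
#'   \code{n_modes}.
#' @export
energy_spectrum <- function(snapshots, grid) {
  if (!is.null(snapshots$ux)) snapshots <- list(snapshots)
  nx <- nrow(snapshots[[1]]$ux)
  ny <- ncol(snapshots[[1]]$ux)
  L <- grid$L
  kx <- fcm_freqs(nx, L)
  ky <- fcm_freqs(ny, grid$L_y %||% L)
  kmag <- sqrt(outer(kx^2, ky^2, "+"))
  dk <- 2 * pi / L
  shell <- pmax(1L, as.integer(round(kmag / dk)))
  nshell <- max(shell)
  per_snap <- matrix(0, length(snapshots), nshell)
  for (i in seq_along(snapshots)) {
    uxh <- stats::fft(snapshots[[i]]$ux) / (nx * ny)
    uyh <- stats::fft(snapshots[[i]]$uy) / (nx * ny)
    e <- 0.5 * (Mod(uxh)^2 + Mod(uyh)^2)
    m <- tapply(as.vector(e), factor(as.vector(shell), levels = 1:nshell),
                mean)
    m[is.na(m)] <- 0
    per_snap[i, ] <- m
  }
  nm <- tabulate(shell, nshell)
  data.frame(
    k = dk * seq_len(nshell),
    S_k = colMeans(per_snap),
    sd = if (nrow(per_snap) > 1) apply(per_snap, 2, stats::sd) else 0,
    n_modes = nm
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Centre-of-mass velocity spectrum
#'
#' Deposits each swimmer's centre-of-mass velocity on a 2D grid with a
#' Gaussian kernel of width \code{d/4} (weight-normalized; empty cells
#' zero) and computes the shell-averaged spectrum of the resulting field.
#' The flat plateau at sub-flagellum scales reflects the noise floor of the
#' field construction.
#'
#' @param X_cm n_swimmers x 2 positions.
#' @param U_cm n_swimmers x 2 velocities.
#' @param grid a \code{\link{grid_spec}} (box size source).
#' @param n_grid deposit grid resolution (default 128).
#' @param kernel_width Gaussian kernel width (default \code{d/4}; pass a
#'   number to override).
#' @param d swimmer length (needed when \code{kernel_width} is NULL).
#' @return data frame as in \code{\link{energy_spectrum}}.
#' @export
com_velocity_spectrum <- function(X_cm, U_cm, grid, n_grid = 128L,
                                  kernel_width = NULL, d = 70.1) {
  X_cm <- rbind(X_cm); U_cm <- rbind(U_cm)
  if (nrow(X_cm) == 0) stop("no swimmers")
  if (is.null(kernel_width)) kernel_width <- d / 4
  h <- grid$L / n_grid
  xg <- (0:(n_grid - 1)) * h
  wsum <- matrix(0, n_grid, n_grid)
  ux <- matrix(0, n_grid, n_grid)
  uy <- matrix(0, n_grid, n_grid)
  for (s in seq_len(nrow(X_cm))) {
    dxv <- xg - (X_cm[s, 1] %% grid$L)
    dxv <- dxv - grid$L * round(dxv / grid$L)
    dyv <- xg - (X_cm[s, 2] %% (grid$L_y %||% grid$L))
    dyv <- dyv - grid$L * round(dyv / grid$L)
    w <- outer(exp(-0.5 * dxv^2 / kernel_width^2),
               exp(-0.5 * dyv^2 / kernel_width^2))
    wsum <- wsum + w
    ux <- ux + w * U_cm[s, 1]
    uy <- uy + w * U_cm[s, 2]
  }
  nz <- wsum > 1e-12
  ux[nz] <- ux[nz] / wsum[nz]
  uy[nz] <- uy[nz] / wsum[nz]
  ux[!nz] <- 0
  uy[!nz] <- 0
  energy_spectrum(list(list(ux = ux, uy = uy)),
                  list(L = grid$L, L_y = grid$L_y %||% grid$L))
}

#' Pair displacement map
#'
#' For each initial offset, runs a two-swimmer simulation for
#' \code{n_periods} undulation periods and records the change of the
#' relative centre-of-mass position, in units of the swimmer length.
#'
#' @param offsets matrix or data frame with columns \code{x}, \code{y}
#'   (initial offsets of swimmer 2 relative to swimmer 1).
#' @param delta_phi imposed phase difference.
#' @param params,grid model and box.
#' @param n_periods run length (default 4).
#' @param backend mobility backend.
#' @param solver optional \code{\link{solver_settings}}.
#' @return data frame with the offsets and displacement components
#'   \code{ddx}, \code{ddy} (NA rows where a step failed).
#' @export
pair_displacement_map <- function(offsets, delta_phi, params, grid,
                                  n_periods = 4, backend = "fcm",
                                  solver = solver_settings()) {
  offsets <- as.data.frame(offsets)
  names(offsets)[1:2] <- c("x", "y")
  out <- cbind(offsets, ddx = NA_real_, ddy = NA_real_)
  for (i in seq_len(nrow(offsets))) {
    cfg <- suspension_config(N = 2, init_mode = "pair",
                             delta_phi = delta_phi,
                             pair_offset = c(offsets$x[i], offsets$y[i]),
                             grid = grid, params = params)
    res <- tryCatch({
      sys <- initialize_suspension(cfg, grid, params, backend = backend,
                                   solver = solver)
      tr <- run_film(sys, n_periods = n_periods, record_every = 5L)
      com <- swimmer_com(tr)
      nfr <- dim(com)[1]
      rel0 <- com[1, 2, ] - com[1, 1, ]
      rel1 <- com[nfr, 2, ] - com[nfr, 1, ]
      (rel1 - rel0) / params$d
    }, error = function(e) c(NA_real_, NA_real_))
    out$ddx[i] <- res[1]
    out$ddy[i] <- res[2]
  }
  out
}

#' Cluster size distribution
#'
#' Swimmers are linked when their minimum body--body distance is below
#' \code{distance_cut} and their mean orientations align beyond
#' \code{align_cut}; connected components of this graph are the clusters.
#' (A substitute metric for aggregation analysis; component sizes are
#' returned sorted decreasingly.)
#'
#' @param sys a \code{film_system}, or a list with \code{q}, \code{nsw},
#'   \code{params}, \code{grid}.
#' @param distance_cut link distance (default \code{3 b}).
#' @param align_cut minimum orientation dot product (default
#'   \code{cos(30 deg)}).
#' @return integer vector of cluster sizes, decreasing.
#' @export
cluster_sizes <- function(sys, distance_cut = NULL, align_cut = cos(pi / 6)) {
  params <- sys$params
  if (is.null(distance_cut)) distance_cut <- 3 * params$b
  N <- sys$nsw
  bps <- params$N_flag + 1
  L <- sys$grid$L
  Ly <- sys$grid$L_y
  pos <- lapply(seq_len(N), function(s) {
    cols <- 3 * bps * (s - 1) + seq_len(3 * bps)
    q <- sys$q[cols]
    cbind(q[seq(1, 3 * bps, by = 3)], q[seq(2, 3 * bps, by = 3)])
  })
  ori <- vapply(seq_len(N), function(s) {
    p <- pos[[s]]
    v <- p[1, ] - p[bps, ]
    v / sqrt(sum(v^2))
  }, numeric(2))
  parent <- seq_len(N)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      if (sum(ori[, i] * ori[, j]) <= align_cut) next
      dxm <- outer(pos[[i]][, 1], pos[[j]][, 1], "-")
      dym <- outer(pos[[i]][, 2], pos[[j]][, 2], "-")
      dxm <- dxm - L * round(dxm / L)
      dym <- dym - Ly * round(dym / Ly)
      if (min(dxm^2 + dym^2) < distance_cut^2) {
        parent[find(i)] <- find(j)
      }
    }
  }
  roots <- vapply(seq_len(N), find, 0L)
  sort(tabulate(match(roots, unique(roots))), decreasing = TRUE)
}

#' Period-resolved mean of a drive-locked time series
#'
#' The instantaneous force moments of a steady swimmer oscillate at the
#' undulation frequency with amplitudes orders of magnitude above their
#' period means, so a plain average leaks oscillation unless the window is
#' exactly commensurate. This helper regresses the series on a constant
#' plus harmonics of the drive period and returns the constant: the clean
#' period mean for any window covering at least two periods.
#'
#' @param y numeric series.
#' @param t sample times.
#' @param T_period drive period.
#' @param harmonics number of harmonics removed (default 8).
#' @return the period-mean of \code{y}.
#' @export
period_mean <- function(y, t, T_period, harmonics = 8L) {
  stopifnot(diff(range(t)) >= 1.5 * T_period)
  X <- cbind(1, do.call(cbind, lapply(seq_len(harmonics), function(k) {
    cbind(sin(2 * pi * k * t / T_period), cos(2 * pi * k * t / T_period))
  })))
  as.numeric(qr.solve(X, y)[1])
}
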