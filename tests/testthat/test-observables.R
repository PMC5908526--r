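# helper: minimal trajectory-like object from explicit per-frame data
toy_traj <- function(q_rows, F_rows, T_rows, times, params, nsw = 1) {
  nb <- length(T_rows[[1]])
  list(q = do.call(rbind, q_rows),
       F_fluid = do.call(rbind, F_rows),
       T_fluid = do.call(rbind, T_rows),
       times = times, nsw = nsw, params = params, dt = diff(times[1:2]),
       backend = "rft")
}

test_that("force moments reproduce two-body arithmetic and vanish for a
           point force at the centre of mass", {
  p <- ref_params()
  bps <- p$N_flag + 1
  # all bodies collapsed at the origin except two carrying the force pair
  q <- numeric(3 * bps)
  h <- 6
  q[seq(1, 3 * bps, 3)] <- 0
  q[1] <- h / 2   # body 1 at +h/2 x
  q[4] <- -h / 2  # body 2 at -h/2 x
  Fv <- numeric(2 * bps)
  # pusher: fluid pushed outward along the axis, so the forces ON the
  # fluid point away from the centre; the moments use the body loads
  Fv[1] <- 2.5    # +F x on fluid at +h/2
  Fv[3] <- -2.5
  Tv <- numeric(bps)
  # two frames to allow a swimming-direction estimate along +x
  q2 <- q; q2[seq(1, 3 * bps, 3)] <- q2[seq(1, 3 * bps, 3)] + 1e-3
  tr <- toy_traj(list(q, q2), list(Fv, Fv), list(Tv, Tv), c(0, 1), p)
  mo <- force_moments(tr)
  expect_equal(mo$G11[1], -2.5 * h, tolerance = 1e-9)
  expect_equal(mo$G22[1], 2.5 * h / 2 * 0, tolerance = 1e-9)
  expect_lt(abs(mo$G12[1]), 1e-9)
  expect_lt(abs(mo$A12[1]), 1e-9)
  # a single point force applied at the centre of mass: all moments zero
  qc <- numeric(3 * bps)
  Fc <- numeric(2 * bps)
  Fc[1:2] <- c(1, 2)
  trc <- toy_traj(list(qc, qc + 1e-3), list(Fc, Fc),
                  list(Tv, Tv), c(0, 1), p)
  moc <- force_moments(trc)
  expect_lt(max(abs(moc$G11), abs(moc$K111)), 1e-9)
})

test_that("normalization scales moments by F0 d and F0 d^2", {
  p <- ref_params()
  bps <- p$N_flag + 1
  q <- numeric(3 * bps)
  q[1] <- 3; q[4] <- -3
  Fv <- numeric(2 * bps)
  Fv[1] <- -1; Fv[3] <- 1
  Tv <- numeric(bps)
  tr <- toy_traj(list(q, q), list(Fv, Fv), list(Tv, Tv), c(0, 1), p)
  m_raw <- force_moments(tr)
  m_nrm <- force_moments(tr, F0 = 2)
  expect_equal(m_nrm$G11, m_raw$G11 / (2 * p$d), tolerance = 1e-12)
  expect_equal(m_nrm$K111, m_raw$K111 / (2 * p$d^2), tolerance = 1e-12)
})

test_that("crossover estimate follows the printed ratio arithmetic", {
  # max dipole 5.5 x |mean| = 5.775e-3, max quadrupole 7 x |mean| =
  # 1.625e-2: crossover ~ 2.8 swimmer lengths
  fake <- data.frame(G11 = c(-1.050e-3, 5.775e-3),
                     K111 = c(-2.321e-3, -1.6247e-2))
  r <- singularity_crossover(fake)
  expect_equal(r, 2.81, tolerance = 0.01)
  expect_equal(singularity_crossover(
    transform(fake, K111 = 2 * K111)), 2 * r, tolerance = 1e-12)
  expect_equal(singularity_crossover(transform(fake, K111 = 0)), 0)
  expect_error(singularity_crossover(transform(fake, G11 = 0)), "dipole")
})

test_that("order parameters hit their limiting values", {
  p <- ref_params()
  bps <- p$N_flag + 1
  mk_traj <- function(angles) {
    q <- numeric(0)
    for (a in angles) {
      sw <- straight_swimmer(p, c(0, 0), a)
      q <- c(q, sw$q)
    }
    list(q = matrix(q, 1), times = 0, nsw = length(angles), params = p,
         dt = p$dt)
  }
  # tangent +x means swimming -x: p_hat = head - tip = -x direction
  tr <- mk_traj(rep(0, 8))
  op <- order_parameters(tr, e0 = c(-1, 0), smooth_window = 0)
  expect_equal(op$S1, 1)
  expect_equal(op$S2, 1)
  # half +y, half -y (perpendicular): S1 = 0, S2 = -1
  tr2 <- mk_traj(rep(c(pi / 2, -pi / 2), 4))
  op2 <- order_parameters(tr2, e0 = c(-1, 0), smooth_window = 0)
  expect_equal(op2$S1, 0, tolerance = 1e-12)
  expect_equal(op2$S2, -1, tolerance = 1e-12)
  # isotropic: CLT bound 3/sqrt(N)
  set.seed(31)
  N <- 1e4
  ang <- stats::runif(N, 0, 2 * pi)
  proj <- cos(ang)
  S1 <- mean(proj)
  S2 <- mean(2 * proj^2 - 1)
  expect_lt(abs(S1), 3 / sqrt(N))
  expect_lt(abs(S2), 3 / sqrt(N))
})

test_that("the energy spectrum satisfies Parseval and localizes a single
           mode", {
  g <- list(L = 100, L_y = 100, N_x = 64)
  nx <- 64
  xg <- (0:(nx - 1)) * g$L / nx
  k0 <- 3 * 2 * pi / g$L
  A <- 1.7
  ux <- matrix(0, nx, nx)
  uy <- matrix(rep(A * sin(k0 * xg), nx), nx, nx)
  spec <- energy_spectrum(list(list(ux = ux, uy = uy)), g)
  # total energy per unit area: A^2/4
  expect_equal(sum(spec$S_k * spec$n_modes), A^2 / 4, tolerance = 1e-10)
  peak <- spec$k[which.max(spec$S_k)]
  expect_equal(peak, k0, tolerance = 1e-10)
  # zero field: zero spectrum
  s0 <- energy_spectrum(list(list(ux = ux * 0, uy = uy * 0)), g)
  expect_true(all(s0$S_k == 0))
  # Parseval on a random field
  set.seed(9)
  ur <- list(ux = matrix(rnorm(nx * nx), nx), uy = matrix(rnorm(nx * nx), nx))
  sr <- energy_spectrum(list(ur), g)
  expect_equal(sum(sr$S_k * sr$n_modes),
               mean(0.5 * (ur$ux^2 + ur$uy^2)), tolerance = 1e-8)
})

test_that("the low-pass filter is linear, preserves constants and damps
           the beat frequency", {
  p <- ref_params()
  dt <- p$T_period / 64
  tgrid <- seq(0, 40 * p$T_period, by = dt)
  w <- 8 * p$T_period
  cst <- lowpass_filter(rep(2.5, length(tgrid)), w, dt)
  expect_true(all(abs(cst - 2.5) < 1e-12))
  osc <- sin(p$omega_bar * tgrid)
  f <- lowpass_filter(osc, w, dt)
  # moving-average transfer function at 8 periods: |sinc(8)| ~ 0
  expect_lt(max(abs(f)), 0.05)
  a <- rnorm(length(tgrid)); b <- rnorm(length(tgrid))
  expect_equal(lowpass_filter(a + 2 * b, w, dt),
               lowpass_filter(a, w, dt) + 2 * lowpass_filter(b, w, dt),
               tolerance = 1e-12)
  expect_error(lowpass_filter(1:3, w, dt * 1e6), "cadence")
})

test_that("centre-of-mass velocity spectra behave for uniform motion and a
           single swimmer", {
  g <- list(L = 200, L_y = 200, N_x = 128)
  p <- ref_params()
  set.seed(13)
  X <- cbind(runif(20, 0, 200), runif(20, 0, 200))
  U <- matrix(rep(c(1, 0), each = 20), 20)
  sp <- com_velocity_spectrum(X, U, g, n_grid = 64, d = p$d)
  # uniform velocities: energy concentrated at the lowest shells
  low <- sum((sp$S_k * sp$n_modes)[1:4])
  tot <- sum(sp$S_k * sp$n_modes)
  expect_gt(low / tot, 0.5)
  # single swimmer: spectrum equals the transform of one deposited kernel
  sp1 <- com_velocity_spectrum(matrix(c(100, 100), 1),
                               matrix(c(1, 0), 1), g, n_grid = 64, d = p$d)
  expect_gt(sum(sp1$S_k), 0)
  expect_error(com_velocity_spectrum(matrix(0, 0, 2), matrix(0, 0, 2), g),
               "swimmers")
})

test_that("cluster detection matches a brute-force component search", {
  p <- ref_params()
  g <- grid_spec(512, 512, 64)
  set.seed(41)
  N <- 12
  sysq <- numeric(0)
  angs <- runif(N, 0, 2 * pi)
  xs <- runif(N, 0, g$L); ys <- runif(N, 0, g$L_y)
  for (i in seq_len(N)) {
    sysq <- c(sysq, straight_swimmer(p, c(xs[i], ys[i]), angs[i])$q)
  }
  sys <- list(q = sysq, nsw = N, params = p, grid = g)
  cs <- cluster_sizes(sys, distance_cut = 12, align_cut = cos(pi / 3))
  expect_equal(sum(cs), N)
  # brute-force oracle via igraph on the same adjacency
  skip_if_not_installed("igraph")
  bps <- p$N_flag + 1
  pos <- lapply(seq_len(N), function(s) {
    cols <- 3 * bps * (s - 1) + seq_len(3 * bps)
    q <- sysq[cols]
    cbind(q[seq(1, 3 * bps, by = 3)], q[seq(2, 3 * bps, by = 3)])
  })
  ori <- sapply(seq_len(N), function(s) {
    v <- pos[[s]][1, ] - pos[[s]][bps, ]
    v / sqrt(sum(v^2))
  })
  adj <- matrix(FALSE, N, N)
  for (i in 1:(N - 1)) for (j in (i + 1):N) {
    dxm <- outer(pos[[i]][, 1], pos[[j]][, 1], "-")
    dym <- outer(pos[[i]][, 2], pos[[j]][, 2], "-")
    dxm <- dxm - g$L * round(dxm / g$L)
    dym <- dym - g$L_y * round(dym / g$L_y)
    adj[i, j] <- adj[j, i] <-
      (min(dxm^2 + dym^2) < 144) && sum(ori[, i] * ori[, j]) > cos(pi / 3)
  }
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  ref <- sort(as.integer(table(igraph::components(gr)$membership)),
              decreasing = TRUE)
  expect_equal(as.integer(cs), ref)
  # all far apart: N singletons
  sep <- list(q = unlist(lapply(seq_len(4), function(i) {
    straight_swimmer(p, c(10, 100 * i - 50), 0)$q
  })), nsw = 4, params = p, grid = g)
  expect_equal(cluster_sizes(sep, distance_cut = 3), rep(1L, 4))
})

test_that("F0 normalization is linear in the mean speed", {
  p <- ref_params()
  tr <- list(params = p, backend = "rft")
  f1 <- f0_normalization(tr, U_mean = 0.05)
  f2 <- f0_normalization(tr, U_mean = 0.10)
  expect_equal(f2, 2 * f1, tolerance = 1e-12)
  expect_gt(f1, 0)
  expect_equal(f1, 6 * pi * p$eta * p$a_eff_trans * 0.05, tolerance = 1e-12)
  expect_error(f0_normalization(tr, U_mean = 0), "zero")
})

test_that("the in-phase pair displacement map is mirror symmetric", {
  p <- physical_params(steps_per_period = 100L)
  g <- grid_spec(256, 128, 64)
  offs <- data.frame(x = c(0, 0), y = c(0.35 * p$d, -0.35 * p$d))
  mp <- pair_displacement_map(offs, delta_phi = 0, params = p, grid = g,
                              n_periods = 1, backend = "fcm")
  expect_false(any(is.na(mp$ddx)))
  # the reflected offset is the same physical pair with the swimmer labels
  # exchanged, so the relative centre-of-mass displacement flips sign
  expect_equal(mp$ddx[1], -mp$ddx[2], tolerance = 1e-6)
  expect_equal(mp$ddy[1], -mp$ddy[2], tolerance = 1e-6)
})
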