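test_that("spreading conserves force and torque moments", {
  g <- small_grid()
  env <- fcm_envelopes(1)
  pos <- matrix(c(g$L / 2 + 0.13, g$L_y / 2 - 0.21, g$L_z / 2), 1)
  f <- fcm_spread(pos, matrix(c(1, 0, 0), 1), g, env$sigma)
  tot <- vapply(f$f, function(a) sum(a) * g$dx^3, 0)
  expect_equal(tot, c(1, 0, 0), tolerance = 1e-10)
  # pure torque: zero net force, first moment equals the torque
  ft <- fcm_spread(pos, matrix(0, 1, 3), g, env$sigma,
                   torque = matrix(c(0, 0, 1), 1),
                   sigma_dip = env$sigma_dip)
  tot_t <- vapply(ft$f, function(a) sum(a) * g$dx^3, 0)
  expect_lt(max(abs(tot_t)), 1e-8)
  xg <- (0:(g$N_x - 1)) * g$dx - pos[1]
  yg <- (0:(g$N_y - 1)) * g$dx - pos[2]
  RX <- array(rep(xg, times = g$N_y * g$N_z), dim(ft$f[[1]]))
  RY <- array(rep(rep(yg, each = g$N_x), times = g$N_z), dim(ft$f[[1]]))
  mom_z <- sum(RX * ft$f[[2]] - RY * ft$f[[1]]) * g$dx^3
  # the spectral rotlet (ik with Nyquist-zeroed derivatives) reproduces the
  # torque moment to discretization accuracy
  expect_equal(mom_z, 1, tolerance = 1e-5)
  # two equal and opposite forces: k = 0 mode vanishes
  pos2 <- rbind(c(10, 10, g$L_z / 2), c(14, 11, g$L_z / 2))
  F2 <- rbind(c(1, 2, 0), c(-1, -2, 0))
  f2 <- fcm_spread(pos2, F2, g, env$sigma)
  expect_lt(max(abs(vapply(f2$f, sum, 0))) * g$dx^3, 1e-12)
})

test_that("the spectral solve is divergence-free and matches a single-mode
           closed form", {
  g <- small_grid(32, 32, 32)
  k0 <- 2 * 2 * pi / g$L
  A <- 0.7
  xg <- (0:(g$N_x - 1)) * g$dx
  f <- list(array(0, c(g$N_x, g$N_y, g$N_z)),
            array(rep(A * sin(k0 * xg), times = g$N_y * g$N_z),
                  c(g$N_x, g$N_y, g$N_z)),
            array(0, c(g$N_x, g$N_y, g$N_z)))
  field <- structure(list(f = f, grid = g), class = "fluid_field")
  sol <- stokes_solve_periodic(field, g, eta = 1.3)
  expect_equal(sol$u[[2]], f[[2]] / (1.3 * k0^2), tolerance = 1e-10)
  expect_lt(max(abs(sol$u[[1]])), 1e-12)
  expect_lt(field_divergence(sol), 1e-10)
  # random zero-mean forcing is also projected divergence-free
  set.seed(5)
  fr <- lapply(1:3, function(i) {
    a <- array(rnorm(g$N_x * g$N_y * g$N_z), c(g$N_x, g$N_y, g$N_z))
    a - mean(a)
  })
  sol2 <- stokes_solve_periodic(
    structure(list(f = fr, grid = g), class = "fluid_field"), g, 1)
  expect_lt(field_divergence(sol2), 1e-10)
})

test_that("interpolation recovers uniform and rigid-rotation fields", {
  g <- small_grid(32, 32, 32)
  env <- fcm_envelopes(1)
  dims <- c(g$N_x, g$N_y, g$N_z)
  cfield <- structure(list(
    u = list(array(1.5, dims), array(-0.3, dims), array(0.2, dims)),
    grid = g), class = "fluid_field")
  pos <- rbind(c(5, 5, 5), c(7.7, 4.1, 6.2))
  out <- fcm_interpolate(cfield, pos, env$sigma)
  expect_equal(out$U, cbind(c(1.5, 1.5), c(-0.3, -0.3), c(0.2, 0.2)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # rigid rotation u = omega x r about the box centre: W ~ omega
  ctr <- c(g$L, g$L_y, g$L_z) / 2
  om <- c(0, 0, 0.4)
  xg <- (0:(g$N_x - 1)) * g$dx - ctr[1]
  yg <- (0:(g$N_y - 1)) * g$dx - ctr[2]
  RX <- array(rep(xg, times = g$N_y * g$N_z), dims)
  RY <- array(rep(rep(yg, each = g$N_x), times = g$N_z), dims)
  # window to vanish at the periodic boundary
  wfun <- exp(-(RX^2 + RY^2) / (2 * 4^2))
  rot <- structure(list(u = list(-om[3] * RY * wfun, om[3] * RX * wfun,
                                 array(0, dims)), grid = g),
                   class = "fluid_field")
  out2 <- fcm_interpolate(rot, matrix(ctr, 1), env$sigma,
                          sigma_dip = env$sigma_dip)
  expect_equal(out2$W[1, 3], om[3], tolerance = 0.05)
})

test_that("isolated FCM drag matches the periodic-corrected Stokes law", {
  g <- small_grid()
  a <- 1
  env <- fcm_envelopes(a)
  pos <- matrix(c(g$L / 2, g$L_y / 2, g$L_z / 2), 1)
  mob <- fcm_mobility(pos, matrix(c(1, 0, 0), 1), g, env$sigma)
  xi <- a / g$L
  U_h <- (1 - 2.837297 * xi + 4.19 * xi^3 - 27.4 * xi^6) / (6 * pi * a)
  expect_equal(mob$U[1, 1], U_h, tolerance = 0.01)
  # rotational drag: W = T / (8 pi eta a^3)
  mr <- fcm_mobility(pos, matrix(0, 1, 3), g, env$sigma,
                     torque = matrix(c(0, 0, 1), 1),
                     sigma_dip = env$sigma_dip)
  expect_equal(mr$W[1, 3], 1 / (8 * pi * a^3), tolerance = 0.02)
  # zero input, zero output
  m0 <- fcm_mobility(pos, matrix(0, 1, 3), g, env$sigma)
  expect_equal(max(abs(m0$U)), 0)
})

test_that("mobility action is linear, reciprocal and dissipative", {
  g <- small_grid(32, 32, 32)
  env <- fcm_envelopes(1)
  set.seed(23)
  n <- 4
  pos <- cbind(runif(n, 3, g$L - 3), runif(n, 3, g$L_y - 3),
               runif(n, 3, g$L_z - 3))
  F1 <- matrix(rnorm(3 * n), n)
  F2 <- matrix(rnorm(3 * n), n)
  al <- 0.7; be <- -1.3
  Ua <- fcm_mobility(pos, al * F1 + be * F2, g, env$sigma)$U
  U1 <- fcm_mobility(pos, F1, g, env$sigma)$U
  U2 <- fcm_mobility(pos, F2, g, env$sigma)$U
  expect_equal(Ua, al * U1 + be * U2, tolerance = 1e-10)
  # reciprocity <U1, F2> = <U2, F1>
  expect_equal(sum(U1 * F2), sum(U2 * F1), tolerance = 1e-10)
  # dissipativity: F . M F >= 0, including torques
  T1 <- matrix(rnorm(3 * n), n)
  out <- fcm_mobility(pos, F1, g, env$sigma, torque = T1,
                      sigma_dip = env$sigma_dip)
  expect_gte(sum(out$U * F1) + sum(out$W * T1), 0)
})

test_that("planar fast path reproduces the 3D route to machine precision", {
  p <- ref_params()
  gs <- grid_spec(64, 64, 64, dx = 19.40 / 64)
  be <- planar_backend(p, gs, nsw = 1, steric = FALSE)
  set.seed(42)
  nb <- 5
  pos2 <- cbind(runif(nb, 5, gs$L - 5), runif(nb, 5, gs$L_y - 5))
  F2 <- matrix(rnorm(2 * nb), nb)
  Tz <- rnorm(nb)
  cls <- c(1L, rep(0L, nb - 1))
  out_p <- planar_mobility(be, pos2, F2, Tz, cls)
  pos3 <- cbind(pos2, gs$L_z / 2)
  sig <- ifelse(cls == 1, fcm_envelopes(p$a_eff_trans)$sigma,
                fcm_envelopes(p$b)$sigma)
  sigd <- ifelse(cls == 1, fcm_envelopes(p$a_eff_rot)$sigma_dip,
                 fcm_envelopes(p$b)$sigma_dip)
  field <- fcm_spread(pos3, cbind(F2, 0), gs, sig,
                      torque = cbind(0, 0, Tz), sigma_dip = sigd)
  field <- stokes_solve_periodic(field, gs, p$eta)
  out3 <- fcm_interpolate(field, pos3, sig, sigma_dip = sigd)
  expect_lt(max(abs(cbind(out_p$U, 0) - out3$U)), 1e-12)
  expect_lt(max(abs(out_p$Wz - out3$W[, 3])), 1e-12)
})

test_that("near-field velocity differences follow the Oseen solution", {
  # cubic-lattice images have zero flow gradient at the source by symmetry,
  # so differences of on-axis velocities at r1, r2 << L cancel the periodic
  # background to O(r^2/L^3)
  g <- grid_spec(128, 128, 128, dx = 0.55)
  a <- 1.5
  env <- fcm_envelopes(a)
  ctr <- c(g$L, g$L_y, g$L_z) / 2
  probes <- rbind(ctr, ctr + c(5, 0, 0), ctr + c(10, 0, 0))
  field <- fcm_spread(matrix(ctr, 1), matrix(c(1, 0, 0), 1), g, env$sigma)
  field <- stokes_solve_periodic(field, g, 1)
  # pointwise sampling via a narrow interpolation envelope is unnecessary:
  # read grid values on-axis
  ix <- round(probes[, 1] / g$dx) + 1
  iy <- round(probes[1, 2] / g$dx) + 1
  iz <- round(probes[1, 3] / g$dx) + 1
  u_ax <- field$u[[1]][ix, iy, iz]
  oseen <- function(r) 2 / (8 * pi * r) # on-axis: (1 + rhat rhat)/(8 pi r)
  diff_num <- u_ax[2] - u_ax[3]
  diff_th <- oseen(5) - oseen(10)
  expect_equal(diff_num, diff_th, tolerance = 0.02)
})

test_that("thin-film in-plane flow is longer ranged than the bulk Oseen
           decay", {
  p <- ref_params()
  g <- grid_spec(256, 256, 64, dx = 19.40 / 64)
  be <- planar_backend(p, g, nsw = 1, steric = FALSE)
  ctr <- c(g$L / 2, g$L_y / 2)
  # an in-plane force dipole (force-free system) probed along y
  dpos <- rbind(ctr + c(2, 0), ctr - c(2, 0))
  Fd <- rbind(c(1, 0), c(-1, 0))
  fld <- planar_midplane_field(be, dpos, Fd, c(0, 0), c(0L, 0L))
  r1 <- g$L_z          # just beyond the film-thickness crossover
  r2 <- 1.8 * g$L_z    # still inside the quarter box
  iy1 <- round((ctr[2] + r1) / g$dx) + 1
  iy2 <- round((ctr[2] + r2) / g$dx) + 1
  ixc <- round(ctr[1] / g$dx) + 1
  u1 <- abs(fld$ux[ixc, iy1])
  u2 <- abs(fld$ux[ixc, iy2])
  # a bulk dipole flow decays ~ 1/r^2; the film decay is slower
  expect_gt(u2 / u1, (r1 / r2)^2)
})

test_that("solitary swimmer speed is insensitive to grid refinement", {
  # dx halved relative to the film default: speed change within 1%
  p <- physical_params(steps_per_period = 100L)
  run_speed <- function(g) {
    cfg <- suspension_config(N = 1, init_mode = "solitary",
                            grid = g, params = p)
    sys <- initialize_suspension(cfg, g, p, backend = "fcm")
    sys$solver$jac_refresh <- 300L
    tr <- run_film(sys, n_periods = 2, record_every = 4L)
    mean(mean_swimming_speed(tr))
  }
  s1 <- run_speed(grid_spec(256, 256, 64, dx = 19.40 / 64))
  s2 <- run_speed(grid_spec(512, 512, 128, dx = 19.40 / 128))
  expect_equal(s2 / s1, 1, tolerance = 0.01)
})

test_that("the 3D slice solver matches the reference route for off-plane
           forcing", {
  g <- grid_spec(32, 32, 32, dx = 0.5)
  sigma <- 0.8
  set.seed(77)
  nf <- 6
  pos <- cbind(runif(nf, 6, g$L - 6), runif(nf, 6, g$L_y - 6),
               runif(nf, 6, g$L_z - 6))
  F <- cbind(rnorm(nf), rnorm(nf), 0)
  F[, 1] <- F[, 1] - mean(F[, 1])
  F[, 2] <- F[, 2] - mean(F[, 2])
  out <- spermfilm:::.film_slice_cpp(g$N_x, g$N_y, g$N_z, g$dx, 1, sigma,
                                     pos, F)
  field <- fcm_spread(pos, F, g, sigma)
  field <- stokes_solve_periodic(field, g, 1)
  iz <- g$N_z / 2 + 1
  # the two routes use equivalent but differently-centred spreading
  # windows; agreement is limited by the 7-sigma truncation tail
  expect_equal(out$ux, field$u[[1]][, , iz], tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_equal(out$uy, field$u[[2]][, , iz], tolerance = 1e-7,
               ignore_attr = TRUE)
})
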