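test_that("preferred curvature wave has the documented structure", {
  p <- ref_params()
  expect_equal(preferred_curvature(0, Phi = 0, phi = 0, params = p), 0)
  expect_equal(preferred_curvature(p$l, Phi = 1.3, phi = 0.4, params = p), 0)
  s <- seq(0, p$l, length.out = 200)
  for (ph in c(0, 1, 2.5)) {
    k <- preferred_curvature(s, Phi = ph, phi = 0.3, params = p)
    expect_true(all(abs(k) <= p$K0 + 1e-15))
  }
  expect_error(preferred_curvature(-0.1, params = p), "arclength")
  expect_error(preferred_curvature(p$l + 1, params = p), "arclength")
  # amplitude envelope: flat until the tip ramp, then linear to zero
  expect_equal(tip_ramp(0.5 * p$l, p), 1)
  expect_equal(tip_ramp(p$l, p), 0)
  mid <- (1 - p$gamma_tip / 2) * p$l
  expect_equal(tip_ramp(mid, p), 0.5, tolerance = 1e-12)
})

test_that("bending torques vanish for straight shapes and match the
           continuum moment on a shallow arc", {
  p <- ref_params()
  sw <- straight_swimmer(p)
  st <- state_from_q(sw$q, p)
  tb <- bending_torques(st, p)
  expect_lt(max(abs(tb)), 1e-12)
  # discrete circular arc with curvature << 1/ds: joint torque ~ K_B kappa
  kap <- 1e-3
  thetas <- kap * (seq_len(p$N_flag) - 0.5) * p$ds
  sw2 <- swimmer_from_angles(p, thetas = thetas)
  st2 <- state_from_q(sw2$q, p)
  tb2 <- bending_torques(st2, p)
  expect_equal(tb2[, 3], rep(p$K_B * kap, p$N_flag - 1),
               tolerance = (kap * p$ds)^2 + 1e-9)
})

test_that("joint torques are the negative gradient of the driven elastic
           energy", {
  p <- ref_params()
  set.seed(7)
  thetas <- cumsum(c(0.3, rnorm(p$N_flag - 1, 0, 0.15)))
  Phi <- 1.1
  phi <- 0.5
  sw <- swimmer_from_angles(p, thetas = thetas, phi = phi)
  st <- state_from_q(sw$q, p, phi = phi, Phi = Phi)
  tb <- bending_torques(st, p)
  td <- driving_torques(st, params = p)
  # torque on segment j from joint j is +(tb+td); on j+1 the negative
  tot <- numeric(p$N_flag)
  for (j in seq_len(p$N_flag - 1)) {
    tot[j] <- tot[j] + tb[j, 3] + td[j, 3]
    tot[j + 1] <- tot[j + 1] - tb[j, 3] - td[j, 3]
  }
  h <- 1e-6
  for (j in c(1, 5, 17, p$N_flag)) {
    tp <- thetas; tp[j] <- tp[j] + h
    tm <- thetas; tm[j] <- tm[j] - h
    dE <- (driven_elastic_energy(tp, phi, Phi, p) -
           driven_elastic_energy(tm, phi, Phi, p)) / (2 * h)
    expect_equal(tot[j], -dE, tolerance = 1e-4)
  }
  # internal actuation: the paired joint torques cancel over the swimmer
  expect_lt(abs(sum(tot)), 1e-10 * max(abs(tot)))
})

test_that("driving torques at a straight configuration equal the preferred
           moment K_B kappa0", {
  p <- ref_params()
  sw <- straight_swimmer(p)
  st <- state_from_q(sw$q, p, Phi = 0.9)
  td <- driving_torques(st, params = p)
  sj <- seq_len(p$N_flag - 1) * p$ds
  expect_equal(td[, 3],
               -p$K_B * preferred_curvature(sj, Phi = 0.9, params = p),
               tolerance = 1e-12)
})

test_that("a state at the preferred curvature is a joint equilibrium", {
  p <- ref_params()
  Phi <- 0.7
  sj <- seq_len(p$N_flag - 1) * p$ds
  k0 <- preferred_curvature(sj, Phi = Phi, params = p)
  # build angles whose discrete curvature sin(dtheta)/ds equals kappa0
  dth <- asin(k0 * p$ds)
  thetas <- cumsum(c(0.2, dth))
  sw <- swimmer_from_angles(p, thetas = thetas)
  st <- state_from_q(sw$q, p, Phi = Phi)
  tb <- bending_torques(st, p)
  td <- driving_torques(st, params = p)
  expect_lt(max(abs(tb[, 3] + td[, 3])), 1e-10 * p$K_B * p$K0)
})

test_that("constraint residuals detect stretch and vanish for admissible
           states", {
  p <- ref_params()
  sw <- straight_swimmer(p, head_pos = c(3, 4), theta = 0.3)
  st <- state_from_q(sw$q, p)
  res <- constraint_residuals(st, p)
  expect_lt(max(abs(res$joints)), 1e-12)
  expect_lt(max(abs(res$head)), 1e-12)
  expect_lt(abs(res$clamp), 1e-12)
  # stretch joint n by delta along the tangent
  delta <- 0.05
  q2 <- sw$q
  n_move <- 10 # segments n_move..N shift by delta
  for (j in n_move:p$N_flag) {
    q2[3 * j + 1] <- q2[3 * j + 1] + delta * cos(0.3)
    q2[3 * j + 2] <- q2[3 * j + 2] + delta * sin(0.3)
  }
  res2 <- constraint_residuals(state_from_q(q2, p), p)
  nrm <- sqrt(rowSums(res2$joints^2))
  expect_equal(nrm[n_move - 1], delta, tolerance = 1e-12)
  expect_lt(max(nrm[-(n_move - 1)]), 1e-12)
})

test_that("constraint residuals match a brute-force evaluation on random
           states", {
  p <- ref_params()
  set.seed(11)
  q <- straight_swimmer(p)$q + rnorm(3 * (p$N_flag + 1), 0, 0.1)
  st <- state_from_q(q, p)
  res <- constraint_residuals(st, p)
  for (j in c(1, 7, p$N_flag - 1)) {
    yj <- q[(3 * j + 1):(3 * j + 2)]
    yj1 <- q[(3 * (j + 1) + 1):(3 * (j + 1) + 2)]
    tj <- c(cos(q[3 * j + 3]), sin(q[3 * j + 3]))
    tj1 <- c(cos(q[3 * (j + 1) + 3]), sin(q[3 * (j + 1) + 3]))
    expect_equal(res$joints[j, 1:2], yj1 - yj - (p$ds / 2) * (tj + tj1),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("constraint forces are the virtual-work conjugates of the
           residuals", {
  p <- ref_params()
  set.seed(13)
  sw <- straight_swimmer(p)
  q <- sw$q + rnorm(length(sw$q), 0, 0.05)
  nlam <- 3 + 2 * (p$N_flag - 1)
  lam <- rnorm(nlam)
  model <- spermfilm:::model_desc(p, 1, 0, NULL, steric = FALSE)
  out <- spermfilm:::.forces_cpp(model, q, lam, 0)
  # -d(lambda . g)/dq by central differences (forces and torques together)
  h <- 1e-6
  for (ci in c(1, 2, 3, 10, 45, 88)) {
    qp <- q; qp[ci] <- qp[ci] + h
    qm <- q; qm[ci] <- qm[ci] - h
    gp <- spermfilm:::.forces_cpp(model, qp, lam, 0)$g
    gm <- spermfilm:::.forces_cpp(model, qm, lam, 0)$g
    grad <- sum(lam * (gp - gm)) / (2 * h)
    bi <- (ci - 1) %/% 3 + 1
    comp <- (ci - 1) %% 3 + 1
    # constraint part only: strip elastic torques by zeroing K_B and K0
    val <- if (comp == 3) out$Tz[bi] else out$F[2 * (bi - 1) + comp]
    if (comp == 3) {
      model0 <- model; model0$KB <- 0
      val <- spermfilm:::.forces_cpp(model0, q, lam, 0)$Tz[bi]
    }
    expect_equal(val, -grad, tolerance = 1e-5 * max(1, abs(grad)))
  }
})

test_that("the assembled non-hydrodynamic force system is self-equilibrated", {
  # the zero-net-torque identity holds on the constraint manifold (the
  # multiplier forces do no net work only for admissible configurations),
  # so build a random admissible shape
  p <- ref_params()
  set.seed(17)
  thetas <- cumsum(c(0.4, rnorm(p$N_flag - 1, 0, 0.2)))
  sw <- swimmer_from_angles(p, c(2, -1), thetas)
  q <- sw$q
  nlam <- 3 + 2 * (p$N_flag - 1)
  lam <- rnorm(nlam)
  model <- spermfilm:::model_desc(p, 1, 0.4, NULL, steric = FALSE)
  out <- spermfilm:::.forces_cpp(model, q, lam, 1.2)
  Fm <- matrix(out$F, ncol = 2, byrow = TRUE)
  expect_lt(max(abs(colSums(Fm))), 1e-10 * max(1, max(abs(Fm))))
  # net torque about the origin: sum(Tz) + sum(r x F)
  xs <- q[seq(1, length(q), 3)]
  ys <- q[seq(2, length(q), 3)]
  net_torque <- sum(out$Tz) + sum(xs * Fm[, 2] - ys * Fm[, 1])
  expect_lt(abs(net_torque), 1e-9 * max(1, sum(abs(out$Tz))))
})

test_that("segment constraint-force identities hold", {
  p <- ref_params()
  set.seed(19)
  sw <- straight_swimmer(p)
  st <- state_from_q(sw$q, p)
  Lambda <- matrix(rnorm(3 * (p$N_flag - 1)), ncol = 3)
  Lambda[, 3] <- 0
  cf <- constraint_forces(st, Lambda, p)
  expect_lt(max(abs(colSums(cf$F))), 1e-12)
  n <- 12
  expect_equal(cf$F[n, ], Lambda[n, ] - Lambda[n - 1, ], tolerance = 1e-12)
  # single nonzero multiplier affects only the two adjacent segments
  L2 <- matrix(0, p$N_flag - 1, 3)
  L2[5, ] <- c(1, 2, 0)
  cf2 <- constraint_forces(st, L2, p)
  expect_equal(cf2$F[5, ], c(1, 2, 0))
  expect_equal(cf2$F[6, ], -c(1, 2, 0))
  expect_lt(max(abs(cf2$F[-c(5, 6), ])), 1e-14)
})
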