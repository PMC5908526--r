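test_that("initialization is deterministic and respects the placement
           contracts", {
  p <- ref_params()
  g <- grid_spec(256, 256, 64)
  cfg <- suspension_config(N = 6, init_mode = "polar", grid = g, params = p,
                           phase_seed = 5, placement_seed = 9)
  s1 <- initialize_suspension(cfg, g, p, backend = "rft")
  s2 <- initialize_suspension(cfg, g, p, backend = "rft")
  expect_identical(s1$q, s2$q)
  expect_identical(s1$phases, s2$phases)
  # polar start: all tangents along +x (swimming -x), order parameter 1
  th <- s1$q[seq(3, length(s1$q), by = 3)]
  expect_true(all(th == 0))
  traj0 <- list(q = matrix(s1$q, 1), times = 0, nsw = 6, params = p,
                dt = p$dt)
  op <- order_parameters(traj0, e0 = c(-1, 0), smooth_window = 0)
  expect_equal(op$S1, 1, tolerance = 1e-12)
  expect_equal(op$S2, 1, tolerance = 1e-12)
  # no steric overlap at start
  st <- steric_forces(s1)
  expect_lt(max(abs(st)), 1e-12)
})

test_that("isotropic placement avoids overlaps and respects the seed", {
  p <- ref_params()
  g <- grid_spec(512, 512, 64)
  cfg <- suspension_config(N = 5, init_mode = "isotropic", grid = g,
                           params = p, placement_seed = 21)
  s1 <- initialize_suspension(cfg, g, p, backend = "rft")
  s2 <- initialize_suspension(cfg, g, p, backend = "rft")
  expect_identical(s1$q, s2$q)
  expect_lt(max(abs(steric_forces(s1))), 1e-12)
})

test_that("lognormal frequency draws match the prescribed moments", {
  p <- physical_params(sigma_rel = 0.2)
  dr <- sample_frequencies(p, 1e6, seed = 4)
  m <- p$omega_bar
  s <- p$sigma_omega
  se_mean <- s / sqrt(1e6)
  expect_lt(abs(mean(dr) - m), 3 * se_mean)
  # sd standard error for lognormal, approximate via fourth moment
  se_sd <- stats::sd((dr - mean(dr))^2) / (2 * s * sqrt(1e6))
  expect_lt(abs(stats::sd(dr) - s), 3 * se_sd)
  expect_true(all(dr > 0))
  # zero spread: all draws exactly the mean
  p0 <- physical_params(sigma_rel = 0)
  expect_identical(sample_frequencies(p0, 10, seed = 1), rep(p0$omega_bar, 10))
  # reproducibility
  expect_identical(sample_frequencies(p, 5, seed = 11),
                   sample_frequencies(p, 5, seed = 11))
})

test_that("steric forces obey the third law and the contact magnitude", {
  p <- ref_params()
  g <- grid_spec(256, 256, 64)
  # two parallel straight swimmers close enough to touch laterally
  cfg <- suspension_config(N = 2, init_mode = "pair",
                           pair_offset = c(0, 2 * p$b * 1.05),
                           grid = g, params = p)
  sys <- initialize_suspension(cfg, g, p, backend = "rft", steric = TRUE)
  Fm <- steric_forces(sys)
  expect_gt(max(abs(Fm)), 0)
  expect_lt(max(abs(colSums(Fm))), 1e-10 * max(abs(Fm)))
  # contact magnitude between two isolated segments equals F_S
  model <- spermfilm:::model_desc(p, 2, c(0, 0), g, steric = TRUE)
  bps <- p$N_flag + 1
  q <- numeric(2 * 3 * bps)
  # place the two swimmers far apart, then move one segment pair to contact
  sw1 <- straight_swimmer(p, c(30, 60))
  sw2 <- straight_swimmer(p, c(30, 120))
  q <- c(sw1$q, sw2$q)
  # segment 5 of swimmer 2 exactly at contact distance 2b from segment 5
  # of swimmer 1, displaced in y
  i1 <- 3 * 5 + 1
  i2 <- 3 * bps + 3 * 5 + 1
  q[i2] <- q[i1]
  q[i2 + 1] <- q[i1 + 1] + 2 * p$b
  out <- spermfilm:::.forces_cpp(model, q, numeric(2 * (3 + 2 * (p$N_flag - 1))),
                                 c(0, 0))
  Fm2 <- matrix(out$F, ncol = 2, byrow = TRUE)
  fmag <- sqrt(sum(Fm2[bps + 6, ]^2))
  # neighbouring segments sit beyond the cutoff, so the contact force is
  # exactly F_S
  expect_equal(fmag, p$F_S, tolerance = 1e-10)
  expect_equal(p$F_S, 15 * pi * p$d, tolerance = 1e-12)
  # beyond the cutoff: zero
  q[i2 + 1] <- q[i1 + 1] + 2.5 * p$b
  out2 <- spermfilm:::.forces_cpp(model, q,
                                  numeric(2 * (3 + 2 * (p$N_flag - 1))),
                                  c(0, 0))
  Fm3 <- matrix(out2$F, ncol = 2, byrow = TRUE)
  expect_lt(max(abs(Fm3[bps + 6, ])), 1e-12)
})

test_that("frequency redraws keep the integrated phase continuous", {
  p <- physical_params(sigma_rel = 0.2, steps_per_period = 60L)
  g <- small_grid(64, 64, 64)
  cfg <- suspension_config(N = 1, init_mode = "solitary", grid = g,
                           params = p, freq_seed = 3)
  sys <- initialize_suspension(cfg, g, p, backend = "rft")
  Phis <- times <- omegas <- numeric(130)
  for (i in seq_len(130)) {
    om_before <- sys$omega_cur
    k_next <- floor((sys$time + sys$solver$dt) / p$T_period + 1e-12)
    if (k_next > sys$freq_epoch) {
      sys$freq_epoch <- k_next
      sys$omega_cur <- sample_frequencies(p, 1, seed = sys$freq_seed + k_next)
    }
    sys <- film_step(sys)
    Phis[i] <- sys$Phi
    omegas[i] <- sys$omega_cur
    times[i] <- sys$time
  }
  # Phi is continuous: the per-step change is exactly -omega_cur dt
  dPhi <- diff(c(0, Phis))
  expect_equal(dPhi, -omegas * sys$solver$dt, tolerance = 1e-12)
  # at least one redraw happened over > 2 periods
  expect_gt(length(unique(round(omegas, 12))), 1)
})
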