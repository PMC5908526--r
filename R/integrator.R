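# Implicit time integration: BDF2 in the body configurations with the
# constraint residuals appended, solved each step by a matrix-free
# ("bad") Broyden iteration. The inverse-Jacobian approximation is seeded
# with per-swimmer finite-difference blocks of the residual under the cheap
# local-drag closure and carried across steps as a limited-memory sequence
# of rank-one updates.

#' Residual of one implicit step
#'
#' Stacks (i) the BDF2 kinematic mismatch
#' \code{X - (4 q_prev - q_prev2)/3 - (2 dt/3) V(X)} (backward Euler on the
#' bootstrap step), where \code{V} is the mobility solve of all
#' non-hydrodynamic forces at the trial configuration, with (ii) the
#' constraint residuals at the trial configuration. A zero residual is an
#' accepted step. Midplane restriction is built into the planar
#' representation: bodies carry no out-of-plane degrees of freedom, so
#' \code{U_z = 0} and in-plane spin components vanish identically.
#'
#' @param sys a \code{film_system}.
#' @param X trial state: configurations then multipliers.
#' @param Phi_new integrated drive phases at the new time.
#' @param scheme 2 for BDF2, 1 for backward Euler.
#' @param diagnostics also return forces on the fluid and body velocities.
#' @return numeric residual vector (or list when \code{diagnostics}).
#' @export
bdf2_residual <- function(sys, X, Phi_new = sys$Phi, scheme = 2L,
                          diagnostics = FALSE) {
  q1 <- sys$q
  q2 <- if (is.null(sys$q_old)) sys$q else sys$q_old
  .residual_cpp(sys$ctx, X, q1, q2, Phi_new, sys$solver$dt,
                as.integer(scheme), sys$backend == "fcm", sys$rft,
                diagnostics)
}

#' Broyden's method for a nonlinear system
#'
#' Matrix-free "bad" Broyden iteration on the inverse Jacobian,
#' identity-seeded unless \code{B0_apply} is supplied, with a restart after
#' \code{restart_every} stored updates and simple step halving when the
#' residual norm grows.
#'
#' @param residual_fn function of the state vector returning the residual.
#' @param x0 initial guess.
#' @param tol stopping tolerance on the residual 2-norm.
#' @param maxit iteration cap.
#' @param B0_apply optional function applying the seed inverse Jacobian.
#' @param memory optional environment carrying stored updates across calls.
#' @param restart_every drop stored updates beyond this count.
#' @param step_max trust bound on the largest monitored component of a
#'   single quasi-Newton step (guards against runaway steps through stiff
#'   contact events; \code{Inf} disables it).
#' @param step_max_idx indices of the components the bound is measured on
#'   (default: all); the whole step is rescaled, preserving its direction.
#' @return list with \code{x}, \code{fval}, \code{iterations},
#'   \code{converged}.
#' @export
broyden_solve <- function(residual_fn, x0, tol = 1e-10, maxit = 100L,
                          B0_apply = NULL, memory = NULL,
                          restart_every = 250L, step_max = Inf,
                          step_max_idx = NULL) {
  if (is.null(memory)) {
    memory <- new.env(parent = emptyenv())
  }
  if (is.null(memory$U)) {
    memory$U <- list()
    memory$V <- list()
  }
  apply_B <- function(f) {
    out <- B0_apply(f)
    if (length(memory$U)) {
      for (i in seq_along(memory$U)) {
        out <- out + memory$U[[i]] * sum(memory$V[[i]] * f)
      }
    }
    out
  }
  x <- x0
  f <- residual_fn(x)
  nf <- sqrt(sum(f * f))
  if (is.null(B0_apply)) {
    # identity seed scaled by the initial residual norm (keeps the first
    # step O(1) for poorly scaled problems)
    s0 <- max(1, nf)
    B0_apply <- function(f) f / s0
  }
  it <- 0L
  nf0 <- nf
  x_best <- x
  f_best <- f
  nf_best <- nf
  while (nf > tol && it < maxit) {
    it <- it + 1L
    dx_full <- -apply_B(f)
    smax <- if (is.null(step_max_idx)) max(abs(dx_full)) else
      max(abs(dx_full[step_max_idx]))
    if (is.finite(step_max) && smax > step_max) {
      dx_full <- dx_full * (step_max / smax)
    }
    alpha <- 1
    repeat {
      x_new <- x + alpha * dx_full
      f_new <- residual_fn(x_new)
      nf_new <- sqrt(sum(f_new * f_new))
      if (nf_new <= 1.2 * nf || alpha <= 1 / 32) break
      alpha <- alpha / 2
    }
    if (nf_new > 1e3 * max(nf0, tol)) {
      # runaway iteration: bail out and let the caller reseed from the
      # best iterate
      break
    }
    dx <- x_new - x
    df <- f_new - f
    dd <- sum(df * df)
    if (dd > 0) {
      if (length(memory$U) >= restart_every) {
        # slide the window: keep the most recent half of the updates
        keep <- (length(memory$U) %/% 2 + 1):length(memory$U)
        memory$U <- memory$U[keep]
        memory$V <- memory$V[keep]
      }
      u <- (dx - apply_B(df)) / dd
      memory$U[[length(memory$U) + 1]] <- u
      memory$V[[length(memory$V) + 1]] <- df
    }
    x <- x_new
    f <- f_new
    nf <- nf_new
    if (nf < nf_best) {
      x_best <- x
      f_best <- f
      nf_best <- nf
    }
  }
  if (nf_best < nf) {
    x <- x_best
    f <- f_best
    nf <- nf_best
  }
  list(x = x, fval = f, iterations = it, converged = nf <= tol,
       resnorm = nf)
}

# full dense inverse finite-difference Jacobian of the actual-backend
# residual; affordable for small systems, refreshed sparingly
build_full_precond <- function(sys, X, Phi_new, scheme) {
  n <- length(X)
  r0 <- bdf2_residual(sys, X, Phi_new, scheme)
  J <- matrix(0, n, n)
  nq <- length(sys$q)
  for (c in seq_len(n)) {
    h <- if (c <= nq) 1e-6 * max(1, sys$params$ds) else 1e-6 * sys$params$K_B
    Xp <- X
    Xp[c] <- Xp[c] + h
    J[, c] <- (bdf2_residual(sys, Xp, Phi_new, scheme) - r0) / h
  }
  Binv <- tryCatch(solve(J), error = function(e) NULL)
  if (is.null(Binv)) {
    Binv <- solve(J + diag(1e-8 * max(abs(diag(J))), n))
  }
  function(f) as.numeric(Binv %*% f)
}

# per-swimmer block preconditioner: inverse finite-difference Jacobian of
# the RFT-closure residual, applied blockwise
build_block_precond <- function(sys, X, Phi_new, scheme) {
  blocks <- .rft_jac_blocks(sys$ctx, X, sys$q,
                            if (is.null(sys$q_old)) sys$q else sys$q_old,
                            Phi_new, sys$solver$dt, as.integer(scheme),
                            sys$rft)
  inv <- lapply(blocks, function(J) {
    out <- tryCatch(solve(J), error = function(e) NULL)
    if (is.null(out)) {
      out <- solve(J + diag(1e-8 * max(abs(diag(J))), nrow(J)))
    }
    out
  })
  idx <- sys$block_index
  function(f) {
    out <- numeric(length(f))
    for (s in seq_along(inv)) {
      out[idx[[s]]] <- inv[[s]] %*% f[idx[[s]]]
    }
    out
  }
}

block_index_list <- function(nsw, nseg) {
  bps <- nseg + 1
  nlam <- 3 + 2 * (nseg - 1)
  nq <- 3 * bps * nsw
  lapply(seq_len(nsw), function(s) {
    c((3 * bps * (s - 1) + 1):(3 * bps * s),
      (nq + nlam * (s - 1) + 1):(nq + nlam * s))
  })
}

#' Advance the system by one time step
#'
#' One accepted BDF2/Broyden step (backward Euler on the first step to build
#' the two-step history). The drive phase advances as
#' \code{dPhi = -omega_cur dt}. Step failure (no convergence within the
#' iteration cap) aborts with a diagnostic rather than accepting the state.
#'
#' @param sys a \code{film_system}.
#' @return the advanced system; the last step's solver diagnostics are in
#'   \code{sys$last_diag} and the converged fluid forces in
#'   \code{sys$last_forces}.
#' @export
film_step <- function(sys) {
  dt <- sys$solver$dt
  scheme <- if (sys$step_count == 0L) 1L else 2L
  Phi_new <- sys$Phi - sys$omega_cur * dt
  X0 <- c(if (is.null(sys$q_old)) sys$q else 2 * sys$q - sys$q_old, sys$lam)
  ndof <- length(X0)
  tol <- sys$solver$broyden_tol * sqrt(ndof)

  refresh <- is.null(sys$bro$B0) ||
    sys$step_count %% sys$solver$jac_refresh == 0L ||
    isTRUE(sys$bro$force_refresh)
  if (refresh) {
    # the full Jacobian captures cross-swimmer steric stiffness that the
    # per-swimmer blocks cannot; affordable up to a handful of swimmers
    full <- sys$nsw <= 6
    sys$bro$B0 <- if (full) {
      build_full_precond(sys, X0, Phi_new, scheme)
    } else {
      build_block_precond(sys, X0, Phi_new, scheme)
    }
    sys$bro$U <- list()
    sys$bro$V <- list()
    sys$bro$force_refresh <- FALSE
  }

  res_fn <- function(X) {
    bdf2_residual(sys, X, Phi_new, scheme, diagnostics = FALSE)
  }
  step_cap <- sys$params$ds
  q_idx <- seq_len(length(sys$q))
  sol <- broyden_solve(res_fn, X0, tol = tol,
                       maxit = sys$solver$broyden_maxit,
                       B0_apply = sys$bro$B0, memory = sys$bro,
                       step_max = step_cap, step_max_idx = q_idx)
  if (!sol$converged) {
    # damped-Newton fallback: rebuild the finite-difference Jacobian at the
    # best iterate on every retry (stiff steric contacts move the Jacobian
    # far from any quasi-Newton approximation)
    n_retry <- if (sys$backend == "rft") 6L else 3L
    for (retry in seq_len(n_retry)) {
      full <- sys$nsw <= 6
      sys$bro$B0 <- if (full) {
        build_full_precond(sys, sol$x, Phi_new, scheme)
      } else {
        build_block_precond(sys, sol$x, Phi_new, scheme)
      }
      sys$bro$U <- list()
      sys$bro$V <- list()
      sol2 <- broyden_solve(res_fn, sol$x, tol = tol,
                            maxit = sys$solver$broyden_maxit,
                            B0_apply = sys$bro$B0, memory = sys$bro,
                            step_max = step_cap / 2, step_max_idx = q_idx)
      sol2$iterations <- sol$iterations + sol2$iterations
      sol <- sol2
      if (sol$converged) break
    }
  }
  if (!sol$converged) {
    stop(sprintf(
      "implicit step failed at t = %.5g: residual %.3e after %d iterations",
      sys$time + dt, sol$resnorm, sol$iterations))
  }
  # constraint admissibility may require a tighter solve than the overall
  # residual norm criterion
  nq <- length(sys$q)
  g_tol <- sys$solver$constraint_tol * sys$params$ds
  for (refine in 1:2) {
    g_now <- abs(sol$fval[-seq_len(nq)])
    if (!length(g_now) || max(g_now) <= g_tol) break
    sol2 <- broyden_solve(res_fn, sol$x, tol = max(tol / 10, g_tol / 2),
                          maxit = sys$solver$broyden_maxit,
                          B0_apply = sys$bro$B0, memory = sys$bro)
    sol2$iterations <- sol$iterations + sol2$iterations
    sol <- sol2
  }
  if (sol$iterations > 25L) sys$bro$force_refresh <- TRUE

  diag_eval <- bdf2_residual(sys, sol$x, Phi_new, scheme, diagnostics = TRUE)
  sys$q_old <- sys$q
  sys$q <- sol$x[seq_len(nq)]
  sys$lam <- sol$x[-seq_len(nq)]
  sys$Phi <- Phi_new
  sys$time <- sys$time + dt
  sys$step_count <- sys$step_count + 1L
  g <- diag_eval$res[-seq_len(nq)]
  sys$last_diag <- list(iterations = sol$iterations, resnorm = sol$resnorm,
                        max_constraint = if (length(g)) max(abs(g)) else 0)
  sys$last_forces <- list(F_fluid = diag_eval$F_fluid,
                          T_fluid = diag_eval$T_fluid, V = diag_eval$V)
  sys
}

#' Run the simulation loop
#'
#' Repeated implicit steps with steric, elastic, driving and constraint
#' forces fed to the chosen mobility backend. When the stochastic frequency
#' modulation is active, per-swimmer frequencies are redrawn from the
#' lognormal law at every multiple of the mean period; the integrated phase
#' is continuous across redraws.
#'
#' @param sys a \code{film_system} from \code{\link{initialize_suspension}}.
#' @param n_periods duration in mean undulation periods (or give
#'   \code{n_steps}).
#' @param n_steps duration in steps.
#' @param record_every record every k-th step (default 1).
#' @param progress print progress every ~period.
#' @return a \code{film_trajectory}: recorded times, configurations, drive
#'   state, forces exerted on the fluid, body velocities, solver
#'   diagnostics, and the final system under \code{$sys}.
#' @export
run_film <- function(sys, n_periods = NULL, n_steps = NULL,
                     record_every = 1L, progress = FALSE) {
  dt <- sys$solver$dt
  if (is.null(n_steps)) {
    stopifnot(!is.null(n_periods))
    n_steps <- round(n_periods * sys$params$T_period / dt)
  }
  n_rec <- floor(n_steps / record_every)
  nq <- length(sys$q)
  nb <- nq / 3
  rec <- list(
    times = numeric(n_rec),
    q = matrix(0, n_rec, nq),
    Phi = matrix(0, n_rec, sys$nsw),
    omega = matrix(0, n_rec, sys$nsw),
    F_fluid = matrix(0, n_rec, 2 * nb),
    T_fluid = matrix(0, n_rec, nb),
    V = matrix(0, n_rec, 3 * nb),
    iterations = integer(n_rec),
    max_constraint = numeric(n_rec)
  )
  Tm <- sys$params$T_period
  ri <- 0L
  for (step in seq_len(n_steps)) {
    # synchronous frequency redraw at multiples of the mean period
    if (sys$params$sigma_omega > 0) {
      k_next <- floor((sys$time + dt) / Tm + 1e-12)
      if (k_next > sys$freq_epoch) {
        sys$freq_epoch <- k_next
        sys$omega_cur <- sample_frequencies(sys$params, sys$nsw,
                                            seed = sys$freq_seed + k_next)
      }
    }
    sys <- film_step(sys)
    if (step %% record_every == 0L) {
      ri <- ri + 1L
      rec$times[ri] <- sys$time
      rec$q[ri, ] <- sys$q
      rec$Phi[ri, ] <- sys$Phi
      rec$omega[ri, ] <- sys$omega_cur
      rec$F_fluid[ri, ] <- sys$last_forces$F_fluid
      rec$T_fluid[ri, ] <- sys$last_forces$T_fluid
      rec$V[ri, ] <- sys$last_forces$V
      rec$iterations[ri] <- sys$last_diag$iterations
      rec$max_constraint[ri] <- sys$last_diag$max_constraint
    }
    if (progress && step %% sys$params$steps_per_period == 0L) {
      message(sprintf("t = %.4g (%d/%d steps), broyden %d it",
                      sys$time, step, n_steps, sys$last_diag$iterations))
    }
  }
  traj <- c(rec, list(params = sys$params, grid = sys$grid,
                      config = sys$config, backend = sys$backend,
                      dt = dt, record_every = record_every, nsw = sys$nsw,
                      sys = sys))
  class(traj) <- "film_trajectory"
  traj
}

#' Swimmer centres of mass along a trajectory
#'
#' Arithmetic mean of all body positions of each swimmer.
#'
#' @param traj a \code{film_trajectory}.
#' @return array frames x swimmers x 2.
#' @export
swimmer_com <- function(traj) {
  bps <- traj$params$N_flag + 1
  nf <- nrow(traj$q)
  out <- array(0, c(nf, traj$nsw, 2))
  for (s in seq_len(traj$nsw)) {
    cols_x <- 3 * bps * (s - 1) + seq(1, 3 * bps, by = 3)
    cols_y <- cols_x + 1
    out[, s, 1] <- rowMeans(traj$q[, cols_x, drop = FALSE])
    out[, s, 2] <- rowMeans(traj$q[, cols_y, drop = FALSE])
  }
  out
}

#' Mean swimming speed over a time window
#'
#' Displacement-based mean centre-of-mass speed between two times,
#' reported per swimmer.
#'
#' @param traj a \code{film_trajectory}.
#' @param t_from,t_to window limits (defaults: second half of the run).
#' @return numeric vector of speeds.
#' @export
mean_swimming_speed <- function(traj, t_from = NULL, t_to = NULL) {
  if (is.null(t_to)) t_to <- max(traj$times)
  if (is.null(t_from)) t_from <- t_to / 2
  i0 <- which.min(abs(traj$times - t_from))
  i1 <- which.min(abs(traj$times - t_to))
  com <- swimmer_com(traj)
  disp <- sqrt((com[i1, , 1] - com[i0, , 1])^2 +
               (com[i1, , 2] - com[i0, , 2])^2)
  disp / (traj$times[i1] - traj$times[i0])
}
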