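# Multi-swimmer orchestration: initial conditions, the stochastic frequency
# process, steric forces, and construction of the simulation system object.

#' Draw per-swimmer undulation frequencies
#'
#' Frequencies are drawn from a lognormal law with linear-scale mean
#' \code{omega_bar} and standard deviation \code{sigma_omega}
#' (log-parameters \code{mu = log(m^2 / sqrt(m^2 + s^2))},
#' \code{sd = sqrt(log(1 + s^2/m^2))}). With \code{sigma_omega = 0} every
#' draw equals \code{omega_bar} exactly. Draws are reproducible for a given
#' seed.
#'
#' @param params a \code{\link{physical_params}}.
#' @param n number of swimmers.
#' @param seed integer seed for this draw (the run loop passes
#'   \code{freq_seed + epoch}).
#' @return numeric vector of positive frequencies.
#' @export
sample_frequencies <- function(params, n, seed = NULL) {
  m <- params$omega_bar
  s <- params$sigma_omega
  if (s == 0) return(rep(m, n))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed %% .Machine$integer.max)
  }
  mu <- log(m^2 / sqrt(m^2 + s^2))
  sdl <- sqrt(log(1 + s^2 / m^2))
  stats::rlnorm(n, meanlog = mu, sdlog = sdl)
}

#' Steric barrier forces between all bodies
#'
#' Pairwise repulsion between non-bonded bodies with magnitude
#' \code{F_S ((R_ref^2 - r^2) / (R_ref^2 - (a_i+a_j)^2))^4} for
#' \code{r < R_ref = chi (a_i + a_j)} and zero beyond; exactly \code{F_S} at
#' contact. Bonded neighbours (same swimmer, body index difference <= 2)
#' are excluded; distances use the minimum image in the periodic box.
#'
#' @param sys a \code{film_system} (or any object with \code{$model} and
#'   planar coordinates \code{$q}).
#' @return n_bodies x 2 matrix of in-plane forces.
#' @export
steric_forces <- function(sys) {
  out <- .forces_cpp(sys$model, sys$q, numeric(length(sys$lam)),
                     rep(0, sys$nsw))
  matrix(out$F, ncol = 2, byrow = TRUE)
}

#' Initialize a film system
#'
#' Builds the planar simulation state for a suspension in the periodic
#' film. Placement modes: \code{"polar"} puts swimmers on a jittered lattice
#' of lanes, all aligned with tangent along +x (so they swim towards -x),
#' with phases uniform on \code{[0, 2 pi)}; \code{"isotropic"} draws
#' uniformly random positions and orientations with bounded overlap
#' retries; \code{"pair"} places two parallel swimmers separated by
#' \code{pair_offset} with phase difference \code{delta_phi};
#' \code{"solitary"} one swimmer at the box centre. Deterministic given the
#' seeds in the configuration.
#'
#' @param config a \code{\link{suspension_config}}.
#' @param grid a \code{\link{grid_spec}}.
#' @param params a \code{\link{physical_params}}.
#' @param backend \code{"fcm"} (full hydrodynamics) or \code{"rft"}
#'   (local drag only).
#' @param solver a \code{\link{solver_settings}} (default uses
#'   \code{params$dt}).
#' @param rft optional \code{\link{rft_coeffs}} override.
#' @param steric include steric forces (default: multi-swimmer systems).
#' @return an object of class \code{film_system}.
#' @export
initialize_suspension <- function(config, grid, params,
                                  backend = c("fcm", "rft"),
                                  solver = solver_settings(),
                                  rft = NULL, steric = config$N > 1) {
  backend <- match.arg(backend)
  N <- config$N
  d <- params$d

  withr_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    expr
  }

  phases <- switch(config$init_mode,
    solitary = 0,
    pair = c(0, config$delta_phi),
    withr_seed(config$phase_seed, stats::runif(N, 0, 2 * pi)))

  placement <- switch(config$init_mode,
    solitary = list(x = grid$L / 2 - d / 2, y = grid$L_y / 2, th = 0),
    pair = list(x = grid$L / 2 - d / 2 + c(0, config$pair_offset[1]),
                y = grid$L_y / 2 + c(-0.5, 0.5) * config$pair_offset[2],
                th = c(0, 0)),
    polar = polar_placement(N, grid, params, config$placement_seed),
    isotropic = isotropic_placement(N, grid, params, config$placement_seed))

  q <- numeric(0)
  for (s in seq_len(N)) {
    sw <- straight_swimmer(params, c(placement$x[s], placement$y[s]),
                           placement$th[s], phases[s])
    q <- c(q, sw$q)
  }

  if (backend == "fcm") {
    be <- planar_backend(params, grid, N, phases, steric)
    ctx <- be$ctx
    model <- be$model
  } else {
    model <- model_desc(params, N, phases, grid, steric)
    ctx <- .model_ctx_new(model)
  }
  if (is.null(solver$dt)) solver$dt <- params$dt
  if (is.null(rft)) rft <- rft_coeffs(params)

  sys <- list(
    params = params, grid = grid, config = config, backend = backend,
    solver = solver, rft = rft, model = model, ctx = ctx,
    nsw = N, phases = phases,
    q = q, q_old = NULL,
    lam = numeric(N * (3 + 2 * (params$N_flag - 1))),
    Phi = rep(0, N),
    omega_cur = rep(params$omega_bar, N),
    freq_seed = config$freq_seed, freq_epoch = 0,
    time = 0, step_count = 0L,
    block_index = block_index_list(N, params$N_flag),
    bro = new.env(parent = emptyenv())
  )
  class(sys) <- "film_system"
  if (params$sigma_omega > 0) {
    sys$omega_cur <- sample_frequencies(params, N, seed = config$freq_seed)
  }
  sys
}

# lanes of nose-to-tail swimmers, jittered; guarantees non-overlap at
# moderate effective area fractions
polar_placement <- function(N, grid, params, seed) {
  d <- params$d
  gap <- 0.03 * d
  per_lane <- max(1, floor(grid$L / (d + gap)))
  n_lanes <- ceiling(N / per_lane)
  lane_dy <- grid$L_y / n_lanes
  if (lane_dy < 3 * params$b) {
    stop("polar placement: too many swimmers for the box")
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  xs <- ys <- numeric(N)
  for (s in seq_len(N)) {
    lane <- (s - 1) %/% per_lane
    slot <- (s - 1) %% per_lane
    xs[s] <- (slot + 0.1) * grid$L / per_lane +
      stats::runif(1, 0, 0.3) * gap
    # lateral jitter small enough that beat envelopes of neighbouring
    # lanes cannot interlock (the lattice is jittered to stay overlap-free)
    ys[s] <- (lane + 0.5) * lane_dy +
      stats::runif(1, -0.05, 0.05) * lane_dy
  }
  list(x = xs, y = ys, th = rep(0, N))
}

isotropic_placement <- function(N, grid, params, seed, max_tries = 2000) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  d <- params$d
  xs <- ys <- th <- numeric(N)
  # segment-chain overlap test against already placed swimmers; clearance
  # covers the head--segment steric range chi (a + b)
  clearance <- 1.15 * 1.1 * (params$a + params$b)
  seg_pts <- function(x, y, ang) {
    s <- seq(0, d, length.out = 48)
    cbind(x + s * cos(ang), y + s * sin(ang))
  }
  placed <- list()
  for (s in seq_len(N)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      x <- stats::runif(1, 0, grid$L)
      y <- stats::runif(1, 0, grid$L_y)
      ang <- stats::runif(1, 0, 2 * pi)
      pts <- seg_pts(x, y, ang)
      clash <- FALSE
      for (p in placed) {
        dxp <- outer(pts[, 1], p[, 1], "-")
        dyp <- outer(pts[, 2], p[, 2], "-")
        dxp <- dxp - grid$L * round(dxp / grid$L)
        dyp <- dyp - grid$L_y * round(dyp / grid$L_y)
        if (min(dxp^2 + dyp^2) < clearance^2) {
          clash <- TRUE
          break
        }
      }
      if (!clash) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("isotropic placement: could not resolve overlaps")
    xs[s] <- x; ys[s] <- y; th[s] <- ang
    placed[[s]] <- seg_pts(x, y, ang)
  }
  list(x = xs, y = ys, th = th)
}

#' @export
print.film_system <- function(x, ...) {
  cat(sprintf(
    "film_system: %d swimmer(s), backend %s, t = %.4g (%d steps)\n",
    x$nsw, x$backend, x$time, x$step_count))
  if (!is.na(x$config$nu)) {
    cat(sprintf("  effective area fraction nu = %.3g\n", x$config$nu))
  }
  invisible(x)
}
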