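# Spectral experiments on the thin film.

#' Energy spectrum of a film driven by spatially uncorrelated forcing
#'
#' Drives the periodic thin film with \code{n_forces} regularized point
#' forces at uniformly random positions (throughout the film volume) with
#' isotropic random in-plane directions, solves the 3D periodic Stokes
#' equations, and computes the shell-averaged energy spectrum of the
#' midplane velocity slice, averaged over \code{n_draws} independent
#' draws. At sub-flagellum scales (in-plane wavelengths below the film
#' crossover \code{2 pi / L_z}) the incoherent superposition of
#' single-force flows gives a \code{k^-3} decay, the same power law the
#' flagellum-scale forcing imprints on suspension spectra.
#'
#' Forces are regularized with width \code{sigma}, which multiplies the
#' spectrum by the known factor \code{exp(-sigma^2 k^2)}; with
#' \code{deconvolve = TRUE} (default) that factor is divided out so the
#' point-force power law is visible across the whole sub-film band.
#'
#' @param grid a \code{\link{grid_spec}}.
#' @param n_forces forces per draw (>= 1000 recommended).
#' @param n_draws independent draws.
#' @param sigma force regularization width (default: segment envelope).
#' @param eta viscosity.
#' @param seed RNG seed.
#' @param deconvolve divide out the squared regularization envelope.
#' @return data frame with \code{k}, \code{S_k}, \code{sd}, \code{n_modes}
#'   (averaged over draws).
#' @export
uncorrelated_forcing_spectrum <- function(grid, n_forces = 1000L,
                                          n_draws = 20L, sigma = NULL,
                                          eta = 1, seed = 1L,
                                          deconvolve = TRUE) {
  if (is.null(sigma)) sigma <- fcm_envelopes(1)$sigma
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  snaps <- vector("list", n_draws)
  for (dr in seq_len(n_draws)) {
    pos <- cbind(stats::runif(n_forces, 0, grid$L),
                 stats::runif(n_forces, 0, grid$L_y),
                 stats::runif(n_forces, 0, grid$L_z))
    ang <- stats::runif(n_forces, 0, 2 * pi)
    F <- cbind(cos(ang), sin(ang), 0)
    # zero-mean forcing for periodic solvability
    F[, 1] <- F[, 1] - mean(F[, 1])
    F[, 2] <- F[, 2] - mean(F[, 2])
    snaps[[dr]] <- .film_slice_cpp(grid$N_x, grid$N_y, grid$N_z, grid$dx,
                                   eta, sigma, pos, F)
  }
  spec <- energy_spectrum(snaps, grid)
  if (deconvolve) {
    fac <- exp(sigma^2 * spec$k^2)
    spec$S_k <- spec$S_k * fac
    spec$sd <- spec$sd * fac
  }
  spec
}

#' Fit the log-log slope of a spectrum over a wavenumber band
#'
#' @param spec data frame from \code{\link{energy_spectrum}}.
#' @param k_min,k_max band limits.
#' @return least-squares slope of \code{log S(k)} vs \code{log k}.
#' @export
spectrum_slope <- function(spec, k_min, k_max) {
  sel <- spec$k >= k_min & spec$k <= k_max & spec$S_k > 0
  if (sum(sel) < 3) stop("too few shells in the fitting band")
  stats::coef(stats::lm(log(spec$S_k[sel]) ~ log(spec$k[sel])))[[2]]
}
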