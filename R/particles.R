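#' Magnetic drug particle specification
#'
#' Spherical particle of diameter `d_p`, material density `rho_p` and
#' relative magnetic permeability `mu_r_p`. The mass follows as
#' `m_p = (pi/6) d_p^3 rho_p`. The defaults are magnetite-loaded carrier
#' particles: 4 um diameter, 5230 kg/m^3, permeability 9.
#'
#' @param d_p diameter (m).
#' @param rho_p density (kg/m^3).
#' @param mu_r_p relative magnetic permeability, > 1 for paramagnetic
#'   attraction.
#' @return object of class `particle_spec` (includes derived mass `m_p` and
#'   the Stokes response time `tau = rho_p d_p^2 / (18 eta)` is available
#'   via [stokes_time()]).
#' @export
particle_spec <- function(d_p = 4e-6, rho_p = 5230, mu_r_p = 9) {
  .chk(d_p > 0 && rho_p > 0, "particle diameter and density must be positive")
  .chk(mu_r_p > 1, "mu_r_p must exceed 1 (paramagnetic particle)")
  structure(list(d_p = d_p, rho_p = rho_p, mu_r_p = mu_r_p,
                 m_p = pi / 6 * d_p^3 * rho_p),
            class = "particle_spec")
}

#' Stokes relaxation time of a particle
#'
#' `tau = rho_p d_p^2 / (18 eta)`: the exponential time constant with which
#' the particle velocity relaxes to the local air velocity in the Stokes
#' drag limit.
#'
#' @param spec a [particle_spec()].
#' @param eta fluid dynamic viscosity (Pa s).
#' @return time constant (s).
#' @export
stokes_time <- function(spec, eta = 1.78e-5) {
  spec$rho_p * spec$d_p^2 / (18 * eta)
}

#' Schiller-Naumann drag force
#'
#' `F_d = 3 eta C_D Re_p / (4 rho_p d_p^2) * m_p * (u - v)` with drag
#' coefficient `C_D = 24/Re_p (1 + 0.15 Re_p^0.687)` and particle Reynolds
#' number `Re_p = rho |u - v| d_p / eta`. Algebraically this reduces to
#' `3 pi eta d_p (1 + 0.15 Re_p^0.687) (u - v)`, recovering Stokes drag
#' exactly as `Re_p -> 0`, so the force is continuous at `u = v`.
#'
#' @param u fluid velocity, n x 3 or 3-vector (m/s).
#' @param v particle velocity, same shape.
#' @param spec a [particle_spec()].
#' @param rho fluid density (kg/m^3).
#' @param eta fluid dynamic viscosity (Pa s).
#' @return force, same shape as `u` (N).
#' @export
drag_force <- function(u, v, spec, rho = 1.22, eta = 1.78e-5) {
  U <- .as_points(u); V <- .as_points(v)
  rel <- U - V
  Re <- rho * .norm3(rel) * spec$d_p / eta
  f <- 3 * pi * eta * spec$d_p * (1 + 0.15 * Re^0.687)
  out <- rel * f
  if (length(u) == 3 && is.null(dim(u))) drop(out) else out
}

#' Schiller-Naumann drag coefficient
#'
#' @param Re_p particle Reynolds number(s), positive.
#' @return `C_D = 24/Re_p (1 + 0.15 Re_p^0.687)`.
#' @export
drag_coefficient <- function(Re_p) 24 / Re_p * (1 + 0.15 * Re_p^0.687)

#' Magnetophoretic force on a particle
#'
#' `F_m = (pi/4) d_p^3 mu0 mu_r K grad(H^2)` with the permeability contrast
#' factor `K = (mu_r_p - mu_r) / (mu_r_p + 2 mu_r)`. `K` increases
#' monotonically with `mu_r_p` and saturates at 1, so ever more magnetic
#' particles gain ever less force. In air and tissue `mu_r = 1`.
#'
#' @param spec a [particle_spec()].
#' @param gradH2 gradient of H^2, n x 3 or 3-vector (A^2/m^3).
#' @param mu_r relative permeability of the carrier medium.
#' @return force parallel to `gradH2` (N).
#' @export
magnetophoretic_force <- function(spec, gradH2, mu_r = 1) {
  K <- (spec$mu_r_p - mu_r) / (spec$mu_r_p + 2 * mu_r)
  out <- pi / 4 * spec$d_p^3 * .mu0 * mu_r * K * .as_points(gradH2)
  if (length(gradH2) == 3 && is.null(dim(gradH2))) drop(out) else out
}

#' Seed particles on the inlet disc
#'
#' Samples starting positions on the trachea inlet cross-section and sets
#' each initial velocity to the local air velocity. `"flux"` weighting
#' (default) draws radial positions with probability proportional to the
#' local axial velocity times area, i.e. how an inhaled aerosol enters a
#' developed profile; `"uniform"` weights by area only. Deterministic under
#' a fixed seed.
#'
#' @param n number of particles, >= 1.
#' @param tree the airway tree.
#' @param flow a [solve_flow()] result.
#' @param seed RNG seed.
#' @param weighting `"flux"` or `"uniform"`.
#' @return object of class `particle_states`: positions, velocities, status
#'   (`in_flight`), per-particle clock, host-branch visit flag.
#' @export
seed_particles <- function(n, tree, flow, seed = 1,
                           weighting = c("flux", "uniform")) {
  weighting <- match.arg(weighting)
  .chk(n >= 1, "need at least one particle")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  R <- tree$R_seg[1]
  u01 <- runif(n)
  if (weighting == "flux") {
    # radial density proportional to the local axial flux u(r) r at the
    # inlet station: invert the numerically built CDF of the actual profile
    rg <- seq(0, R * 0.999, length.out = 256)
    probe <- .rowvec(tree$start[1, ], 256) +
      outer(rep(1e-6, 256), tree$dir[1, ]) + outer(rg, tree$nrm[1, ])
    ug <- .norm3(flow_velocity(flow, probe))
    cdf <- cumsum(ug * rg); cdf <- cdf / cdf[length(cdf)]
    rt <- approx(c(0, cdf), c(0, rg), xout = u01, ties = "ordered")$y / R
  } else {
    rt <- sqrt(u01)
  }
  phi <- runif(n, 0, 2 * pi)
  e2 <- tree$nrm[1, ]; e3 <- c(0, 0, 1)
  # a hair inside the inlet plane so the seeds classify as lumen
  eps <- 1e-9
  pos <- .rowvec(tree$start[1, ], n) + outer(rep(eps, n), tree$dir[1, ]) +
    outer(rt * R * cos(phi), e2) + outer(rt * R * sin(phi), e3)
  vel <- flow_velocity(flow, pos)
  structure(list(pos = pos, vel = vel,
                 status = rep("in_flight", n),
                 t = numeric(n),
                 visited = matrix(FALSE, n, tree$n_seg),
                 n = n, seed = seed, weighting = weighting),
            class = "particle_states")
}

#' @export
print.particle_states <- function(x, ...) {
  cat("<particle_states>", x$n, "particles:\n")
  print(table(x$status))
  invisible(x)
}
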