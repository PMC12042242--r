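#' Bulk superconducting magnet
#'
#' A cylindrical single-grain bulk superconductor, fully magnetized so that
#' it carries an azimuthal critical current everywhere (Bean critical
#' state). The pose is given by the position of its top-surface centre and
#' the unit axis vector pointing away from that surface into the region of
#' interest (the lung side); the cylinder body occupies axial positions
#' `[-t, 0]` in its own frame.
#'
#' @param a radius (m), positive.
#' @param t thickness (m), positive.
#' @param jc a [jc_curve()].
#' @param center 3-vector, world position of the top-surface centre (m).
#' @param axis unit 3-vector, symmetry axis pointing out of the top surface.
#' @return object of class `bulk_magnet`.
#' @export
bulk_magnet <- function(a, t, jc, center = c(0, 0, 0), axis = c(0, 0, 1)) {
  .chk(a > 0 && t > 0, "magnet dimensions must be positive")
  stopifnot(inherits(jc, "jc_curve"), length(center) == 3, length(axis) == 3)
  nrm <- sqrt(sum(axis^2))
  .chk(nrm > 0, "axis must be a non-zero vector")
  structure(list(a = a, t = t, jc = jc,
                 center = as.numeric(center), axis = as.numeric(axis) / nrm),
            class = "bulk_magnet")
}

#' @export
print.bulk_magnet <- function(x, ...) {
  cat(sprintf("<bulk_magnet> a = %.1f mm, t = %.1f mm, Jc model %s (Jc0 = %.3g A/m^2)\n",
              x$a * 1e3, x$t * 1e3, x$jc$model, x$jc$Jc0))
  invisible(x)
}

# Gauss-Legendre loop quadrature over the cylinder cross-section
# (r' in (0, a), z' in (-t, 0) in the magnet frame, top surface at z' = 0).
# Panels refine the corner singularity that the on-axis surface-centre
# evaluation sees at r' -> 0, z' -> 0.
.loop_grid <- function(a, t, nr = 12, nz = 12, pr = 4, pz = 3) {
  gl_panels <- function(breaks, n) {
    xs <- NULL; ws <- NULL
    for (i in seq_len(length(breaks) - 1)) {
      g <- pracma::gaussLegendre(n, breaks[i], breaks[i + 1])
      xs <- c(xs, g$x); ws <- c(ws, g$w)
    }
    list(x = xs, w = ws)
  }
  gr <- gl_panels(a * seq(0, 1, length.out = pr + 1), nr)
  gz <- gl_panels(-t + t * seq(0, 1, length.out = pz + 1), nz)
  list(r = rep(gr$x, times = length(gz$x)),
       z = rep(gz$x, each = length(gr$x)),
       w = as.vector(outer(gr$w, gz$w)))
}

# Field of one circular loop (radius rl, height zl, current I) at
# axisymmetric points (rho, z); complete elliptic integrals K, E.
.loop_field <- function(rl, zl, I, rho, z) {
  zz <- z - zl
  eps <- 1e-12
  rr <- pmax(rho, eps)
  d2 <- (rl + rr)^2 + zz^2
  m <- pmin(4 * rl * rr / d2, 1 - 1e-14)
  ek <- pracma::ellipke(m)
  den <- (rl - rr)^2 + zz^2
  pref <- .mu0 * I / (2 * pi * sqrt(d2))
  Bz <- pref * (ek$k + (rl^2 - rr^2 - zz^2) / den * ek$e)
  Brho <- pref * zz / rr * (-ek$k + (rl^2 + rr^2 + zz^2) / den * ek$e)
  Brho[rho < eps] <- 0
  list(Brho = Brho, Bz = Bz)
}

# Axisymmetric field of a current distribution at (rho, z) in the magnet
# frame; returns components (Brho, Bz). skip: index of a loop to omit
# (used for self-field evaluation at source nodes).
.dist_field <- function(cur, rho, z, skip = 0L) {
  Brho <- numeric(length(rho)); Bz <- numeric(length(rho))
  for (i in seq_along(cur$r)) {
    if (i == skip) next
    lf <- .loop_field(cur$r[i], cur$z[i], cur$J[i] * cur$w[i], rho, z)
    Brho <- Brho + lf$Brho; Bz <- Bz + lf$Bz
  }
  list(Brho = Brho, Bz = Bz)
}

#' Magnetize a bulk magnet into its critical-state current distribution
#'
#' Returns the azimuthal current density carried by the fully magnetized
#' bulk, discretised on a Gauss-Legendre loop quadrature over the cylinder
#' cross-section. In `constant` mode the density is `Jc0` everywhere (one
#' pass). In `kim` mode the self-consistent critical state is found by a
#' damped fixed-point iteration `J <- Jc(|B(J)|)` evaluated at the loop
#' nodes, stopping when the maximum relative change falls below `tol`.
#'
#' @param magnet a [bulk_magnet()].
#' @param nr,nz Gauss-Legendre nodes per panel in radius/thickness.
#' @param pr,pz number of panels in radius/thickness.
#' @param damping fixed-point damping factor in (0, 1].
#' @param tol relative convergence tolerance of the fixed point.
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   residual history.
#' @return object of class `current_distribution` with per-loop radius `r`,
#'   axial position `z` (magnet frame, top surface at 0), quadrature weight
#'   `w` (m^2) and current density `J` (A/m^2).
#' @export
magnetize <- function(magnet, nr = 12, nz = 12, pr = 4, pz = 3,
                      damping = 0.5, tol = 1e-3, max_iter = 100) {
  stopifnot(inherits(magnet, "bulk_magnet"))
  g <- .loop_grid(magnet$a, magnet$t, nr, nz, pr, pz)
  cur <- structure(list(r = g$r, z = g$z, w = g$w,
                        J = rep(magnet$jc$Jc0, length(g$r)),
                        a = magnet$a, t = magnet$t,
                        iterations = 0L, residuals = numeric(0)),
                   class = "current_distribution")
  if (magnet$jc$model == "constant") {
    cur$iterations <- 1L
    return(cur)
  }
  for (it in seq_len(max_iter)) {
    # |B| at every source node from all other loops (the self-loop term of
    # a point quadrature is singular; its true cell contribution is O(dx)
    # and is excluded by exact cancellation of the clamped evaluation)
    Brho <- numeric(length(cur$r)); Bz <- numeric(length(cur$r))
    for (i in seq_along(cur$r)) {
      lf <- .loop_field(cur$r[i], cur$z[i], cur$J[i] * cur$w[i], cur$r, cur$z)
      lf$Brho[i] <- 0; lf$Bz[i] <- 0    # exclude the singular self term
      Brho <- Brho + lf$Brho; Bz <- Bz + lf$Bz
    }
    Bmag <- sqrt(Brho^2 + Bz^2)
    Jnew <- eval_jc(magnet$jc, Bmag)
    res <- max(abs(Jnew - cur$J) / magnet$jc$Jc0)
    cur$residuals <- c(cur$residuals, res)
    cur$J <- (1 - damping) * cur$J + damping * Jnew
    cur$iterations <- it
    if (res < tol) return(cur)
  }
  stop(sprintf("magnetize: Kim fixed point did not converge in %d iterations (residuals: %s)",
               max_iter, paste(signif(tail(cur$residuals, 5), 3), collapse = ", ")))
}

#' Magnetostatic field of a magnetized bulk at arbitrary points
#'
#' Evaluates the Biot-Savart field of the stored azimuthal current density
#' by superposing circular current loops, each loop's off-axis field written
#' in complete elliptic integrals. The result is exact to quadrature
#' tolerance and axisymmetric about the magnet axis.
#'
#' @param magnet a [bulk_magnet()] (provides the pose).
#' @param current a `current_distribution` from [magnetize()].
#' @param x points: 3-vector or n x 3 matrix of world coordinates (m).
#' @return n x 3 matrix of B vectors (T) in world coordinates (a plain
#'   vector if `x` was one point).
#' @export
field_at_point <- function(magnet, current, x) {
  stopifnot(inherits(magnet, "bulk_magnet"), inherits(current, "current_distribution"))
  X <- .as_points(x)
  n <- nrow(X)
  rel <- X - .rowvec(magnet$center, n)
  zeta <- drop(rel %*% magnet$axis)
  perp <- rel - outer(zeta, magnet$axis)
  rho <- .norm3(perp)
  f <- .dist_field(current, rho, zeta)
  rhohat <- perp / ifelse(rho > 1e-12, rho, 1)
  B <- outer(f$Bz, magnet$axis) + rhohat * f$Brho
  if (length(x) == 3 && is.null(dim(x))) drop(B) else B
}
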