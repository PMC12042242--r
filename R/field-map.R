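#' Precomputed field map of a magnetized bulk
#'
#' Tabulates the magnet's field on a regular axisymmetric (rho, zeta) grid
#' in the magnet frame, where `zeta` is the distance from the top surface
#' along the axis (positive on the lung side) and `rho` the distance from
#' the axis. Stored per node: flux density components (T), the squared field
#' strength `H^2 = |B|^2 / mu0^2` (valid where the relative permeability is
#' 1, i.e. air and tissue), and its gradient by centred finite differences.
#' Queries interpolate bilinearly and rotate back to world vectors, so one
#' map serves every magnet-lung distance whose geometry it covers.
#'
#' @param magnet a [bulk_magnet()].
#' @param current a `current_distribution` from [magnetize()]. A coarser
#'   quadrature than the [magnetize()] default is fine here: away from the
#'   magnet surface the integrand is smooth.
#' @param box optional world-coordinate bounding box `list(lo =, hi =)` that
#'   must be covered; converted to (rho, zeta) extents using the magnet pose.
#' @param spacing grid spacing (m), default 1 mm.
#' @param rho_max,zeta_range explicit extents (m) overriding `box`.
#' @return object of class `field_map`.
#' @export
build_field_map <- function(magnet, current, box = NULL, spacing = 1e-3,
                            rho_max = NULL, zeta_range = NULL) {
  stopifnot(inherits(magnet, "bulk_magnet"))
  .chk(spacing > 0, "spacing must be positive")
  if (!is.null(box)) {
    corners <- as.matrix(expand.grid(x = c(box$lo[1], box$hi[1]),
                                     y = c(box$lo[2], box$hi[2]),
                                     z = c(box$lo[3], box$hi[3])))
    rel <- corners - .rowvec(magnet$center, nrow(corners))
    zc <- drop(rel %*% magnet$axis)
    rc <- .norm3(rel - outer(zc, magnet$axis))
    if (is.null(zeta_range)) zeta_range <- c(max(min(zc) - spacing, spacing / 2),
                                             max(zc) + spacing)
    if (is.null(rho_max)) rho_max <- max(rc) + 2 * spacing
  }
  .chk(!is.null(rho_max) && !is.null(zeta_range),
       "either box or rho_max + zeta_range must be given")
  .chk(zeta_range[1] > 0, "field map must lie outside the magnet (zeta > 0)")
  rho <- seq(0, rho_max + spacing, by = spacing)
  zeta <- seq(zeta_range[1], zeta_range[2] + spacing, by = spacing)
  g <- expand.grid(rho = rho, zeta = zeta)
  f <- .dist_field(current, g$rho, g$zeta)
  nr <- length(rho); nz <- length(zeta)
  Brho <- matrix(f$Brho, nr, nz)
  Bz <- matrix(f$Bz, nr, nz)
  H2 <- (Brho^2 + Bz^2) / .mu0^2
  # centred differences (one-sided at the boundary rows/columns)
  ddim <- function(M, h, along) {
    D <- M
    if (along == 1) {
      n <- nrow(M)
      D[2:(n - 1), ] <- (M[3:n, ] - M[1:(n - 2), ]) / (2 * h)
      D[1, ] <- (M[2, ] - M[1, ]) / h
      D[n, ] <- (M[n, ] - M[n - 1, ]) / h
    } else {
      n <- ncol(M)
      D[, 2:(n - 1)] <- (M[, 3:n] - M[, 1:(n - 2)]) / (2 * h)
      D[, 1] <- (M[, 2] - M[, 1]) / h
      D[, n] <- (M[, n] - M[, n - 1]) / h
    }
    D
  }
  structure(list(rho = rho, zeta = zeta, spacing = spacing,
                 Brho = Brho, Bz = Bz, H2 = H2,
                 g2rho = ddim(H2, spacing, 1), g2zeta = ddim(H2, spacing, 2),
                 magnet = magnet),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("<field_map> rho [0, %.0f] mm x zeta [%.1f, %.0f] mm, spacing %.2g mm, peak |B| %.3g T\n",
              max(x$rho) * 1e3, min(x$zeta) * 1e3, max(x$zeta) * 1e3,
              x$spacing * 1e3, sqrt(max(x$H2)) * .mu0))
  invisible(x)
}

#' Place a field map at a magnet pose
#'
#' Attaches a world pose to a magnet-frame [build_field_map()] result: the
#' top-surface centre sits at `center` and the axis (pointing toward the
#' lung) is `axis`. With the lung centred on the z = 0 plane and the magnet
#' above it at distance `d`, use `center = c(x0, y0, d)`, `axis = c(0, 0, -1)`.
#'
#' @param map a `field_map`.
#' @param center world position of the magnet top-surface centre (m).
#' @param axis unit vector from the top surface toward the lung.
#' @return a `placed_field` object queried by [query_field()].
#' @export
place_magnet <- function(map, center, axis = c(0, 0, -1)) {
  stopifnot(inherits(map, "field_map"))
  axis <- as.numeric(axis); axis <- axis / sqrt(sum(axis^2))
  structure(list(map = map, center = as.numeric(center), axis = axis),
            class = "placed_field")
}

# bilinear interpolation of one stored matrix at (rho, zeta)
.fm_interp <- function(map, M, rho, zeta) {
  h <- map$spacing
  ir <- pmin(pmax(floor(rho / h) + 1, 1), length(map$rho) - 1)
  iz <- pmin(pmax(floor((zeta - map$zeta[1]) / h) + 1, 1), length(map$zeta) - 1)
  fr <- rho / h - (ir - 1)
  fz <- (zeta - map$zeta[1]) / h - (iz - 1)
  n <- nrow(M)
  i00 <- ir + (iz - 1) * n
  M[i00] * (1 - fr) * (1 - fz) + M[i00 + 1] * fr * (1 - fz) +
    M[i00 + n] * (1 - fr) * fz + M[i00 + n + 1] * fr * fz
}

#' Query B and grad(H^2) from a placed field map
#'
#' @param pf a `placed_field` from [place_magnet()] (or `NULL`, meaning no
#'   magnet: zero field everywhere).
#' @param x 3-vector or n x 3 matrix of world points (m).
#' @param clip if `TRUE`, points radially beyond the map return zero field
#'   (the far-field tail) instead of erroring; axial range violations always
#'   error because they indicate a map built with the wrong extents.
#' @return list with `B` and `gradH2` (n x 3 matrices, SI units).
#' @export
query_field <- function(pf, x, clip = FALSE) {
  X <- .as_points(x)
  n <- nrow(X)
  if (is.null(pf)) {
    z <- matrix(0, n, 3)
    return(list(B = z, gradH2 = z))
  }
  stopifnot(inherits(pf, "placed_field"))
  map <- pf$map
  rel <- X - .rowvec(pf$center, n)
  zeta <- drop(rel %*% pf$axis)
  perp <- rel - outer(zeta, pf$axis)
  rho <- .norm3(perp)
  tol <- map$spacing
  if (any(zeta < min(map$zeta) - tol) || any(zeta > max(map$zeta) + tol))
    stop("query_field: axial coordinate outside the field map extent")
  zeta <- pmin(pmax(zeta, min(map$zeta)), max(map$zeta))
  out_r <- rho > max(map$rho)
  if (any(out_r) && !clip)
    stop("query_field: radial coordinate outside the field map extent")
  rho_q <- pmin(rho, max(map$rho))
  Brho <- .fm_interp(map, map$Brho, rho_q, zeta)
  Bz <- .fm_interp(map, map$Bz, rho_q, zeta)
  grho <- .fm_interp(map, map$g2rho, rho_q, zeta)
  gz <- .fm_interp(map, map$g2zeta, rho_q, zeta)
  if (any(out_r)) {
    Brho[out_r] <- 0; Bz[out_r] <- 0; grho[out_r] <- 0; gz[out_r] <- 0
  }
  rhohat <- perp / ifelse(rho > 1e-12, rho, 1)
  list(B = outer(Bz, pf$axis) + rhohat * Brho,
       gradH2 = outer(gz, pf$axis) + rhohat * grho)
}

#' Numerical divergence of a field map
#'
#' Cylindrical-coordinate divergence `(1/rho) d(rho Brho)/drho + dBz/dzeta`
#' at interior grid nodes, normalised by `|B| / spacing` so the result is a
#' dimensionless discretisation residual. Used to verify that the tabulated
#' field is solenoidal to discretisation tolerance.
#'
#' @param map a `field_map`.
#' @return matrix of normalised divergence residuals at interior nodes.
#' @export
field_map_divergence <- function(map) {
  stopifnot(inherits(map, "field_map"))
  h <- map$spacing
  nr <- length(map$rho); nz <- length(map$zeta)
  ir <- 2:(nr - 1); iz <- 2:(nz - 1)
  rB <- map$Brho * map$rho           # rho * Brho, recycled down columns
  drB <- (rB[ir + 1, iz] - rB[ir - 1, iz]) / (2 * h)
  dBz <- (map$Bz[ir, iz + 1] - map$Bz[ir, iz - 1]) / (2 * h)
  div <- drB / map$rho[ir] + dBz
  Bmag <- sqrt(map$Brho[ir, iz]^2 + map$Bz[ir, iz]^2)
  div * h / pmax(Bmag, 1e-12)
}
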