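#' Default Weibel airway dimensions, generations G0-G3
#'
#' Branch lengths and radii (mm) of the idealised symmetric dichotomous
#' airway model: G0 (trachea) 120/9, G1 47.6/6.1, G2 19/4.15, G3 7.6/2.8.
#'
#' @return data.frame with columns `generation`, `length_mm`, `radius_mm`.
#' @export
weibel_dims <- function() {
  data.frame(generation = 0:3,
             length_mm = c(120, 47.6, 19, 7.6),
             radius_mm = c(9, 6.1, 4.15, 2.8))
}

#' Build a planar symmetric Weibel airway tree
#'
#' Constructs the binary airway tree in the z = 0 plane: the trachea (G0)
#' runs along +x from the origin and every branch splits into two daughters
#' rotated by +/- `half_angle` about z from the parent direction. Child
#' branches start exactly at the parent end point; a junction sphere of the
#' parent radius bridges the carina region so that the union of branch
#' cylinders and junction spheres is watertight for point classification.
#'
#' @param dims data.frame as [weibel_dims()] (lengths/radii in mm); fewer
#'   generations are allowed (a single row gives one straight duct).
#' @param half_angle bifurcation half-angle per daughter (degrees), in
#'   (0, 90).
#' @return object of class `lung_tree`. Segments are stored with world
#'   start points, unit directions, lengths and radii in metres.
#' @export
build_weibel_tree <- function(dims = weibel_dims(), half_angle = 35) {
  .chk(all(dims$length_mm > 0) && all(dims$radius_mm > 0),
       "branch dimensions must be positive")
  ngen <- nrow(dims)
  if (ngen > 1)
    .chk(half_angle > 0 && half_angle < 90,
         "half_angle must be in (0, 90) degrees")
  L <- dims$length_mm / 1000
  R <- dims$radius_mm / 1000
  segs <- list()
  rot <- function(v, ang) {
    c(cos(ang) * v[1] - sin(ang) * v[2], sin(ang) * v[1] + cos(ang) * v[2], 0)
  }
  add_seg <- function(gen, start, dir, parent) {
    id <- length(segs) + 1L
    segs[[id]] <<- list(id = id, gen = gen, parent = parent,
                        children = integer(0),
                        start = start, dir = dir, L = L[gen + 1], R = R[gen + 1])
    if (parent > 0)
      segs[[parent]]$children <<- c(segs[[parent]]$children, id)
    if (gen + 1 < ngen) {
      endp <- start + dir * L[gen + 1]
      ha <- half_angle * pi / 180
      add_seg(gen + 1L, endp, rot(dir, +ha), id)
      add_seg(gen + 1L, endp, rot(dir, -ha), id)
    }
    id
  }
  add_seg(0L, c(0, 0, 0), c(1, 0, 0), 0L)
  tree <- structure(list(segments = segs, dims = dims,
                         half_angle = half_angle, tumor = NULL),
                    class = "lung_tree")
  tree <- .tree_cache(tree)
  tree
}

# Precompute per-segment frames and matrices used by the vectorized
# geometry queries; called after any structural change.
.tree_cache <- function(tree) {
  segs <- tree$segments
  n <- length(segs)
  tree$n_seg <- n
  tree$start <- t(vapply(segs, `[[`, numeric(3), "start"))
  tree$dir <- t(vapply(segs, `[[`, numeric(3), "dir"))
  tree$L_seg <- vapply(segs, `[[`, numeric(1), "L")
  tree$R_seg <- vapply(segs, `[[`, numeric(1), "R")
  tree$gen <- vapply(segs, `[[`, integer(1), "gen")
  tree$is_leaf <- vapply(segs, function(s) length(s$children) == 0, logical(1))
  # side normal in the plane (z x dir) and the vertical unit vector
  tree$nrm <- t(apply(tree$dir, 1, function(d) c(-d[2], d[1], 0)))
  # daughter cylinders extend upstream into the parent by the parent
  # radius: this merges the branches at the carina (watertight union) and
  # lets the velocity direction turn into the daughter before the junction,
  # as the real flow does
  par <- vapply(segs, `[[`, integer(1), "parent")
  tree$ext_up <- ifelse(par > 0, tree$R_seg[pmax(par, 1L)], 0)
  # radius of the daughter branches (NA for leaves): the end of an internal
  # branch tapers conically to this radius over its last own-radius so the
  # surrogate flow converges into the daughters as the real flow does
  tree$R_child <- vapply(segs, function(s)
    if (length(s$children) > 0) tree$R_seg[s$children[1]] else NA_real_,
    numeric(1))
  tree
}

#' Add an obstructing epithelial wall tumor to a branch
#'
#' The tumor is modelled as a sphere of radius `r = r_ratio * R_host` whose
#' centre lies on the host branch wall, so the spherical cap protruding
#' into the lumen reaches a depth `r` ("growing from the epithelium"). The
#' axial station is a label: `P0`, `P1`, `P2` are the proximal, mid and
#' distal thirds of the host branch (centres at L/6, L/2, 5L/6). The
#' azimuthal angle `alpha` rotates the centre about the branch axis; at
#' `alpha = 0` the tumor sits on the +z wall, facing the magnet.
#'
#' @param tree a [build_weibel_tree()] result.
#' @param r_ratio tumor radius over host branch radius, in (0, 1].
#' @param location `"P0"`, `"P1"` or `"P2"`.
#' @param alpha azimuthal angle (degrees) in `[-90, 90]`.
#' @param host host segment id; default is the G1 daughter on the +y side
#'   (the trachea's first child), or the single duct in a one-branch tree.
#' @return the tree with a `tumor` component (centre, radius, host id).
#' @export
add_tumor <- function(tree, r_ratio = 0.8, location = c("P1", "P0", "P2"),
                      alpha = 0, host = NULL) {
  stopifnot(inherits(tree, "lung_tree"))
  location <- match.arg(location)
  .chk(r_ratio > 0 && r_ratio <= 1, "r_ratio must be in (0, 1]")
  .chk(alpha >= -90 && alpha <= 90, "alpha must be in [-90, 90] degrees")
  if (is.null(host)) {
    host <- if (tree$n_seg == 1) 1L else tree$segments[[1]]$children[1]
  }
  .chk(host >= 1 && host <= tree$n_seg, "host branch does not exist")
  seg <- tree$segments[[host]]
  xi0 <- switch(location, P0 = seg$L / 6, P1 = seg$L / 2, P2 = 5 * seg$L / 6)
  a <- alpha * pi / 180
  nrm <- tree$nrm[host, ]
  center <- seg$start + seg$dir * xi0 +
    seg$R * (cos(a) * c(0, 0, 1) + sin(a) * nrm)
  tree$tumor <- list(host = host, r_ratio = r_ratio, r = r_ratio * seg$R,
                     location = location, alpha = alpha,
                     xi0 = xi0, center = center)
  tree
}

# Local coordinates of points X relative to segment i:
# xi (axial), d2 (squared radial distance to the axis).
# Column-wise arithmetic: this sits in the integrator's innermost loop.
.seg_coords <- function(tree, i, X) {
  s <- tree$start[i, ]; d <- tree$dir[i, ]
  r1 <- X[, 1] - s[1]; r2 <- X[, 2] - s[2]; r3 <- X[, 3] - s[3]
  xi <- r1 * d[1] + r2 * d[2] + r3 * d[3]
  d2 <- r1 * r1 + r2 * r2 + r3 * r3 - xi * xi
  list(xi = xi, d2 = d2)
}

# TRUE for points inside the lumen: union of branch cylinders and junction
# spheres, minus the tumor sphere (a solid obstruction).
.in_lumen <- function(tree, X) {
  X <- .as_points(X)
  n <- nrow(X)
  inside <- rep(FALSE, n)
  for (i in seq_len(tree$n_seg)) {
    sc <- .seg_coords(tree, i, X)
    inside <- inside | (sc$xi >= -tree$ext_up[i] & sc$xi <= tree$L_seg[i] &
                          sc$d2 <= tree$R_seg[i]^2)
  }
  if (!is.null(tree$tumor)) {
    ct <- tree$tumor$center
    dt2 <- (X[, 1] - ct[1])^2 + (X[, 2] - ct[2])^2 + (X[, 3] - ct[3])^2
    inside <- inside & (dt2 > tree$tumor$r^2)
  }
  inside
}

#' Classify points against the airway geometry
#'
#' Partitions space for the particle boundary rules: `lumen` (airway
#' interior), `tumor_surface` (on/inside the tumor sphere), `outlet` (on a
#' terminal-branch exit disc, within `tol` of the exit plane), `wall`
#' (within `tol` of the remaining lumen boundary) and `outside`.
#'
#' @param tree a finalized `lung_tree`.
#' @param x 3-vector or n x 3 matrix (m).
#' @param tol surface tolerance (m).
#' @return character vector of classifications.
#' @export
classify_point <- function(tree, x, tol = 1e-6) {
  X <- .as_points(x)
  n <- nrow(X)
  out <- rep("outside", n)
  # tumor sphere (solid): inside or on it
  if (!is.null(tree$tumor)) {
    rel <- X - .rowvec(tree$tumor$center, n)
    dt <- sqrt(rowSums(rel * rel))
    tum <- dt <= tree$tumor$r + tol
  } else tum <- rep(FALSE, n)
  inl <- .in_lumen(tree, X)
  out[inl] <- "lumen"
  # outlet discs of leaf segments
  outlet <- rep(FALSE, n)
  for (i in which(tree$is_leaf)) {
    sc <- .seg_coords(tree, i, X)
    outlet <- outlet | (abs(sc$xi - tree$L_seg[i]) <= tol &
                          sc$d2 <= tree$R_seg[i]^2)
  }
  out[outlet] <- "outlet"
  out[tum & !inl] <- "tumor_surface"
  # wall: boundary points that are neither tumor nor outlet; detect by
  # probing a small neighbourhood
  maybe_wall <- which(out %in% c("lumen", "outside"))
  if (length(maybe_wall) > 0 && tol > 0) {
    Xs <- X[maybe_wall, , drop = FALSE]
    on_b <- rep(FALSE, length(maybe_wall))
    for (dxi in list(c(tol, 0, 0), c(0, tol, 0), c(0, 0, tol))) {
      shift <- .rowvec(2 * dxi, length(maybe_wall))
      on_b <- on_b | (.in_lumen(tree, Xs + shift) != .in_lumen(tree, Xs - shift))
    }
    out[maybe_wall][on_b] <- "wall"
  }
  out
}

#' Fraction of the host cross-section left open at an axial station
#'
#' At axial coordinate `xi` along the tumor's host branch, the tumor sphere
#' cuts the circular cross-section in a disc of radius
#' `sqrt(r^2 - (xi - xi0)^2)` centred on the wall circle. The open fraction
#' is one minus the lens-shaped intersection area over the full disc area.
#'
#' @param tree tree with a tumor.
#' @param xi axial coordinates along the host branch (m), vectorised.
#' @return open area fraction in (0, 1].
#' @export
open_area_fraction <- function(tree, xi) {
  .chk(!is.null(tree$tumor), "tree has no tumor")
  tum <- tree$tumor
  R <- tree$R_seg[tum$host]
  dz <- xi - tum$xi0
  rt2 <- tum$r^2 - dz^2
  frac <- rep(1, length(xi))
  hit <- rt2 > 0
  if (any(hit)) {
    rt <- sqrt(rt2[hit])
    d <- R  # centre-to-centre distance: sphere centre is on the wall circle
    # circle-circle intersection area (radii R and rt, centres d apart)
    a1 <- (d^2 + R^2 - rt^2) / (2 * d * R)
    a2 <- (d^2 + rt^2 - R^2) / (2 * d * rt)
    a1 <- pmin(pmax(a1, -1), 1); a2 <- pmin(pmax(a2, -1), 1)
    lens <- R^2 * acos(a1) + rt^2 * acos(a2) -
      0.5 * sqrt(pmax((-d + R + rt) * (d + R - rt) * (d - R + rt) * (d + R + rt), 0))
    frac[hit] <- pmax(1 - lens / (pi * R^2), 1e-3)
  }
  frac
}

#' Monte Carlo area of the tumor surface patch exposed to the lumen
#'
#' Samples points uniformly on the tumor sphere and measures the fraction
#' lying inside the unobstructed lumen (the exposed cap on which particles
#' can deposit), returning `fraction * 4 pi r^2`.
#'
#' @param tree tree with tumor.
#' @param n number of sphere samples.
#' @param seed RNG seed for reproducibility.
#' @return area (m^2).
#' @export
tumor_patch_area <- function(tree, n = 20000, seed = 1) {
  .chk(!is.null(tree$tumor), "tree has no tumor")
  tum <- tree$tumor
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v <- v / .norm3(v)
  P <- .rowvec(tum$center, n) + v * tum$r
  # exposed: inside the airway union ignoring the tumor itself
  bare <- tree; bare$tumor <- NULL
  mean(.in_lumen(bare, P)) * 4 * pi * tum$r^2
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.lung_tree <- function(x, ...) {
  cat(sprintf("<lung_tree> %d segments, generations 0-%d, half-angle %g deg\n",
              x$n_seg, max(x$gen), x$half_angle))
  if (!is.null(x$tumor))
    cat(sprintf("  tumor: host %d, r/R = %g, %s, alpha = %g deg\n",
                x$tumor$host, x$tumor$r_ratio, x$tumor$location, x$tumor$alpha))
  invisible(x)
}
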